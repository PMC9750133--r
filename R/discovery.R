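#' Editing efficiency from edited/unedited base counts
#'
#' The efficiency of C-to-U conversion at a site is the fraction of edited
#' transcripts, `100 * t / (t + c)` in percent (equivalently `A/(A+G)` for a
#' minus-strand transcript observed in plus-strand genome orientation).
#'
#' @param t_count edited (T, or A on the minus strand) read count.
#' @param c_count unedited (C, or G) read count.
#' @return editing efficiency in percent.
#' @export
editing_efficiency <- function(t_count, c_count) {
  if (any(t_count + c_count == 0)) {
    stop_data("editing_efficiency undefined for zero coverage")
  }
  100 * t_count / (t_count + c_count)
}

#' Call SNPs from a strand-aware pileup
#'
#' One record per (position, transcript strand) where the most frequent
#' non-reference base reaches `min_rate` of the strand coverage and coverage
#' is at least `min_coverage`. The SNP rate denominator is the total strand
#' coverage at the position (all four bases); the two-allele editing
#' efficiency `alt/(alt+ref)` is reported alongside. Y/R-masked reference
#' positions are evaluated against their unmasked base (Y = C, R = G).
#'
#' @param pileup a `pileup` from [build_pileup()].
#' @param genome the matching `organelle_genome` (possibly masked).
#' @param min_rate minimum non-reference rate, inclusive (default 0.05).
#' @param min_coverage minimum strand coverage (default 20).
#' @return `data.frame` with columns `genome_id`, `position`, `strand`
#'   (transcript strand), `ref_base`, `alt_base`, `ref_count`, `alt_count`,
#'   `coverage`, `alt_rate`, `efficiency` (percent) and `snp_class`
#'   (`C_to_T`, `G_to_A` or `other`).
#' @export
call_snps <- function(pileup, genome, min_rate = 0.05, min_coverage = 20L) {
  stopifnot(min_rate > 0, min_rate <= 1)
  gchars <- unmask_base(seq_chars(genome$sequence))
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (strand in c("+", "-")) {
    cols <- if (strand == "+") 1:4 else 5:8
    cnt <- pileup$counts[, cols, drop = FALSE]
    cov <- rowSums(cnt)
    cand <- which(cov >= min_coverage)
    for (p in cand) {
      ref <- gchars[p]
      ri <- match(ref, bases)
      if (is.na(ri)) next
      nonref <- cnt[p, -ri]
      ai <- which.max(nonref)
      alt_count <- nonref[ai]
      if (alt_count == 0) next
      alt <- bases[-ri][ai]
      rate <- alt_count / cov[p]
      if (rate < min_rate) next
      cls <- if (ref == "C" && alt == "T" && strand == "+") "C_to_T"
             else if (ref == "G" && alt == "A" && strand == "-") "G_to_A"
             else "other"
      out[[length(out) + 1L]] <- data.frame(
        genome_id = pileup$genome_id, position = p, strand = strand,
        ref_base = ref, alt_base = alt,
        ref_count = cnt[p, ri], alt_count = alt_count,
        coverage = cov[p], alt_rate = rate,
        efficiency = editing_efficiency(alt_count, cnt[p, ri]),
        snp_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(genome_id = character(), position = integer(),
                      strand = character(), ref_base = character(),
                      alt_base = character(), ref_count = integer(),
                      alt_count = integer(), coverage = integer(),
                      alt_rate = numeric(), efficiency = numeric(),
                      snp_class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# location class of a site relative to the annotation, given the strand of
# the edited transcript
location_class <- function(position, strand, features) {
  ov <- features[features$start <= position & features$end >= position &
                   !features$ftype %in% c("IR"), , drop = FALSE]
  same <- ov[ov$strand == strand, , drop = FALSE]
  if (nrow(same) > 0) {
    # prefer the most specific annotation (intron over the surrounding gene)
    pref <- c("intron", "CDS", "tRNA", "rRNA", "UTR5", "UTR3", "intergenic")
    ft <- same$ftype[order(match(same$ftype, pref))][1]
    return(if (ft == "intergenic") "intergenic" else ft)
  }
  if (nrow(ov) > 0) {
    if (all(ov$ftype == "intergenic")) return("intergenic_antisense")
    return("antisense")
  }
  "intergenic"
}

#' Filter SNPs down to editing-site candidates
#'
#' Keeps only C-to-T (plus-strand) and G-to-A (minus-strand) SNPs, the two
#' guises of C-to-U editing; removes positions at known editing sites or
#' overlapping tRNA/rRNA genes (hypermodified by unrelated enzymes); and
#' annotates each remaining candidate with a location class (`antisense` when
#' the edited strand opposes the annotated feature).
#'
#' @param snps SNP `data.frame` from [call_snps()].
#' @param known_sites known-sites `data.frame` (`genome_id`, `position`,
#'   `strand`, `name`), or `NULL`.
#' @param features feature `data.frame` of the same reference.
#' @return the filtered SNPs with an added `location_class` column.
#' @export
filter_candidates <- function(snps, known_sites = NULL, features = NULL) {
  keep <- snps$snp_class %in% c("C_to_T", "G_to_A")
  snps <- snps[keep, , drop = FALSE]
  if (!is.null(known_sites) && nrow(snps) > 0) {
    known_key <- paste(known_sites$genome_id, known_sites$position)
    snps <- snps[!paste(snps$genome_id, snps$position) %in% known_key, , drop = FALSE]
  }
  if (is.null(features)) features <- data.frame(name = character(),
                                                ftype = character(),
                                                start = integer(), end = integer(),
                                                strand = character())
  if (nrow(snps) > 0) {
    in_structural <- vapply(seq_len(nrow(snps)), function(i) {
      any(features$ftype %in% c("tRNA", "rRNA") &
            features$start <= snps$position[i] &
            features$end >= snps$position[i])
    }, logical(1))
    snps <- snps[!in_structural, , drop = FALSE]
  }
  snps$location_class <- vapply(seq_len(nrow(snps)), function(i) {
    location_class(snps$position[i], snps$strand[i], features)
  }, character(1))
  rownames(snps) <- NULL
  snps
}

#' Discover off-target editing sites across libraries
#'
#' A site is retained iff its editing efficiency reaches `threshold` percent
#' in at least one mutant library while the wild-type efficiency stays below
#' `wt_cutoff` percent (sites absent from a library are reported as 0).
#'
#' @param mutant_snps named list of filtered SNP `data.frame`s (one per
#'   mutant library; names become the per-library columns).
#' @param wt_snps SNP `data.frame` of the wild-type library (unfiltered SNPs
#'   are fine; only the efficiency at the candidate positions is used).
#' @param threshold minimum editing efficiency in percent (default 5).
#' @param wt_cutoff maximum tolerated wild-type efficiency in percent
#'   (default 1; the expectation is 0, but an exact zero is fragile under
#'   sequencing error).
#' @return `data.frame` with `genome_id`, `position`, `strand`,
#'   `location_class`, one efficiency column per mutant library, and `wt`.
#' @export
discover_offtargets <- function(mutant_snps, wt_snps = NULL, threshold = 5,
                                wt_cutoff = 1) {
  if (length(mutant_snps) == 0) stop_config("no mutant libraries supplied")
  gids <- unique(unlist(lapply(mutant_snps, function(x) unique(x$genome_id))))
  key <- function(x) paste(x$genome_id, x$position, x$strand)
  all_sites <- unique(do.call(rbind, lapply(mutant_snps, function(x) {
    x[, c("genome_id", "position", "strand", "location_class"), drop = FALSE]
  })))
  if (is.null(all_sites) || nrow(all_sites) == 0) {
    out <- data.frame(genome_id = character(), position = integer(),
                      strand = character(), location_class = character())
    for (nm in names(mutant_snps)) out[[nm]] <- numeric(0)
    out$wt <- numeric(0)
    return(out)
  }
  eff_at <- function(snps, k) {
    if (is.null(snps) || nrow(snps) == 0) return(rep(0, length(k)))
    m <- match(k, key(snps))
    ifelse(is.na(m), 0, snps$efficiency[m])
  }
  ks <- key(all_sites)
  for (nm in names(mutant_snps)) all_sites[[nm]] <- eff_at(mutant_snps[[nm]], ks)
  all_sites$wt <- eff_at(wt_snps, ks)
  eff <- as.matrix(all_sites[names(mutant_snps)])
  keep <- apply(eff, 1, max) >= threshold & all_sites$wt < wt_cutoff
  out <- all_sites[keep, , drop = FALSE]
  out <- out[order(out$genome_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the off-target retention filter to an editing matrix
#'
#' Fixture-oriented counterpart of [discover_offtargets()]: given a table of
#' per-library editing percentages, keeps rows edited to at least `threshold`
#' percent in one of the listed libraries with wild type below `wt_cutoff`.
#'
#' @param tab `data.frame` with a `site` column and numeric library columns.
#' @param libraries character vector of mutant library column names.
#' @param wt_col name of the wild-type/control column, or `NULL` to skip the
#'   wild-type filter.
#' @param threshold minimum editing percentage (default 5).
#' @param wt_cutoff maximum wild-type percentage (default 1).
#' @return the retained rows.
#' @export
offtarget_sites <- function(tab, libraries, wt_col = "wt", threshold = 5,
                            wt_cutoff = 1) {
  eff <- as.matrix(tab[libraries])
  keep <- apply(eff, 1, max) >= threshold
  if (!is.null(wt_col)) keep <- keep & tab[[wt_col]] < wt_cutoff
  tab[keep, , drop = FALSE]
}

#' Classify off-target sites into high- and low-affinity targets
#'
#' High-affinity targets are edited (>= `threshold` percent) already in at
#' least one moderate-expression library; low-affinity targets are edited
#' only in the overexpression libraries.
#'
#' @param tab editing `data.frame` with a `site` column and library columns.
#' @param moderate_libs,over_libs column names partitioning the libraries.
#' @param threshold editing percentage threshold (default 5).
#' @return named character vector (`high`/`low`) over the sites edited in at
#'   least one library; unedited sites are dropped.
#' @export
classify_affinity <- function(tab, moderate_libs, over_libs, threshold = 5) {
  stopifnot(length(intersect(moderate_libs, over_libs)) == 0)
  if (nrow(tab) == 0) return(setNames(character(0), character(0)))
  mod <- apply(as.matrix(tab[moderate_libs]), 1, max) >= threshold
  ove <- apply(as.matrix(tab[over_libs]), 1, max) >= threshold
  cls <- ifelse(mod, "high", ifelse(ove, "low", NA_character_))
  out <- setNames(cls, tab$site)
  out[!is.na(out)]
}

#' Codon impact of a C-to-U edit in a coding sequence
#'
#' For a site inside a same-strand CDS, translates the reference and the
#' edited codon (standard genetic code) and reports the amino-acid change as
#' e.g. `"S->L"`, `"Q->STOP"` or `"synonymous"`; sites outside any CDS on the
#' edited strand yield `"-"`.
#'
#' @param position 1-based genome position of the edited C.
#' @param strand transcript strand of the edit.
#' @param genome the `organelle_genome`.
#' @param features feature `data.frame`; CDS intervals are assumed to start
#'   in frame at their `start` (plus strand) / `end` (minus strand).
#' @param require_cds error instead of returning `"-"` when the site is not
#'   in a CDS.
#' @return impact string.
#' @export
annotate_impact <- function(position, strand, genome, features,
                            require_cds = FALSE) {
  cds <- features[features$ftype == "CDS" & features$strand == strand &
                    features$start <= position & features$end >= position, ,
                  drop = FALSE]
  if (nrow(cds) == 0) {
    if (require_cds) stop_data("position ", position, " is not inside a CDS on strand ", strand)
    return("-")
  }
  cds <- cds[1, ]
  gchars <- unmask_base(seq_chars(genome$sequence))
  offset <- if (strand == "+") position - cds$start else cds$end - position
  codon_i <- offset %/% 3L           # 0-based codon index
  within <- offset %% 3L             # 0-based position within codon
  codon_pos <- if (strand == "+") {
    cds$start + codon_i * 3L + 0:2
  } else {
    cds$end - codon_i * 3L - (0:2)
  }
  codon <- gchars[codon_pos]
  if (strand == "-") codon <- chartr("ACGT", "TGCA", codon)
  ref_codon <- paste(codon, collapse = "")
  edited <- codon
  edited[within + 1L] <- "T"
  alt_codon <- paste(edited, collapse = "")
  aa <- function(cod) {
    a <- Biostrings::GENETIC_CODE[[cod]]
    if (is.null(a)) NA_character_ else a
  }
  ref_aa <- aa(ref_codon); alt_aa <- aa(alt_codon)
  if (is.na(ref_aa) || is.na(alt_aa)) return("-")
  if (ref_aa == alt_aa) return("synonymous")
  lab <- function(a) if (a == "*") "STOP" else a
  paste0(lab(ref_aa), "->", lab(alt_aa))
}
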