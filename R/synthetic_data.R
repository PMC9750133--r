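#' Simulation parameters for a strand-specific paired-end library
#'
#' Describes a sequencing library of the kind used for organellar editing-site
#' discovery: strand-specific paired-end reads (2 x 150 nt by default) drawn
#' from transcripts with an average insert size of 250 bp, with per-site
#' binomial C-to-U editing, partial intron splicing, optional antisense
#' transcription and a uniform per-base substitution error rate.
#'
#' @param genome_id id of the genome the library derives from.
#' @param n_pairs number of read pairs to simulate.
#' @param read_length read length in nt (default 150).
#' @param insert_mean,insert_sd fragment (insert) size distribution in nt.
#' @param error_rate per-base substitution error probability.
#' @param editing_fractions named numeric vector: names are 1-based genome
#'   positions of editable Cs (on the transcribed strand), values the
#'   per-molecule editing probability.
#' @param spliced_fraction probability that an intron is spliced out of a
#'   transcript copy.
#' @param antisense_fraction probability that a fragment derives from the
#'   antisense strand of its transcription unit.
#' @param seed integer seed; every [simulate_reads()] call uses one seeded
#'   generator so runs are reproducible.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(genome_id, n_pairs, read_length = 150L,
                            insert_mean = 250L, insert_sd = 25L,
                            error_rate = 0.001,
                            editing_fractions = numeric(),
                            spliced_fraction = 0, antisense_fraction = 0,
                            seed = 1L) {
  probs <- c(error_rate, editing_fractions, spliced_fraction, antisense_fraction)
  if (any(probs < 0 | probs > 1)) stop_config("all probabilities must be in [0,1]")
  if (n_pairs < 0) stop_config("n_pairs must be >= 0")
  if (read_length > insert_mean) stop_config("read_length must be <= insert_mean")
  structure(list(genome_id = genome_id, n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 editing_fractions = editing_fractions,
                 spliced_fraction = spliced_fraction,
                 antisense_fraction = antisense_fraction,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Build a toy organellar genome
#'
#' Generates a random sequence of the requested length (deterministic for a
#' given seed) and stamps in the requested features and editable C positions.
#' Editable sites on the plus strand are forced to C; sites whose transcript
#' is on the minus strand are forced to G on the plus strand (i.e. a C on the
#' transcribed strand).
#'
#' @param config list with elements `id`, `length`, `seed`, optional
#'   `features` (feature `data.frame` as in [organelle_genome()]) and
#'   optional `editable_sites` (`data.frame` with `position`, `strand`,
#'   `name`).
#' @return an `organelle_genome`; editable sites are attached as attribute
#'   `"editable_sites"`.
#' @export
build_toy_genome <- function(config) {
  len <- config$length
  feats <- config$features
  if (!is.null(feats) && nrow(feats) > 1) {
    # same-strand features must not overlap
    for (s in c("+", "-")) {
      f <- feats[feats$strand == s, , drop = FALSE]
      if (nrow(f) > 1) {
        f <- f[order(f$start), ]
        if (any(f$start[-1] <= f$end[-nrow(f)])) {
          stop_config("overlapping same-strand features in toy genome config")
        }
      }
    }
  }
  chars <- with_seed(config$seed %||% 1L,
                     sample(c("A", "C", "G", "T"), len, replace = TRUE))
  sites <- config$editable_sites
  if (!is.null(sites) && nrow(sites) > 0) {
    plus <- sites$strand == "+"
    chars[sites$position[plus]] <- "C"
    chars[sites$position[!plus]] <- "G"
  }
  g <- organelle_genome(id = config$id %||% "toy",
                        sequence = paste(chars, collapse = ""),
                        circular = isTRUE(config$circular),
                        features = feats)
  attr(g, "editable_sites") <- sites
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# transcription units: every non-intron, non-IR feature; introns are
# associated with the unit that contains them
transcription_units <- function(genome) {
  feats <- genome$features
  units <- feats[!feats$ftype %in% c("intron", "IR"), , drop = FALSE]
  introns <- feats[feats$ftype == "intron", , drop = FALSE]
  if (nrow(units) == 0) stop_config("genome has no transcribed features")
  lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    inn <- introns[introns$start >= u$start & introns$end <= u$end &
                     introns$strand == u$strand, , drop = FALSE]
    list(name = u$name, start = u$start, end = u$end, strand = u$strand,
         introns = inn)
  })
}

# map genome positions to offsets on the sense strand of a unit's pre-mRNA
unit_offset <- function(unit, positions) {
  if (unit$strand == "+") positions - unit$start + 1L
  else unit$end - positions + 1L
}

mutate_bases <- function(chars, idx) {
  # substitution errors: each errored base becomes one of the other three
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 3, dimnames = list(NULL, c("A","C","G","T")))
  pick <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- alt[cbind(pick, match(chars[idx], c("A","C","G","T")))]
  chars
}

#' Simulate strand-specific paired-end reads
#'
#' Draws fragments from the transcription units of `genome` (probability
#' proportional to unit length, uniform start within the unit). Each
#' transcript copy is independently edited per site with
#' `Bernoulli(editing_fraction)`, retains each intron with probability
#' `1 - spliced_fraction`, and derives from the antisense strand with
#' probability `antisense_fraction`. Per-base substitution errors are applied
#' after editing. Mate 1 carries the transcript sense; mate 2 is the reverse
#' complement of the fragment's 3' end. Base qualities are constant high
#' quality.
#'
#' @param genome an `organelle_genome` with at least one transcribed feature.
#' @param spec a [simulation_spec()].
#' @return `data.frame` with one row per pair: `id`, `mate1_seq`, `mate2_seq`,
#'   `mate1_qual`, `mate2_qual`, and the true origin (`feature`, `strand`,
#'   `start` = 1-based genome position of the fragment's leftmost plus-strand
#'   base for unspliced fragments, the unit start otherwise).
#' @export
simulate_reads <- function(genome, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  rl <- spec$read_length
  empty <- data.frame(id = character(), mate1_seq = character(),
                      mate2_seq = character(), mate1_qual = character(),
                      mate2_qual = character(), feature = character(),
                      strand = character(), start = integer(),
                      stringsAsFactors = FALSE)
  if (spec$n_pairs == 0) return(empty)
  units <- transcription_units(genome)
  gchars <- seq_chars(genome$sequence)

  ef <- spec$editing_fractions
  epos <- as.integer(names(ef))
  # every editing position must be a C on the transcribed strand of its unit
  for (p in epos) {
    hit <- FALSE
    for (u in units) {
      if (p >= u$start && p <= u$end) {
        hit <- TRUE
        b <- gchars[p]
        ok <- if (u$strand == "+") b %in% c("C", "Y") else b %in% c("G", "R")
        if (!ok) {
          stop_config(sprintf("editing position %d is not a C on the transcribed strand", p))
        }
      }
    }
    if (!hit) stop_config(sprintf("editing position %d is not inside a transcription unit", p))
  }

  with_seed(spec$seed, {
    lens <- vapply(units, function(u) as.integer(u$end - u$start + 1L), integer(1))
    uidx <- sample.int(length(units), spec$n_pairs, replace = TRUE,
                       prob = lens / sum(lens))
    rows <- vector("list", spec$n_pairs)
    for (i in seq_len(spec$n_pairs)) {
      u <- units[[uidx[i]]]
      ulen <- u$end - u$start + 1L
      # sense-strand pre-mRNA of this unit
      mol <- gchars[u$start:u$end]
      if (u$strand == "-") mol <- rev(chartr("ACGT", "TGCA", mol))
      # per-copy editing on the transcribed strand
      upos <- epos[epos >= u$start & epos <= u$end]
      if (length(upos) > 0) {
        off <- unit_offset(u, upos)
        edited <- runif(length(upos)) < ef[as.character(upos)]
        mol[off[edited]] <- "T"
      }
      # splice each intron with probability spliced_fraction
      if (nrow(u$introns) > 0) {
        drop <- logical(length(mol))
        for (j in seq_len(nrow(u$introns))) {
          if (runif(1) < spec$spliced_fraction) {
            io <- sort(unit_offset(u, c(u$introns$start[j], u$introns$end[j])))
            drop[io[1]:io[2]] <- TRUE
          }
        }
        mol <- mol[!drop]
      }
      frag_strand <- u$strand
      if (spec$antisense_fraction > 0 && runif(1) < spec$antisense_fraction) {
        mol <- rev(chartr("ACGT", "TGCA", mol))
        frag_strand <- if (u$strand == "+") "-" else "+"
      }
      mlen <- length(mol)
      ins <- round(rnorm(1, spec$insert_mean, spec$insert_sd))
      ins <- max(rl, min(ins, mlen))
      s <- if (mlen - ins >= 1) sample.int(mlen - ins + 1L, 1L) else 1L
      frag <- mol[s:(s + ins - 1L)]
      m1 <- frag[1:rl]
      m2 <- rev(chartr("ACGT", "TGCA", frag[(ins - rl + 1L):ins]))
      if (spec$error_rate > 0) {
        e1 <- which(runif(rl) < spec$error_rate)
        if (length(e1) > 0) m1 <- mutate_bases(m1, e1)
        e2 <- which(runif(rl) < spec$error_rate)
        if (length(e2) > 0) m2 <- mutate_bases(m2, e2)
      }
      gstart <- if (u$strand == "+") u$start + s - 1L else u$end - (s + ins - 2L)
      rows[[i]] <- list(paste(m1, collapse = ""), paste(m2, collapse = ""),
                        u$name, frag_strand, as.integer(gstart))
    }
    qual <- strrep("I", rl)
    data.frame(id = sprintf("%s_pair%06d", spec$genome_id, seq_len(spec$n_pairs)),
               mate1_seq = vapply(rows, `[[`, character(1), 1L),
               mate2_seq = vapply(rows, `[[`, character(1), 2L),
               mate1_qual = qual, mate2_qual = qual,
               feature = vapply(rows, `[[`, character(1), 3L),
               strand = vapply(rows, `[[`, character(1), 4L),
               start = vapply(rows, `[[`, integer(1), 5L),
               stringsAsFactors = FALSE)
  })
}

#' Simulate junction-spanning reads at a fixed spliced fraction
#'
#' Draws single-end reads that cross a splice junction: each read derives
#' from the spliced form with probability `spliced_fraction`, otherwise from
#' one of the two unspliced borders (chosen uniformly). Read starts are
#' uniform among placements that leave at least `overhang` bases on both
#' sides of the junction, so every read is informative for
#' [splice_ratio()].
#'
#' @param junctions a [junction_reference()].
#' @param n_reads number of reads.
#' @param spliced_fraction probability a read derives from the spliced form.
#' @param read_length read length in nt (default 60).
#' @param overhang minimum bases on each side of the junction (default:
#'   the junction reference's `min_overhang`).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return character vector of read sequences.
#' @export
simulate_junction_reads <- function(junctions, n_reads, spliced_fraction,
                                    read_length = 60L, overhang = NULL,
                                    error_rate = 0, seed = 1L) {
  if (spliced_fraction < 0 || spliced_fraction > 1) {
    stop_config("spliced_fraction must be in [0,1]")
  }
  ov <- overhang %||% junctions$min_overhang
  with_seed(seed, {
    src <- ifelse(runif(n_reads) < spliced_fraction, 1L,
                  sample(2:3, n_reads, replace = TRUE))
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- junctions$seqs[[src[i]]]
      j <- junctions$junction[src[i]]
      lo <- max(1L, j - read_length + ov + 1L)
      hi <- min(nchar(s) - read_length + 1L, j - ov + 1L)
      if (hi < lo) stop_config("read_length/overhang incompatible with junction reference")
      st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      rd <- substr(s, st, st + read_length - 1L)
      if (error_rate > 0) {
        ch <- seq_chars(rd)
        e <- which(runif(read_length) < error_rate)
        if (length(e) > 0) ch <- mutate_bases(ch, e)
        rd <- paste(ch, collapse = "")
      }
      reads[i] <- rd
    }
    reads
  })
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' @param pairs `data.frame` from [simulate_reads()].
#' @param prefix output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  rec <- function(ids, seqs, quals) {
    as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  }
  writeLines(rec(pairs$id, pairs$mate1_seq, pairs$mate1_qual), f1)
  writeLines(rec(pairs$id, pairs$mate2_seq, pairs$mate2_qual), f2)
  invisible(c(f1, f2))
}

#' Read a pair of FASTQ files into the pairs data.frame layout
#' @param file1,file2 mate-1 and mate-2 FASTQ paths.
#' @return `data.frame` with `id`, `mate1_seq`, `mate2_seq`, `mate1_qual`,
#'   `mate2_qual`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  l1 <- readLines(file1); l2 <- readLines(file2)
  i <- seq(1, length(l1), by = 4)
  data.frame(id = sub("^@", "", l1[i]),
             mate1_seq = l1[i + 1], mate2_seq = l2[i + 1],
             mate1_qual = l1[i + 3], mate2_qual = l2[i + 3],
             stringsAsFactors = FALSE)
}

#' Packaged editing-efficiency tables
#'
#' Loads the editing matrices shipped with the package: the 33-site
#' off-target table of the Arabidopsis factor expressed in tobacco (per-line
#' RNA-seq editing percentages, `table2`), the cacao-factor off-target panel
#' (`table4`), the panel measured in the target-overexpressing transplastomic
#' background (`table5`), and the five endogenous Arabidopsis targets
#' (`arabidopsis_targets`).
#'
#' @return a list of class `paper_fixtures` with elements `table2`, `table4`,
#'   `table5` (data.frames) and `arabidopsis_targets` (character vector).
#' @export
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "ppredit", mustWork = TRUE)
  t2 <- read.delim(path("offtarget_table2.tsv"), stringsAsFactors = FALSE)
  t4 <- read.delim(path("offtarget_table4.tsv"), stringsAsFactors = FALSE)
  t5 <- read.delim(path("offtarget_table5.tsv"), stringsAsFactors = FALSE)
  at <- readLines(path("arabidopsis_targets.txt"))
  lib2 <- c("hpl6", "hpl1", "ubq3", "ubq1")
  stopifnot(all(t2$wt == 0),
            all(unlist(t2[c(lib2, "wt")]) >= 0),
            all(unlist(t2[c(lib2, "wt")]) <= 100),
            sum(t2$genome == "cp") == 32L,
            sum(t2$genome == "mt") == 1L)
  structure(list(table2 = t2, table4 = t4, table5 = t5,
                 arabidopsis_targets = at),
            class = "paper_fixtures")
}

#' Look up one editing percentage in a fixture matrix
#' @param tab fixture `data.frame` with a `site` column.
#' @param site site name, e.g. `"ndhB-291"`.
#' @param library column name of the line, e.g. `"ubq1"`.
#' @return numeric editing percentage.
#' @export
fixture_value <- function(tab, site, library) {
  i <- match(site, tab$site)
  if (is.na(i)) stop_data("unknown site: ", site)
  tab[[library]][i]
}
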