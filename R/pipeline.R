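#' Run the discovery pipeline end to end
#'
#' Chains the analysis stages in order: reference preparation (Y/R masking of
#' known sites, optional inverted-repeat collapse), read-pair selection and
#' alignment, strand-aware pileups, SNP calling, candidate filtering and
#' off-target discovery with wild-type subtraction. Intermediates and the
#' resolved configuration are written to `out_dir` so a run is fully
#' reproducible; identical configuration gives identical outputs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{genomes}{list of `organelle_genome` objects (unmasked).}
#'     \item{known_sites}{known editing-site `data.frame`, or `NULL`.}
#'     \item{ir}{optional list `(genome_id, start, end, flank)` for IR
#'       collapse.}
#'     \item{libraries}{named list: per library, a pairs `data.frame` (as
#'       from [simulate_reads()] or [read_fastq_pairs()]).}
#'     \item{wt_library}{name of the wild-type library in `libraries`.}
#'     \item{thresholds}{optional overrides: `min_rate`, `min_coverage`,
#'       `wt_cutoff`, `threshold`, `min_len`, `min_identity`,
#'       `min_read_cov`.}
#'     \item{collapse_duplicates}{discovery-mode read collapsing (default
#'       TRUE).}
#'   }
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list with `offtargets` (discovery table), `snps` (per-library
#'   filtered SNP tables), `pileups`, and `genomes` (the masked references).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  th <- config$thresholds %||% list()
  min_rate <- th$min_rate %||% 0.05
  min_coverage <- th$min_coverage %||% 20L
  wt_cutoff <- th$wt_cutoff %||% 1
  threshold <- th$threshold %||% 5
  min_len <- th$min_len %||% 100L
  min_identity <- th$min_identity %||% 0.85
  min_read_cov <- th$min_read_cov %||% 0.5
  # quantification-grade efficiencies need uncollapsed read counts; identical-
  # read collapsing (discovery mode) is exposed via config$collapse_duplicates
  collapse <- config$collapse_duplicates %||% FALSE

  genomes <- config$genomes
  if (inherits(genomes, "organelle_genome")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")

  # stage 1: reference preparation
  if (!is.null(config$ir)) {
    ir <- config$ir
    genomes[[ir$genome_id]] <- collapse_inverted_repeat(
      genomes[[ir$genome_id]], ir$start, ir$end, ir$flank %||% 75L)
  }
  if (!is.null(config$known_sites)) {
    genomes <- lapply(genomes, mask_known_sites, sites = config$known_sites)
  }
  indexes <- lapply(genomes, genome_index)

  # stage 2+3: per-library mapping, pileup, SNP calling, filtering
  wt_name <- config$wt_library
  lib_names <- names(config$libraries)
  snps <- list(); pileups <- list()
  for (lib in lib_names) {
    sel <- select_organellar_pairs(config$libraries[[lib]], indexes,
                                   min_len = min_len,
                                   min_identity = min_identity,
                                   min_read_cov = min_read_cov)
    lib_snps <- list()
    for (gid in names(genomes)) {
      pu <- build_pileup(sel$alignments, genomes[[gid]],
                         collapse_duplicates = collapse,
                         min_identity = min_identity)
      pileups[[paste(lib, gid, sep = ".")]] <- pu
      lib_snps[[gid]] <- call_snps(pu, genomes[[gid]],
                                   min_rate = min_rate,
                                   min_coverage = min_coverage)
    }
    raw <- do.call(rbind, lib_snps)
    feats <- do.call(rbind, lapply(genomes, `[[`, "features"))
    snps[[lib]] <- filter_candidates(raw, config$known_sites, feats)
  }

  # stage 4: discovery with wild-type subtraction
  mut <- snps[setdiff(lib_names, wt_name)]
  wt <- if (!is.null(wt_name)) snps[[wt_name]] else NULL
  offtargets <- discover_offtargets(mut, wt, threshold = threshold,
                                    wt_cutoff = wt_cutoff)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (gid in names(genomes)) {
      write_genome_fasta(genomes[[gid]], file.path(out_dir, paste0(gid, ".masked.fasta")))
    }
    for (lib in lib_names) {
      write.table(snps[[lib]], file.path(out_dir, paste0(lib, ".snps.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (nm in names(pileups)) {
      write_pileup_tsv(pileups[[nm]], file.path(out_dir, paste0(nm, ".pileup.tsv")))
    }
    write.table(offtargets, file.path(out_dir, "offtargets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    resolved <- c(list(min_rate = min_rate, min_coverage = min_coverage,
                       wt_cutoff = wt_cutoff, threshold = threshold,
                       min_len = min_len, min_identity = min_identity,
                       min_read_cov = min_read_cov,
                       collapse_duplicates = collapse,
                       libraries = lib_names, wt_library = wt_name %||% ""))
    writeLines(paste(names(resolved),
                     vapply(resolved, function(x) paste(x, collapse = ","),
                            character(1)), sep = "\t"),
               file.path(out_dir, "resolved_config.tsv"))
  }
  list(offtargets = offtargets, snps = snps, pileups = pileups,
       genomes = genomes)
}
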