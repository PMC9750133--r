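#' Splice-junction reference for an intron-containing gene
#'
#' Three short references classify junction-spanning reads: the spliced form
#' (exon1-exon2 junction) and the two unspliced borders (exon1-intron and
#' intron-exon2). `junction` gives, for each sequence, the 1-based position
#' of the last base before the junction point.
#'
#' @param gene gene name.
#' @param spliced_seq,unspliced5_seq,unspliced3_seq DNA strings.
#' @param junction integer vector of length 3 (junction offsets in the same
#'   order), each interior to its sequence by at least `min_overhang`.
#' @param min_overhang minimum anchor on both sides of a junction for a read
#'   to count (default 10 nt).
#' @return object of class `junction_reference`.
#' @export
junction_reference <- function(gene, spliced_seq, unspliced5_seq,
                               unspliced3_seq, junction, min_overhang = 10L) {
  seqs <- c(spliced = spliced_seq, unspliced5 = unspliced5_seq,
            unspliced3 = unspliced3_seq)
  if (length(junction) != 3) stop_config("junction must have length 3")
  for (i in 1:3) {
    if (junction[i] < min_overhang ||
        nchar(seqs[i]) - junction[i] < min_overhang) {
      stop_config("junction point not interior to ", names(seqs)[i],
                  " by min_overhang")
    }
  }
  structure(list(gene = gene, seqs = seqs, junction = as.integer(junction),
                 min_overhang = as.integer(min_overhang)),
            class = "junction_reference")
}

#' Splice ratio from junction-spanning reads
#'
#' Each read is aligned against the spliced and the two unspliced junction
#' references; it counts as spliced (or unspliced) iff its best alignment
#' crosses the respective junction with at least `min_overhang` aligned
#' bases on both sides. A read counts at most once; a read whose best
#' spliced and unspliced hits tie in identity is discarded. Counts are
#' normalized to the total number of mapped organellar reads, and the splice
#' ratio is normalized spliced over normalized unspliced (the two borders
#' summed).
#'
#' @param reads character vector of read sequences.
#' @param junctions a [junction_reference()].
#' @param total_mapped total mapped organellar reads used for normalization.
#' @param min_identity minimum identity for a junction hit (default 0.85).
#' @return list of class `splice_counts`: `spliced`, `unspliced`,
#'   `total_mapped`, `norm_spliced`, `norm_unspliced`, `ratio` (`NA` and
#'   flagged `ratio_undefined` when unspliced = 0) and `fraction_spliced`.
#' @export
splice_ratio <- function(reads, junctions, total_mapped,
                         min_identity = 0.85) {
  if (total_mapped <= 0) stop_config("total_mapped must be positive")
  ov <- junctions$min_overhang
  idxs <- lapply(seq_along(junctions$seqs), function(i) {
    genome_index(organelle_genome(names(junctions$seqs)[i],
                                  junctions$seqs[[i]], circular = FALSE))
  })
  crosses <- function(a, i) {
    !is.null(a) &&
      a$gstart <= junctions$junction[i] - ov + 1L &&
      a$gstart + a$glen - 1L >= junctions$junction[i] + ov
  }
  spliced <- 0L; unspliced <- 0L
  for (rd in reads) {
    hits <- lapply(idxs, function(ix) align_core(rd, ix))
    sp_id <- if (!is.null(hits[[1]]) && hits[[1]]$identity >= min_identity &&
                 crosses(hits[[1]], 1)) hits[[1]]$identity else -Inf
    un_id <- -Inf
    for (i in 2:3) {
      if (!is.null(hits[[i]]) && hits[[i]]$identity >= min_identity &&
          crosses(hits[[i]], i)) {
        un_id <- max(un_id, hits[[i]]$identity)
      }
    }
    if (sp_id == -Inf && un_id == -Inf) next
    if (sp_id > un_id) spliced <- spliced + 1L
    else if (un_id > sp_id) unspliced <- unspliced + 1L
    # equal-identity spliced/unspliced hits: ambiguous, discarded
  }
  norm_sp <- spliced / total_mapped
  norm_un <- unspliced / total_mapped
  structure(list(spliced = spliced, unspliced = unspliced,
                 total_mapped = total_mapped,
                 norm_spliced = norm_sp, norm_unspliced = norm_un,
                 ratio = if (unspliced == 0) NA_real_ else norm_sp / norm_un,
                 ratio_undefined = unspliced == 0,
                 fraction_spliced = if (spliced + unspliced == 0) NA_real_
                                    else spliced / (spliced + unspliced)),
            class = "splice_counts")
}

#' Reads per kilobase of feature per million mapped reads
#'
#' @param mapped_reads reads mapped to the feature.
#' @param feature_length feature length in nt.
#' @param library_total total mapped (quality-filtered) reads in the library.
#' @return RPKM value, `1e9 * mapped_reads / (feature_length * library_total)`.
#' @export
rpkm <- function(mapped_reads, feature_length, library_total) {
  if (any(feature_length <= 0) || any(library_total <= 0)) {
    stop_config("feature_length and library_total must be positive")
  }
  1e9 * mapped_reads / (feature_length * library_total)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical Ct replicates are averaged per sample and gene;
#' `dCt = Ct(target) - Ct(reference)`, `ddCt = dCt(sample) -
#' dCt(calibrator)`, fold change `2^(-ddCt)`. With `calibrator = NULL` the
#' sample with the highest dCt (lowest expression) is used, so the minimum
#' fold change across samples is 1.
#'
#' @param ct `data.frame` with columns `sample`, `gene`, `ct` (one row per
#'   technical replicate).
#' @param target_gene,reference_gene gene names; every sample must carry
#'   both.
#' @param calibrator calibrator sample name or `NULL` for auto-selection.
#' @return `data.frame` with `sample`, `dct`, `ddct`, `fold`.
#' @export
relative_expression <- function(ct, target_gene, reference_gene,
                                calibrator = NULL) {
  samples <- unique(ct$sample)
  mean_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (length(v) == 0) stop_data("sample ", s, " has no Ct for gene ", g)
    mean(v)
  }
  dct <- vapply(samples, function(s) {
    mean_ct(s, target_gene) - mean_ct(s, reference_gene)
  }, numeric(1))
  if (is.null(calibrator)) calibrator <- samples[which.max(dct)]
  if (!calibrator %in% samples) stop_data("unknown calibrator sample")
  ddct <- dct - dct[match(calibrator, samples)]
  data.frame(sample = samples, dct = dct, ddct = ddct,
             fold = 2^(-ddct), row.names = NULL)
}
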