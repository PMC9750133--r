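#' PPR protein and code-table constructors
#'
#' An editing-type PLS PPR protein is an ordered array of motifs, each
#' contacting one nucleotide via the amino acids at its 5th and last position
#' (position 2 additionally in the three-amino-acid code variant). The code
#' table is configuration, not hard-coded truth: it is an editable TSV of
#' rules `(motif class, aa2, aa5, aa_last) -> preferred nucleotide set`, with
#' `"*"` as wildcard; combinations without a rule are not predictable
#' (`n.p.`).
#'
#' @param id protein identifier.
#' @param motifs `data.frame` with columns `index` (1..n, consecutive),
#'   `mclass` (P1, P2, L1, L2, LL, S1, S2, SS), optional `aa2`, `aa5`,
#'   `aa_last` (single-letter amino acids, NA when unknown).
#' @param cterm character vector, subset of `c("E1","E2","DYW")`.
#' @return an object of class `ppr_protein`.
#' @export
ppr_protein <- function(id, motifs, cterm = c("E1", "E2", "DYW")) {
  motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
  stopifnot(all(c("index", "mclass", "aa5", "aa_last") %in% names(motifs)))
  if (!identical(as.integer(motifs$index), seq_len(nrow(motifs)))) {
    stop_data("motif indices must be consecutive from 1")
  }
  if (is.null(motifs$aa2)) motifs$aa2 <- NA_character_
  structure(list(id = id, motifs = motifs, cterm = cterm),
            class = "ppr_protein")
}

#' @rdname ppr_protein
#' @param path TSV with columns `index`, `mclass`, `aa2`, `aa5`, `aa_last`.
#' @export
read_motif_table <- function(path, id = basename(path)) {
  ppr_protein(id, read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", "")))
}

#' Load a PPR code table
#'
#' With no argument, loads the packaged two-amino-acid code table (the three
#' rules stated for this factor's motifs plus the published generic two-aa
#' rules).
#'
#' @param path optional TSV path with columns `mclass`, `aa2`, `aa5`,
#'   `aa_last`, `nucleotides` (e.g. `"A"`, `"AU"`; RNA alphabet).
#' @return `data.frame` of class `ppr_code`.
#' @export
load_code_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ppr_code_two_aa.tsv", package = "ppredit",
                        mustWork = TRUE)
  }
  code <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mclass", "aa2", "aa5", "aa_last", "nucleotides") %in% names(code)))
  if (any(!nzchar(code$nucleotides))) stop_data("empty nucleotide set in code table")
  class(code) <- c("ppr_code", class(code))
  code
}

#' Predict the nucleotide preference of each PPR motif
#'
#' Pure rule lookup: for each motif, rules with a matching motif class take
#' precedence over wildcard-class rules; under `variant = "three_aa"` the
#' amino acid at position 2 must also match (wildcards allowed). Motifs with
#' no applicable rule (or unknown amino acids) are `"n.p."`.
#'
#' @param protein a [ppr_protein()].
#' @param code a code table from [load_code_table()].
#' @param variant `"two_aa"` (default) or `"three_aa"`.
#' @return character vector, one nucleotide-set string per motif (RNA
#'   alphabet, e.g. `"A"`, `"AU"`) or `"n.p."`.
#' @export
predict_binding <- function(protein, code, variant = c("two_aa", "three_aa")) {
  variant <- match.arg(variant)
  m <- protein$motifs
  vapply(seq_len(nrow(m)), function(i) {
    if (is.na(m$aa5[i]) || is.na(m$aa_last[i])) return("n.p.")
    hit <- code$aa5 == m$aa5[i] & code$aa_last == m$aa_last[i] &
      (code$mclass == "*" | code$mclass == m$mclass[i])
    if (variant == "three_aa") {
      hit <- hit & (code$aa2 == "*" |
                      (!is.na(m$aa2[i]) & code$aa2 == m$aa2[i]))
    }
    rules <- code[hit, , drop = FALSE]
    if (nrow(rules) == 0) return("n.p.")
    # class-specific rules beat wildcard rules; insertion order is irrelevant
    specific <- rules[rules$mclass != "*", , drop = FALSE]
    if (nrow(specific) > 0) specific$nucleotides[1] else rules$nucleotides[1]
  }, character(1))
}

#' Anchor a PPR motif array on a cis-element
#'
#' The last motif is aligned to position -4 relative to the edited cytidine
#' (position 0); motif `k` of `n` then faces position `-4 - (n - k)`. For a
#' 15-motif array the footprint is -18..-4.
#'
#' @param protein a [ppr_protein()].
#' @param anchor_offset cis position faced by the last motif (default -4).
#' @param window cis-element span as `c(min, max)` positions (default
#'   `c(-20, 5)`); an error is raised if the footprint leaves it.
#' @return named integer vector: motif index -> cis position.
#' @export
anchor_alignment <- function(protein, anchor_offset = -4L, window = c(-20L, 5L)) {
  n <- nrow(protein$motifs)
  if (n < 1) stop_data("protein has no motifs")
  pos <- anchor_offset - (n - seq_len(n))
  if (min(pos) < window[1] || max(pos) > window[2]) {
    stop_data("motif footprint extends beyond the cis window")
  }
  setNames(as.integer(pos), seq_len(n))
}

#' Cis-element around an editing site
#'
#' @param site_name site label, e.g. `"ndhB-291"`.
#' @param sequence 26-nt sequence covering positions -20..+5 around the
#'   edited C (position 0); DNA input is converted to RNA.
#' @param span positions covered, `c(-20, 5)` by default.
#' @return object of class `cis_element` (RNA string plus coordinates).
#' @export
cis_element <- function(site_name, sequence, span = c(-20L, 5L)) {
  sequence <- dna_to_rna(sequence)
  expected <- span[2] - span[1] + 1L
  if (nchar(sequence) != expected) {
    stop_data(sprintf("cis element %s: expected %d nt, got %d",
                      site_name, expected, nchar(sequence)))
  }
  zero <- 1L - span[1]
  if (substr(sequence, zero, zero) != "C") {
    stop_data(sprintf("cis element %s: base at position 0 is not C", site_name))
  }
  structure(list(site_name = site_name, sequence = sequence, span = span,
                 edit_index = zero),
            class = "cis_element")
}

cis_base_at <- function(cis, pos) {
  i <- pos - cis$span[1] + 1L
  substr(cis$sequence, i, i)
}

#' Score a cis-element against a PPR binding prediction
#'
#' Every cis position faced by a motif is scored `match` if the observed base
#' is in the predicted set, `mismatch` otherwise; positions faced by an
#' `n.p.` motif score `n.p.`; positions outside the motif footprint are
#' `unaligned`. Only `mismatch` verdicts count towards the total.
#'
#' @param cis a [cis_element()].
#' @param prediction per-motif nucleotide sets from [predict_binding()].
#' @param anchoring motif-to-position map from [anchor_alignment()].
#' @return list of class `scorecard`: `site_name`, per-position `verdicts`
#'   `data.frame` (`position`, `motif`, `base`, `predicted`, `verdict`),
#'   `total_mismatches`, and `n_evaluable` (positions with a prediction).
#' @export
score_cis_element <- function(cis, prediction, anchoring) {
  pos_all <- cis$span[1]:cis$span[2]
  motif_of <- setNames(rep(NA_integer_, length(pos_all)), pos_all)
  motif_of[as.character(anchoring)] <- as.integer(names(anchoring))
  rows <- lapply(pos_all, function(p) {
    mi <- motif_of[[as.character(p)]]
    b <- cis_base_at(cis, p)
    if (is.na(mi)) {
      return(data.frame(position = p, motif = NA_integer_, base = b,
                        predicted = NA_character_, verdict = "unaligned",
                        stringsAsFactors = FALSE))
    }
    pred <- prediction[mi]
    verdict <- if (pred == "n.p.") "n.p."
               else if (grepl(b, pred, fixed = TRUE)) "match"
               else "mismatch"
    data.frame(position = p, motif = mi, base = b, predicted = pred,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  structure(list(site_name = cis$site_name, verdicts = verdicts,
                 total_mismatches = sum(verdicts$verdict == "mismatch"),
                 n_evaluable = sum(verdicts$verdict %in% c("match", "mismatch"))),
            class = "scorecard")
}

#' Score a set of cis-elements and tabulate marginals
#'
#' @param elements list of [cis_element()]s.
#' @param protein a [ppr_protein()].
#' @param code a code table.
#' @param variant passed to [predict_binding()].
#' @return list with `verdicts` (site x motif verdict matrix),
#'   `per_site_mismatches`, `per_motif_mismatches` and `scorecards`.
#' @export
score_cis_set <- function(elements, protein, code, variant = "two_aa") {
  pred <- predict_binding(protein, code, variant)
  anch <- anchor_alignment(protein)
  cards <- lapply(elements, score_cis_element, prediction = pred,
                  anchoring = anch)
  vmat <- t(vapply(cards, function(sc) {
    v <- sc$verdicts
    v$verdict[!is.na(v$motif)][order(v$motif[!is.na(v$motif)])]
  }, character(nrow(protein$motifs))))
  rownames(vmat) <- vapply(cards, `[[`, character(1), "site_name")
  colnames(vmat) <- seq_len(ncol(vmat))
  list(verdicts = vmat,
       per_site_mismatches = rowSums(vmat == "mismatch"),
       per_motif_mismatches = colSums(vmat == "mismatch"),
       scorecards = cards)
}

#' Per-position base frequency matrix of aligned windows
#'
#' @param seqs character vector of equal-length RNA/DNA sequences, anchored
#'   at the same position.
#' @param span positions covered by the sequences, e.g. `c(-30, 10)`.
#' @return list with `counts` and `freq` (4 x width matrices, rows
#'   `A,C,G,U`); frequency columns sum to 1.
#' @export
frequency_matrix <- function(seqs, span) {
  seqs <- dna_to_rna(seqs)
  width <- span[2] - span[1] + 1L
  if (any(nchar(seqs) != width)) stop_data("sequences do not cover the span")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("A", "C", "G", "U")
  counts <- vapply(seq_len(width), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.integer(tab)
  }, integer(4))
  dimnames(counts) <- list(bases, span[1]:span[2])
  freq <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  list(counts = counts, freq = freq)
}

# IUPAC code for a set of RNA bases
iupac_code <- function(bases) {
  if (length(bases) == 0) return("N")
  key <- paste(sort(rna_to_dna(bases)), collapse = "")
  hit <- names(Biostrings::IUPAC_CODE_MAP)[
    vapply(Biostrings::IUPAC_CODE_MAP, function(x) {
      paste(sort(strsplit(x, "")[[1]]), collapse = "") == key
    }, logical(1))]
  if (length(hit) == 0) "N" else hit[1]
}

#' Degenerate IUPAC consensus from a frequency matrix
#'
#' Per position, the IUPAC code of the base set whose frequency reaches
#' `include_threshold`; an empty set yields `N`. Position 0 (the edited C) is
#' fixed to `C` when it lies in the span.
#'
#' @param freqs result of [frequency_matrix()].
#' @param include_threshold inclusion threshold in (0, 1).
#' @return IUPAC consensus string.
#' @export
degenerate_consensus <- function(freqs, include_threshold = 0.2) {
  stopifnot(include_threshold > 0, include_threshold < 1)
  f <- freqs$freq
  cons <- vapply(seq_len(ncol(f)), function(j) {
    iupac_code(rownames(f)[f[, j] >= include_threshold])
  }, character(1))
  zero <- match("0", colnames(f))
  if (!is.na(zero)) cons[zero] <- "C"
  paste(cons, collapse = "")
}
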