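#' Aligned context windows around editing sites
#'
#' Ungapped windows of equal length anchored at the edited cytidine
#' (position 0), by default spanning -50..+50 (101 nt).
#'
#' @param site_names character vector of site labels.
#' @param seqs character vector of equal-length sequences (DNA or RNA; kept
#'   as given, compared case-insensitively).
#' @param span positions covered, default `c(-50, 50)`.
#' @param check_anchor require a C at position 0 (default TRUE).
#' @return object of class `context_window_set`.
#' @export
context_window_set <- function(site_names, seqs, span = c(-50L, 50L),
                               check_anchor = TRUE) {
  width <- span[2] - span[1] + 1L
  seqs <- toupper(rna_to_dna(seqs))
  if (any(nchar(seqs) != width)) {
    stop_data("all windows must cover the full span (", width, " nt)")
  }
  zero <- 1L - span[1]
  if (check_anchor && any(substr(seqs, zero, zero) != "C")) {
    stop_data("anchor base at position 0 must be C in every window")
  }
  structure(list(site_names = site_names, seqs = seqs, span = span),
            class = "context_window_set")
}

#' Windowed mean pairwise sequence similarity
#'
#' For every placement of a sliding window of `window` nt (step 1), computes
#' the mean over all unordered sequence pairs of the fraction of identical
#' positions within the window. The editing site itself (position 0,
#' exclusion `"C"`) or positions -1..+1 (exclusion `"nCn"`) are removed from
#' both numerator and denominator, so guaranteed matches at the anchored C do
#' not inflate the profile. Ambiguity codes (`N`) never count as identical.
#' Values are reported at the window's left-edge position.
#'
#' @param windows a [context_window_set()] with at least two sequences.
#' @param window window width in nt (default 14).
#' @param exclusion `"C"` (exclude position 0) or `"nCn"` (exclude -1..+1).
#' @return `data.frame` with `position` (left edge), `similarity` (in
#'   `[0,1]`, `NA` when no evaluable position remains) and `n_evaluable`.
#' @export
similarity_profile <- function(windows, window = 14L, exclusion = c("C", "nCn")) {
  exclusion <- match.arg(exclusion)
  seqs <- windows$seqs
  n <- length(seqs)
  if (n < 2) stop_data("similarity profile needs at least two sequences")
  span <- windows$span
  width <- span[2] - span[1] + 1L
  if (window > width) stop_data("window wider than the aligned span")
  excl_pos <- if (exclusion == "C") 0L else -1L:1L
  excl_idx <- excl_pos - span[1] + 1L
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  # pairwise identity indicator per column, N never identical
  pair_idx <- utils::combn(n, 2)
  ident <- matrix(FALSE, nrow = ncol(pair_idx), ncol = width)
  for (p in seq_len(ncol(pair_idx))) {
    a <- mat[pair_idx[1, p], ]; b <- mat[pair_idx[2, p], ]
    ident[p, ] <- a == b & a != "N" & b != "N"
  }
  evaluable <- setdiff(seq_len(width), excl_idx)
  starts <- seq_len(width - window + 1L)
  sim <- vapply(starts, function(s) {
    cols <- intersect(s:(s + window - 1L), evaluable)
    if (length(cols) == 0) return(NA_real_)
    mean(rowSums(ident[, cols, drop = FALSE]) / length(cols))
  }, numeric(1))
  n_eval <- vapply(starts, function(s) {
    length(intersect(s:(s + window - 1L), evaluable))
  }, integer(1))
  data.frame(position = starts + span[1] - 1L, similarity = sim,
             n_evaluable = n_eval)
}

#' Base composition at fixed offsets from the editing site
#'
#' @param windows a [context_window_set()].
#' @param offsets integer offsets relative to position 0, e.g. `c(-1, 1)`.
#' @return `data.frame` with `offset`, `base`, `count` and `fraction`.
#' @export
flank_composition <- function(windows, offsets = c(-1L, 1L)) {
  if (length(offsets) == 0) {
    return(data.frame(offset = integer(), base = character(),
                      count = integer(), fraction = numeric()))
  }
  span <- windows$span
  if (any(offsets < span[1] | offsets > span[2])) {
    stop_data("offset outside the aligned span")
  }
  bases <- c("A", "C", "G", "T")
  out <- lapply(offsets, function(off) {
    i <- off - span[1] + 1L
    obs <- substr(windows$seqs, i, i)
    tab <- table(factor(obs, levels = bases))
    data.frame(offset = off, base = bases, count = as.integer(tab),
               fraction = as.integer(tab) / length(obs))
  })
  do.call(rbind, out)
}
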