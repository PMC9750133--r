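#' Build a k-mer index over a reference genome
#'
#' The built-in aligner is a k-mer seed + ungapped extension aligner:
#' substitution-only, deterministic, and small enough to be checked against a
#' brute-force edit-distance oracle. Indels are not modeled (the editing
#' signal is purely substitutional). Masked Y/R bases match both of their
#' constituent bases without penalty.
#'
#' @param genome an `organelle_genome`.
#' @param k seed length (default 15).
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 15L) {
  L <- genome_length(genome)
  chars <- seq_chars(genome$sequence)
  kmap <- new.env(hash = TRUE, parent = emptyenv(), size = max(16L, L))
  if (L >= k) {
    starts <- seq_len(L - k + 1L)
    kmers <- substring(genome$sequence, starts, starts + k - 1L)
    for (i in starts) {
      km <- kmers[i]
      kmap[[km]] <- c(kmap[[km]], i)
    }
  }
  structure(list(genome = genome, k = as.integer(k), chars = chars, kmap = kmap),
            class = "genome_index")
}

as_index <- function(x, k = 15L) {
  if (inherits(x, "genome_index")) x else genome_index(x, k = k)
}

# evaluate one candidate placement of a plus-orientation read sequence
eval_candidate <- function(idx, rchars, start) {
  L <- length(idx$chars)
  rl <- length(rchars)
  g1 <- max(1L, start)
  g2 <- min(L, start + rl - 1L)
  if (g2 < g1) return(NULL)
  roff <- (g1 - start + 1L):(g2 - start + 1L)
  m <- ref_base_match(idx$chars[g1:g2], rchars[roff])
  list(start = start, gstart = g1, glen = g2 - g1 + 1L,
       matches = sum(m), aligned_length = g2 - g1 + 1L)
}

#' Align a read against a reference with the built-in aligner
#'
#' Seeds of length `k` are taken every `seed_step` bases along the read (plus
#' a final seed flush with the read end) and looked up exactly in the genome
#' index; each seed hit proposes an ungapped placement which is scored over
#' the overlapping region. Both the read and its reverse complement are
#' tried. The best alignment maximizes identity (matches / aligned length);
#' ties are broken by leftmost start, then plus strand. Equal-best placements
#' at more than one locus are flagged as multi-mapping.
#'
#' @param read a DNA string.
#' @param index a `genome_index` (or an `organelle_genome`, indexed on the
#'   fly).
#' @param seed_step distance between seed offsets (default: seed length).
#' @return a one-row `data.frame` (`start`, `strand`, `identity`,
#'   `aligned_fraction`, `gstart`, `glen`, `plus_seq`, `multi`) or `NULL`
#'   when no seed hits.
#' @export
align_read <- function(read, index, seed_step = NULL) {
  best <- align_core(read, as_index(index), seed_step)
  if (is.null(best)) return(NULL)
  data.frame(start = best$start, strand = best$strand,
             identity = best$identity,
             aligned_fraction = best$aligned_fraction,
             gstart = best$gstart, glen = best$glen,
             plus_seq = best$plus_seq,
             multi = best$multi, stringsAsFactors = FALSE)
}

# fast single-string reverse complement (ACGT + masking codes)
revcomp1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTYRN", "TGCARYN", x))))
}

align_core <- function(read, idx, seed_step = NULL) {
  k <- idx$k
  rl <- nchar(read)
  if (rl == 0) stop_data("empty read")
  if (is.null(seed_step)) seed_step <- k
  orientations <- list(`+` = read, `-` = revcomp1(read))
  best <- NULL
  best_starts <- integer(0)   # distinct loci achieving the best identity
  for (strand in c("+", "-")) {
    rseq <- orientations[[strand]]
    rchars <- seq_chars(rseq)
    if (rl < k) next
    offs <- unique(c(seq(1L, rl - k + 1L, by = seed_step), rl - k + 1L))
    kmers <- substring(rseq, offs, offs + k - 1L)
    cand <- integer(0)
    for (j in seq_along(offs)) {
      hits <- idx$kmap[[kmers[j]]]
      if (!is.null(hits)) cand <- c(cand, hits - offs[j] + 1L)
    }
    cand <- unique(cand)
    for (s in cand) {
      ev <- eval_candidate(idx, rchars, s)
      if (is.null(ev)) next
      identity <- ev$matches / ev$aligned_length
      as_best <- list(start = ev$start, strand = strand, identity = identity,
                      aligned_fraction = ev$aligned_length / rl,
                      gstart = ev$gstart, glen = ev$glen,
                      plus_seq = substr(rseq, ev$gstart - ev$start + 1L,
                                        ev$gstart - ev$start + ev$glen))
      if (is.null(best) || identity > best$identity + 1e-12) {
        best <- as_best
        best_starts <- ev$start
      } else if (abs(identity - best$identity) <= 1e-12) {
        best_starts <- union(best_starts, ev$start)
        # tie-break: leftmost start, then plus strand
        if (ev$start < best$start ||
            (ev$start == best$start && strand == "+" && best$strand == "-")) {
          best <- as_best
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$multi <- length(best_starts) > 1L
  best
}

#' Select organellar read pairs
#'
#' Applies the pair-selection rule used for organellar transcript enrichment:
#' a pair is kept iff both mates are strictly longer than `min_len` and at
#' least one mate aligns to one of the references with identity >=
#' `min_identity` over more than `min_read_cov` of its length.
#'
#' @param pairs `data.frame` with `id`, `mate1_seq`, `mate2_seq`.
#' @param indexes a single `genome_index` or a list of them (one per
#'   reference genome).
#' @param min_len minimum mate length, exclusive (default 100 nt).
#' @param min_identity minimum alignment identity (default 0.85).
#' @param min_read_cov minimum aligned fraction of the read, exclusive
#'   (default 0.5).
#' @return a list with `pairs` (the selected subset) and `alignments`
#'   (per-mate best alignments of the selected pairs, with the inferred
#'   fragment strand: mate 1 carries the transcript sense).
#' @export
select_organellar_pairs <- function(pairs, indexes, min_len = 100L,
                                    min_identity = 0.85, min_read_cov = 0.5) {
  if (inherits(indexes, "genome_index")) indexes <- list(indexes)
  indexes <- lapply(indexes, as_index)
  n <- nrow(pairs)
  keep <- logical(n)
  # preallocated alignment columns (at most two mates per pair)
  cap <- 2L * n
  c_start <- integer(cap); c_strand <- character(cap)
  c_ident <- numeric(cap); c_frac <- numeric(cap)
  c_gstart <- integer(cap); c_glen <- integer(cap)
  c_pseq <- character(cap); c_multi <- logical(cap)
  c_gid <- character(cap); c_rid <- character(cap)
  c_mate <- integer(cap); c_rseq <- character(cap); c_fstr <- character(cap)
  c_keeprow <- logical(cap)
  m <- 0L
  for (i in seq_len(n)) {
    if (nchar(pairs$mate1_seq[i]) <= min_len || nchar(pairs$mate2_seq[i]) <= min_len) next
    ok <- FALSE
    m0 <- m
    for (mate in 1:2) {
      rd <- if (mate == 1) pairs$mate1_seq[i] else pairs$mate2_seq[i]
      best <- NULL; best_gid <- NA_character_
      for (idx in indexes) {
        a <- align_core(rd, idx)
        if (!is.null(a) && (is.null(best) || a$identity > best$identity)) {
          best <- a
          best_gid <- idx$genome$id
        }
      }
      if (!is.null(best)) {
        m <- m + 1L
        c_start[m] <- best$start; c_strand[m] <- best$strand
        c_ident[m] <- best$identity; c_frac[m] <- best$aligned_fraction
        c_gstart[m] <- best$gstart; c_glen[m] <- best$glen
        c_pseq[m] <- best$plus_seq; c_multi[m] <- best$multi
        c_gid[m] <- best_gid; c_rid[m] <- pairs$id[i]
        c_mate[m] <- mate; c_rseq[m] <- rd
        # fragment (transcript) strand: mate1 = alignment strand, mate2 = flip
        c_fstr[m] <- if (mate == 1) best$strand
                     else if (best$strand == "+") "-" else "+"
        if (best$identity >= min_identity && best$aligned_fraction > min_read_cov) {
          ok <- TRUE
        }
      }
    }
    if (ok) {
      keep[i] <- TRUE
      if (m > m0) c_keeprow[(m0 + 1L):m] <- TRUE
    }
  }
  sel <- which(c_keeprow[seq_len(m)])
  alignments <- data.frame(
    start = c_start[sel], strand = c_strand[sel], identity = c_ident[sel],
    aligned_fraction = c_frac[sel], gstart = c_gstart[sel],
    glen = c_glen[sel], plus_seq = c_pseq[sel], multi = c_multi[sel],
    genome_id = c_gid[sel], read_id = c_rid[sel], mate = c_mate[sel],
    read_seq = c_rseq[sel], frag_strand = c_fstr[sel],
    stringsAsFactors = FALSE)
  list(pairs = pairs[keep, , drop = FALSE], alignments = alignments)
}

#' Build a strand-aware pileup from alignments
#'
#' Counts aligned bases per genome position, in plus-strand orientation,
#' separately for the two inferred transcript strands. In discovery mode
#' (`collapse_duplicates = TRUE`) identical read sequences are counted once
#' per mate, mirroring read collapsing before site discovery; quantification
#' uses uncollapsed reads. Multi-mapping reads (equal best score at more than
#' one locus) are discarded.
#'
#' @param alignments alignment `data.frame` from [select_organellar_pairs()].
#' @param genome the `organelle_genome` the alignments refer to.
#' @param collapse_duplicates logical; collapse identical read sequences.
#' @param min_identity alignments below this identity do not contribute
#'   (default 0.85).
#' @return an object of class `pileup`: a list with `genome_id` and `counts`,
#'   an `L x 8` integer matrix with columns `A+,C+,G+,T+,A-,C-,G-,T-` (base
#'   in plus orientation x transcript strand).
#' @export
build_pileup <- function(alignments, genome, collapse_duplicates = FALSE,
                         min_identity = 0.85) {
  aln <- alignments[alignments$genome_id == genome$id &
                      !alignments$multi &
                      alignments$identity >= min_identity, , drop = FALSE]
  if (collapse_duplicates && nrow(aln) > 0) {
    aln <- aln[!duplicated(paste(aln$mate, aln$read_seq)), , drop = FALSE]
  }
  L <- genome_length(genome)
  counts <- matrix(0L, nrow = L, ncol = 8,
                   dimnames = list(NULL, c("A+", "C+", "G+", "T+",
                                           "A-", "C-", "G-", "T-")))
  base_col <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(nrow(aln))) {
    bases <- seq_chars(aln$plus_seq[i])
    pos <- aln$gstart[i]:(aln$gstart[i] + aln$glen[i] - 1L)
    col <- base_col[bases]
    if (aln$frag_strand[i] == "-") col <- col + 4L
    ok <- !is.na(col)   # sequencing Ns etc. are dropped
    idx <- cbind(pos[ok], col[ok])
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(genome_id = genome$id, counts = counts), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cov <- rowSums(x$counts)
  cat(sprintf("<pileup> %s: %d positions, %d covered, max coverage %d\n",
              x$genome_id, length(cov), sum(cov > 0), max(cov, 0)))
  invisible(x)
}

#' Convert a pileup to a per-position data.frame
#' @param x a `pileup`.
#' @param ... unused.
#' @return `data.frame` with `genome_id`, `position`, the eight strand-aware
#'   base counts and `coverage`; zero-coverage positions are dropped.
#' @export
as.data.frame.pileup <- function(x, ...) {
  cov <- rowSums(x$counts)
  keep <- which(cov > 0)
  out <- data.frame(genome_id = x$genome_id, position = keep,
                    stringsAsFactors = FALSE)
  cnt <- as.data.frame(x$counts[keep, , drop = FALSE], check.names = FALSE)
  cbind(out, cnt, coverage = cov[keep])
}

#' Write / read a pileup TSV
#' @param pileup a `pileup` object.
#' @param path file path.
#' @name pileup_io
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(as.data.frame(pileup), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
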