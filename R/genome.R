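#' Annotated organellar genome
#'
#' A light container for a (typically circular) plastid or mitochondrial
#' reference: an IUPAC DNA sequence plus a feature table. Known editing sites
#' may later be masked to Y/R with [mask_known_sites()], so the accepted
#' alphabet is `A,C,G,T,Y,R,N`.
#'
#' @param id genome identifier, e.g. `"cp"` or `"mt"`.
#' @param sequence a single DNA string.
#' @param circular logical; is the molecule circular?
#' @param features `data.frame` with columns `name`, `ftype` (one of `CDS`,
#'   `intron`, `tRNA`, `rRNA`, `UTR5`, `UTR3`, `intergenic`, `IR`), `start`,
#'   `end` (1-based inclusive) and `strand` (`"+"`/`"-"`).
#' @return an object of class `organelle_genome`.
#' @export
organelle_genome <- function(id, sequence, circular = TRUE, features = NULL) {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(seq_chars(sequence)), REF_ALPHABET)
  if (length(bad) > 0) {
    stop_data("sequence contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  }
  if (is.null(features)) {
    features <- data.frame(name = character(), ftype = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0) {
    stopifnot(all(c("name", "ftype", "start", "end", "strand") %in% names(features)))
    if (any(features$start > features$end)) {
      stop_data("feature start must be <= end")
    }
    if (any(features$start < 1 | features$end > nchar(sequence))) {
      stop_data("feature interval outside [1, genome length]")
    }
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "organelle_genome")
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat(sprintf("<organelle_genome> %s: %d nt, %s, %d feature(s)\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Genome length in nucleotides
#' @param genome an `organelle_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Mask known editing sites with IUPAC ambiguity codes
#'
#' Replaces every known editing position by `Y` (C or T) when the edited
#' transcript is on the plus strand, or `R` (A or G) when it is on the minus
#' strand (where the genomic plus-strand base is a G). Mapping against the
#' masked reference is then unbiased with respect to the editing status of a
#' read. The operation is idempotent, and [unmask_known_sites()] inverts it.
#'
#' @param genome an `organelle_genome`.
#' @param sites `data.frame` with columns `genome_id`, `position` (1-based),
#'   `strand` (transcript strand, `"+"`/`"-"`) and `name`.
#' @return the genome with masked positions.
#' @export
mask_known_sites <- function(genome, sites) {
  sites <- sites[sites$genome_id == genome$id, , drop = FALSE]
  if (nrow(sites) == 0) return(genome)
  chars <- seq_chars(genome$sequence)
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    b <- chars[p]
    if (sites$strand[i] == "+") {
      if (!b %in% c("C", "Y")) {
        stop_data(sprintf("site %s: base at %d is %s, expected C on + strand",
                          sites$name[i], p, b))
      }
      chars[p] <- "Y"
    } else {
      if (!b %in% c("G", "R")) {
        stop_data(sprintf("site %s: base at %d is %s, expected G (plus-strand) for a - strand site",
                          sites$name[i], p, b))
      }
      chars[p] <- "R"
    }
  }
  genome$sequence <- paste(chars, collapse = "")
  genome
}

#' Undo Y/R masking of known editing sites
#'
#' @inheritParams mask_known_sites
#' @return the genome with `Y` restored to `C` and `R` to `G` at the listed
#'   positions.
#' @export
unmask_known_sites <- function(genome, sites) {
  sites <- sites[sites$genome_id == genome$id, , drop = FALSE]
  if (nrow(sites) == 0) return(genome)
  chars <- seq_chars(genome$sequence)
  chars[sites$position] <- unmask_base(chars[sites$position])
  genome$sequence <- paste(chars, collapse = "")
  genome
}

#' Collapse the second copy of the plastid inverted repeat
#'
#' Removes the interior of the given IR copy, retaining `flank` nucleotides
#' from both the 5' and the 3' border so that reads spanning the IR junctions
#' still map. Features downstream of the removed block are shifted; features
#' straddling a border are truncated and flagged in a `truncated` column.
#'
#' @param genome an `organelle_genome`.
#' @param ir_start,ir_end 1-based inclusive coordinates of the IR copy to
#'   collapse; both `NULL` leaves the genome unchanged.
#' @param flank nucleotides to retain at each IR border (default 75).
#' @return the collapsed genome.
#' @export
collapse_inverted_repeat <- function(genome, ir_start = NULL, ir_end = NULL,
                                     flank = 75) {
  if (is.null(ir_start) || is.null(ir_end)) return(genome)
  L <- genome_length(genome)
  if (ir_start < 1 || ir_end > L || ir_start > ir_end) {
    stop_config("invalid IR interval")
  }
  ir_len <- ir_end - ir_start + 1
  if (ir_len < 2 * flank) {
    stop_config(sprintf("IR (%d nt) shorter than 2*flank (%d nt)", ir_len, 2 * flank))
  }
  # removed block: everything between the retained 5' and 3' borders
  rm_start <- ir_start + flank
  rm_end <- ir_end - flank
  rm_len <- rm_end - rm_start + 1
  if (rm_len <= 0) return(genome)
  genome$sequence <- paste0(substr(genome$sequence, 1, rm_start - 1),
                            substr(genome$sequence, rm_end + 1, L))
  feats <- genome$features
  if (nrow(feats) > 0) {
    feats$truncated <- FALSE
    keep <- rep(TRUE, nrow(feats))
    for (i in seq_len(nrow(feats))) {
      s <- feats$start[i]; e <- feats$end[i]
      if (e < rm_start) {
        # untouched
      } else if (s > rm_end) {
        feats$start[i] <- s - rm_len
        feats$end[i] <- e - rm_len
      } else if (s >= rm_start && e <= rm_end) {
        keep[i] <- FALSE               # feature entirely inside the removed block
      } else {
        # straddles a border: truncate to the retained part(s) and flag
        feats$truncated[i] <- TRUE
        if (s < rm_start && e <= rm_end) {
          feats$end[i] <- rm_start - 1
        } else if (s >= rm_start && e > rm_end) {
          feats$start[i] <- rm_start
          feats$end[i] <- e - rm_len
        } else { # spans the whole removed block
          feats$end[i] <- e - rm_len
        }
      }
    }
    genome$features <- feats[keep, , drop = FALSE]
  }
  genome
}

#' Read and write genomes and annotations
#'
#' `write_genome_fasta()`/`read_genome_fasta()` use Biostrings FASTA I/O;
#' `write_features_gff3()`/`read_features_gff3()` round-trip the feature table
#' through rtracklayer; `write_sites_bed()`/`read_sites_bed()` store known
#' editing sites as 6-column BED (0-based half-open converted at the I/O
#' boundary; all in-memory coordinates are 1-based inclusive).
#'
#' @param genome an `organelle_genome`.
#' @param path file path.
#' @name genome_io
NULL

#' @rdname genome_io
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname genome_io
#' @param circular logical flag for the imported genome.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  organelle_genome(id = sub("\\s.*$", "", names(x)[1]),
                   sequence = as.character(x[[1]]),
                   circular = circular)
}

#' @rdname genome_io
#' @export
write_features_gff3 <- function(genome, path) {
  feats <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- feats$ftype
  S4Vectors::mcols(gr)$ID <- feats$name
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  data.frame(name = as.character(S4Vectors::mcols(gr)$ID),
             ftype = as.character(S4Vectors::mcols(gr)$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname genome_io
#' @param sites known-sites `data.frame` (`genome_id`, `position`, `strand`,
#'   `name`).
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$genome_id,
                    start = sites$position - 1L,  # BED is 0-based half-open
                    end = sites$position,
                    name = sites$name,
                    score = 0L,
                    strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_sites_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(genome_id = bed[[1]], position = bed[[3]],
             strand = bed[[6]], name = bed[[4]], stringsAsFactors = FALSE)
}
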