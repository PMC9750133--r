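#' @importFrom stats rnorm runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

# IUPAC bases accepted in reference sequences (Y/R arise from editing-site masking)
REF_ALPHABET <- c("A", "C", "G", "T", "Y", "R", "N")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps the
#' character-vector interface used throughout the package. IUPAC ambiguity
#' codes (including the Y/R masking codes) are complemented correctly.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# vectorised base match against a (possibly masked) reference character vector:
# Y matches C/T, R matches A/G, N matches anything
ref_base_match <- function(ref, obs) {
  (ref == obs) |
    (ref == "Y" & (obs == "C" | obs == "T")) |
    (ref == "R" & (obs == "A" | obs == "G")) |
    (ref == "N")
}

# unmasked identity of a reference base (Y was a C, R was a G before masking)
unmask_base <- function(b) {
  out <- b
  out[b == "Y"] <- "C"
  out[b == "R"] <- "G"
  out
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# convert DNA -> RNA alphabet (used by the cis-element logic)
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

stop_config <- function(...) stop(..., call. = FALSE)
stop_data <- function(...) stop(..., call. = FALSE)
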