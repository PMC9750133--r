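#' Load editing-site allele k-mer pairs
#'
#' Each editing site is genotyped across species by exact matching of a
#' 31-mer centered on the site, in its genomic C and pre-edited T version
#' (the site base at 0-based offset 15). The packaged table carries the
#' three printed pairs (matK-214, rpoB-811, ndhB-291).
#'
#' @param path optional TSV with columns `site`, `kmer_c`, `kmer_t`.
#' @return validated `data.frame` of k-mer pairs.
#' @export
load_allele_kmers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "allele_kmers.tsv", package = "ppredit",
                        mustWork = TRUE)
  }
  km <- read.delim(path, stringsAsFactors = FALSE)
  validate_kmer_pair(km)
  km
}

validate_kmer_pair <- function(km) {
  stopifnot(all(c("site", "kmer_c", "kmer_t") %in% names(km)))
  for (i in seq_len(nrow(km))) {
    kc <- toupper(km$kmer_c[i]); kt <- toupper(km$kmer_t[i])
    if (nchar(kc) != 31 || nchar(kt) != 31) {
      stop_config("k-mers for ", km$site[i], " must be 31 nt")
    }
    diff <- which(seq_chars(kc) != seq_chars(kt))
    if (!identical(diff, 16L)) {
      stop_config("k-mer pair for ", km$site[i],
                  " must differ exactly at the central position")
    }
    if (substr(kc, 16, 16) != "C" || substr(kt, 16, 16) != "T") {
      stop_config("central bases for ", km$site[i], " must be C and T")
    }
  }
  invisible(km)
}

#' Genotype editing-site alleles by exact 31-mer search
#'
#' Searches each sequence for the C and T versions of each site's 31-mer on
#' both strands (the reverse complement of each k-mer is also searched). A
#' sequence matching both versions (e.g. a tandem duplication with mixed
#' alleles) is flagged `ambiguous`, never silently resolved.
#'
#' @param sequences named character vector of DNA sequences (or a
#'   `DNAStringSet`).
#' @param kmers k-mer pair `data.frame` from [load_allele_kmers()].
#' @return `data.frame` with `sequence_id`, `site`, `call`
#'   (`C`/`T`/`ambiguous`/`no_match`) and `strand_found` (`+`, `-`, `both`
#'   or `NA`).
#' @export
scan_alleles <- function(sequences, kmers) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  sequences <- toupper(sequences)
  validate_kmer_pair(kmers)
  find <- function(seqs, km) {
    fwd <- grepl(km, seqs, fixed = TRUE)
    rev <- grepl(revcomp(km), seqs, fixed = TRUE)
    ifelse(fwd & rev, "both", ifelse(fwd, "+", ifelse(rev, "-", NA)))
  }
  out <- list()
  for (i in seq_len(nrow(kmers))) {
    sc <- find(sequences, toupper(kmers$kmer_c[i]))
    st <- find(sequences, toupper(kmers$kmer_t[i]))
    call <- ifelse(!is.na(sc) & !is.na(st), "ambiguous",
                   ifelse(!is.na(sc), "C", ifelse(!is.na(st), "T", "no_match")))
    strand <- ifelse(call == "C", sc, ifelse(call == "T", st, NA))
    out[[i]] <- data.frame(sequence_id = names(sequences),
                           site = kmers$site[i], call = call,
                           strand_found = strand, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Exact peptide scan over all six reading frames
#'
#' Translates each sequence in frames +1..+3 and -1..-3 (standard genetic
#' code; trailing partial codons dropped) and reports every exact occurrence
#' of the query peptide.
#'
#' @param sequences named character vector of DNA sequences (or a
#'   `DNAStringSet`).
#' @param peptide amino-acid string, e.g. the pre-edited 19-mer
#'   `"RIFDIPFYFLSNEWHLLLE"`.
#' @return `data.frame` with `sequence_id`, `frame` (+1..+3, -1..-3),
#'   `aa_offset` (1-based within the frame translation).
#' @export
scan_peptide <- function(sequences, peptide) {
  if (nchar(peptide) == 0) stop_config("peptide must be non-empty")
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  sequences <- toupper(sequences)
  out <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      tpl <- if (fr > 0) s else revcomp(s)
      off <- abs(fr)
      n_cod <- (nchar(tpl) - off + 1L) %/% 3L
      if (n_cod < nchar(peptide)) next
      sub <- substr(tpl, off, off + n_cod * 3L - 1L)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X"))
      hits <- gregexpr(peptide, aa, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (h in as.integer(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = id, frame = fr, aa_offset = h,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence_id = character(), frame = integer(),
                      aa_offset = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Collapse per-sequence allele calls to one call per species
#'
#' A species is called `C` if any of its sequences calls C and none calls T
#' (and symmetrically for `T`); mixed C/T calls (or any per-sequence
#' `ambiguous`) yield `ambiguous`; all `no_match` yields `no_match`.
#'
#' @param calls `data.frame` from [scan_alleles()].
#' @param species named character vector mapping `sequence_id` to species.
#' @return `data.frame` with `species`, `site`, `call`.
#' @export
species_allele_calls <- function(calls, species) {
  calls$species <- species[calls$sequence_id]
  combos <- unique(calls[, c("species", "site")])
  combos$call <- vapply(seq_len(nrow(combos)), function(i) {
    cc <- calls$call[calls$species == combos$species[i] &
                       calls$site == combos$site[i]]
    if (any(cc == "ambiguous") || (any(cc == "C") && any(cc == "T"))) "ambiguous"
    else if (any(cc == "C")) "C"
    else if (any(cc == "T")) "T"
    else "no_match"
  }, character(1))
  rownames(combos) <- NULL
  combos
}

#' Assemble an editotype matrix from allele calls and editing observations
#'
#' Status vocabulary: `genomic_T` (pre-edited T encoded in the DNA),
#' `edited` (genomic C, C-to-U conversion observed), `unedited_C` (genomic C,
#' no editing), `C_unknown_editing` (genomic C, editing status unknown),
#' `no_data` (no allele information), `ambiguous` (conflicting alleles).
#'
#' @param calls per-species calls from [species_allele_calls()].
#' @param editing_observations optional nested list:
#'   `editing_observations[[species]][[site]]` is `TRUE`/`FALSE`/`NA`.
#' @return `data.frame` with `species`, `site`, `status`.
#' @export
build_editotype <- function(calls, editing_observations = list()) {
  if (nrow(calls) == 0) {
    return(data.frame(species = character(), site = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  status <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls$call[i]
    if (cl == "T") return("genomic_T")
    if (cl == "no_match") return("no_data")
    if (cl == "ambiguous") return("ambiguous")
    obs <- editing_observations[[calls$species[i]]][[calls$site[i]]]
    if (is.null(obs) || is.na(obs)) "C_unknown_editing"
    else if (isTRUE(obs)) "edited"
    else "unedited_C"
  }, character(1))
  data.frame(species = calls$species, site = calls$site, status = status,
             stringsAsFactors = FALSE)
}
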