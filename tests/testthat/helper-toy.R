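# shared fixture builders (all in code; nothing on disk)

# a small plus-strand single-gene plastome with one editable C mid-CDS
toy_plus_genome <- function(len = 1500L, cds = c(301L, 900L), site = 600L,
                            seed = 11L, extra_features = NULL) {
  feats <- data.frame(name = "geneA", ftype = "CDS",
                      start = cds[1], end = cds[2], strand = "+",
                      stringsAsFactors = FALSE)
  if (!is.null(extra_features)) feats <- rbind(feats, extra_features)
  build_toy_genome(list(
    id = "cp", length = len, seed = seed, features = feats,
    editable_sites = data.frame(position = site, strand = "+",
                                name = "siteA", stringsAsFactors = FALSE)))
}

# brute-force alignment oracle: best ungapped identity of a read over every
# placement on both strands (mismatch count by position-wise comparison,
# Y/R matching both constituent bases)
brute_force_best <- function(read, genome) {
  gch <- strsplit(genome$sequence, "")[[1]]
  L <- length(gch)
  best <- list(identity = -1)
  for (strand in c("+", "-")) {
    rseq <- if (strand == "+") read else revcomp(read)
    rch <- strsplit(rseq, "")[[1]]
    rl <- length(rch)
    for (s in 1:(L - rl + 1)) {
      g <- gch[s:(s + rl - 1)]
      m <- sum(g == rch |
                 (g == "Y" & rch %in% c("C", "T")) |
                 (g == "R" & rch %in% c("A", "G")) |
                 g == "N")
      id <- m / rl
      if (id > best$identity + 1e-12) {
        best <- list(identity = id, start = s, strand = strand)
      }
    }
  }
  best
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# junction reference over random exon/intron blocks
toy_junctions <- function(seed = 5L, exon = 100L, min_overhang = 10L) {
  withr::with_seed(seed, {
    e1 <- random_dna(exon); intr <- random_dna(exon); e2 <- random_dna(exon)
    junction_reference("geneJ",
                       spliced_seq = paste0(e1, e2),
                       unspliced5_seq = paste0(e1, intr),
                       unspliced3_seq = paste0(intr, e2),
                       junction = c(exon, exon, exon),
                       min_overhang = min_overhang)
  })
}
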