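# build a pileup object by hand: list of (position, strand, base, count)
hand_pileup <- function(L, entries, genome_id = "x") {
  counts <- matrix(0L, nrow = L, ncol = 8,
                   dimnames = list(NULL, c("A+","C+","G+","T+","A-","C-","G-","T-")))
  for (e in entries) {
    col <- match(e$base, c("A", "C", "G", "T")) + if (e$strand == "-") 4L else 0L
    counts[e$position, col] <- counts[e$position, col] + e$count
  }
  structure(list(genome_id = genome_id, counts = counts), class = "pileup")
}

test_that("editing efficiency is t/(t+c) in percent and scale-invariant", {
  expect_equal(editing_efficiency(40, 60), 40)
  expect_equal(editing_efficiency(100, 0), 100)
  expect_equal(editing_efficiency(0, 50), 0)
  expect_equal(editing_efficiency(7, 13), editing_efficiency(70, 130))
  expect_error(editing_efficiency(0, 0), "zero coverage")
})

test_that("call_snps applies the inclusive 5% rate and coverage filters", {
  g <- organelle_genome("x", strrep("C", 10), circular = FALSE)
  pu4 <- hand_pileup(10, list(list(position = 5, strand = "+", base = "C", count = 96),
                              list(position = 5, strand = "+", base = "T", count = 4)))
  expect_equal(nrow(call_snps(pu4, g)), 0)          # 4% < 5%

  pu5 <- hand_pileup(10, list(list(position = 5, strand = "+", base = "C", count = 95),
                              list(position = 5, strand = "+", base = "T", count = 5)))
  snp <- call_snps(pu5, g)
  expect_equal(nrow(snp), 1)
  expect_equal(snp$alt_rate, 0.05)                   # inclusive threshold
  expect_equal(snp$snp_class, "C_to_T")
  expect_equal(snp$efficiency, 5)

  # below min_coverage nothing is called
  expect_equal(nrow(call_snps(pu5, g, min_coverage = 200)), 0)
  empty <- hand_pileup(10, list())
  expect_equal(nrow(call_snps(empty, g)), 0)
})

test_that("minus-strand G-to-A calls represent C-to-U on the transcript", {
  g <- organelle_genome("x", strrep("G", 10), circular = FALSE)
  pu <- hand_pileup(10, list(list(position = 4, strand = "-", base = "G", count = 60),
                             list(position = 4, strand = "-", base = "A", count = 40)))
  snp <- call_snps(pu, g)
  expect_equal(snp$snp_class, "G_to_A")
  expect_equal(snp$strand, "-")
  expect_equal(snp$efficiency, 40)
})

test_that("candidate filtering excludes known sites, structural RNAs and non-editing SNP types", {
  feats <- data.frame(name = c("rrn1", "geneB", "ig"),
                      ftype = c("rRNA", "CDS", "intergenic"),
                      start = c(1, 20, 60), end = c(10, 50, 80),
                      strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  snps <- data.frame(
    genome_id = "x", position = c(5, 30, 35, 70, 40),
    strand = c("+", "+", "+", "+", "-"),
    ref_base = c("C", "C", "A", "C", "G"),
    alt_base = c("T", "T", "G", "T", "A"),
    ref_count = 50, alt_count = 50, coverage = 100, alt_rate = 0.5,
    efficiency = 50,
    snp_class = c("C_to_T", "C_to_T", "other", "C_to_T", "G_to_A"),
    stringsAsFactors = FALSE)
  known <- data.frame(genome_id = "x", position = 30, strand = "+", name = "k")

  out <- filter_candidates(snps, known, feats)
  # rRNA position 5 dropped, known site 30 dropped, A->G dropped
  expect_setequal(out$position, c(70, 40))
  expect_equal(out$location_class[out$position == 70], "intergenic")
  # minus-strand edit over a plus-strand CDS is antisense
  expect_equal(out$location_class[out$position == 40], "antisense")
})

test_that("off-target discovery requires a mutant signal and a silent wild type", {
  mk <- function(pos, eff) data.frame(
    genome_id = "x", position = pos, strand = "+", ref_base = "C",
    alt_base = "T", ref_count = 50, alt_count = 50, coverage = 100,
    alt_rate = eff / 100, efficiency = eff, snp_class = "C_to_T",
    location_class = "CDS", stringsAsFactors = FALSE)
  mut <- list(lib1 = mk(c(10, 20), c(40, 4)), lib2 = mk(30, 80))
  wt <- mk(30, 10)

  out <- discover_offtargets(mut, wt)
  # 20 fails the 5% threshold; 30 is edited in wild type
  expect_equal(out$position, 10)
  expect_equal(out$lib1, 40)
  expect_equal(out$lib2, 0)

  expect_equal(nrow(discover_offtargets(list(l = mk(10, 40)[0, ]))), 0)

  # raising the threshold never adds sites
  n <- vapply(c(5, 20, 50), function(th) {
    nrow(discover_offtargets(mut, wt, threshold = th))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("affinity classification separates moderate- and overexpression-only sites", {
  fx <- load_fixtures()
  cls <- classify_affinity(fx$table2, moderate_libs = c("hpl6", "hpl1"),
                           over_libs = c("ubq3", "ubq1"))
  expect_equal(unname(cls["petB_intr-mid"]), "high")
  expect_equal(unname(cls["ccsA-182"]), "low")
  expect_equal(unname(cls["ndhB-291"]), "high")
  # every Table-2 row is edited somewhere, so every site is classified
  expect_length(cls, nrow(fx$table2))
  empty <- classify_affinity(fx$table2[0, ], c("hpl6"), c("ubq1"))
  expect_length(empty, 0)
})

test_that("codon impact annotation reports amino-acid changes", {
  # plus-strand CDS: ATG TCA CAA CTC TAA
  seq <- paste0(strrep("A", 10), "ATGTCACAACTCTAA", strrep("G", 10))
  g <- organelle_genome("x", seq, circular = FALSE)
  feats <- data.frame(name = "cds", ftype = "CDS", start = 11, end = 25,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(annotate_impact(15, "+", g, feats), "S->L")      # TCA -> TTA
  expect_equal(annotate_impact(17, "+", g, feats), "Q->STOP")   # CAA -> TAA
  expect_equal(annotate_impact(22, "+", g, feats), "synonymous")# CTC -> CTT
  expect_equal(annotate_impact(3, "+", g, feats), "-")
  expect_error(annotate_impact(3, "+", g, feats, require_cds = TRUE), "CDS")

  # minus-strand CDS encoding CAT (H) -> TAT (Y) at codon position 1
  m <- organelle_genome("y", paste0(strrep("A", 5), revcomp("CATGGG"), strrep("A", 5)),
                        circular = FALSE)
  mf <- data.frame(name = "cdsm", ftype = "CDS", start = 6, end = 11,
                   strand = "-", stringsAsFactors = FALSE)
  expect_equal(annotate_impact(11, "-", m, mf), "H->Y")
})
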