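test_that("build_toy_genome honors degenerate configs, strands and seeds", {
  g0 <- build_toy_genome(list(id = "t", length = 1000, seed = 7))
  expect_equal(genome_length(g0), 1000)
  expect_equal(nrow(g0$features), 0)

  # a minus-strand editable site must be a C on the transcribed strand,
  # hence a G on the plus strand
  g1 <- build_toy_genome(list(
    id = "t", length = 500, seed = 3,
    features = data.frame(name = "m", ftype = "CDS", start = 100, end = 400,
                          strand = "-"),
    editable_sites = data.frame(position = 250, strand = "-", name = "s")))
  expect_equal(substr(g1$sequence, 250, 250), "G")

  g2 <- build_toy_genome(list(
    id = "t", length = 500, seed = 3,
    features = data.frame(name = "m", ftype = "CDS", start = 100, end = 400,
                          strand = "-"),
    editable_sites = data.frame(position = 250, strand = "-", name = "s")))
  expect_identical(g1$sequence, g2$sequence)

  expect_error(build_toy_genome(list(
    id = "t", length = 500, seed = 1,
    features = data.frame(name = c("a", "b"), ftype = "CDS",
                          start = c(10, 50), end = c(100, 120),
                          strand = "+"))),
    "overlapping")
})

test_that("simulate_reads produces exact transcript substrings when clean", {
  g <- toy_plus_genome()
  spec <- simulation_spec("cp", n_pairs = 0, seed = 1)
  expect_equal(nrow(simulate_reads(g, spec)), 0)

  spec <- simulation_spec("cp", n_pairs = 50, error_rate = 0, seed = 2)
  pairs <- simulate_reads(g, spec)
  transcript <- substr(g$sequence, 301, 900)
  for (i in seq_len(nrow(pairs))) {
    expect_true(grepl(pairs$mate1_seq[i], transcript, fixed = TRUE))
    expect_true(grepl(revcomp(pairs$mate2_seq[i]), transcript, fixed = TRUE))
  }
  expect_true(all(pairs$strand == "+"))
  expect_true(all(nchar(pairs$mate1_seq) == 150))
  expect_equal(nchar(pairs$mate1_qual), nchar(pairs$mate1_seq))
})

test_that("simulated editing fractions converge to the binomial target", {
  g <- toy_plus_genome()
  spec <- simulation_spec("cp", n_pairs = 2500, error_rate = 0,
                          editing_fractions = c("600" = 0.5), seed = 77)
  pairs <- simulate_reads(g, spec)
  # direct tally oracle: read the base over the site from mate 1 using the
  # known fragment start (no introns, plus strand, no errors)
  off <- 600 - pairs$start + 1
  covered <- off >= 1 & off <= 150
  bases <- substr(pairs$mate1_seq[covered], off[covered], off[covered])
  cov <- sum(bases %in% c("C", "T"))
  expect_gt(cov, 1000)
  frac <- sum(bases == "T") / cov
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / cov))
})

test_that("antisense fragments carry the opposite strand label", {
  g <- toy_plus_genome()
  spec <- simulation_spec("cp", n_pairs = 30, error_rate = 0,
                          antisense_fraction = 1, seed = 5)
  pairs <- simulate_reads(g, spec)
  expect_true(all(pairs$strand == "-"))
  # antisense mate1 matches the reverse complement of the transcript
  transcript <- substr(g$sequence, 301, 900)
  expect_true(all(vapply(pairs$mate1_seq, function(s) {
    grepl(s, revcomp(transcript), fixed = TRUE)
  }, logical(1))))
})

test_that("simulate_reads rejects editing positions that are not C", {
  g <- toy_plus_genome()
  bad <- simulation_spec("cp", n_pairs = 10,
                         editing_fractions = c("601" = 0.5), seed = 1)
  # position 601 is only a C by chance 1/4; force a non-C
  if (substr(g$sequence, 601, 601) == "C") {
    substr(g$sequence, 601, 601) <- "A"
  }
  expect_error(simulate_reads(g, bad), "not a C")
})

test_that("fastq round trip preserves pairs", {
  g <- toy_plus_genome()
  pairs <- simulate_reads(g, simulation_spec("cp", n_pairs = 10, seed = 3))
  prefix <- file.path(withr::local_tempdir(), "lib")
  write_fastq_pairs(pairs, prefix)
  back <- read_fastq_pairs(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
  expect_equal(back$mate1_seq, pairs$mate1_seq)
  expect_equal(back$mate2_seq, pairs$mate2_seq)
  expect_equal(back$id, pairs$id)
})

test_that("packaged fixture tables match the printed shape and values", {
  fx <- load_fixtures()
  t2 <- fx$table2
  expect_equal(nrow(t2), 33)
  expect_equal(sum(t2$genome == "cp"), 32)
  expect_equal(sum(t2$genome == "mt"), 1)
  expect_true(all(t2$wt == 0))
  vals <- unlist(t2[c("hpl6", "hpl1", "ubq3", "ubq1")])
  expect_true(all(vals >= 0 & vals <= 100))

  expect_equal(fixture_value(t2, "ndhB-291", "ubq1"), 91.8)
  expect_equal(fixture_value(t2, "ccmC-83", "hpl6"), 0)
  expect_equal(fixture_value(fx$table4, "ndhB-50", "tc4"), 100)
  expect_length(fx$arabidopsis_targets, 5)
})
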