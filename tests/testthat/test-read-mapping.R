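test_that("exact and reverse-complement reads align perfectly", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  read <- substr(g$sequence, 401, 550)

  a <- align_read(read, idx)
  expect_equal(a$start, 401)
  expect_equal(a$strand, "+")
  expect_equal(a$identity, 1)
  expect_equal(a$aligned_fraction, 1)

  b <- align_read(revcomp(read), idx)
  expect_equal(b$start, 401)
  expect_equal(b$strand, "-")
  expect_equal(b$identity, 1)
})

test_that("aligner agrees with the brute-force identity oracle", {
  g <- build_toy_genome(list(id = "small", length = 600, seed = 21))
  idx <- genome_index(g)
  withr::with_seed(31, {
    for (i in 1:20) {
      start <- sample(1:(600 - 60), 1)
      read <- substr(g$sequence, start, start + 59)
      n_mm <- sample(0:3, 1)
      if (n_mm > 0) {
        ch <- strsplit(read, "")[[1]]
        at <- sample(60, n_mm)
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
        read <- paste(ch, collapse = "")
      }
      if (runif(1) < 0.5) read <- revcomp(read)
      a <- align_read(read, idx, seed_step = 5)
      oracle <- brute_force_best(read, g)
      expect_equal(a$identity, oracle$identity, tolerance = 1e-12)
    }
  })
})

test_that("a single substitution gives identity 149/150", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  read <- substr(g$sequence, 701, 850)
  ch <- strsplit(read, "")[[1]]
  ch[75] <- setdiff(c("A", "C", "G", "T"), ch[75])[1]
  a <- align_read(paste(ch, collapse = ""), idx)
  expect_equal(a$identity, 149 / 150)
  expect_equal(a$start, 701)
})

test_that("Y/R-masked reference bases match both constituent bases", {
  g <- organelle_genome("m", paste0(strrep("A", 30), "C", strrep("G", 30)),
                        circular = FALSE)
  masked <- mask_known_sites(g, data.frame(genome_id = "m", position = 31,
                                           strand = "+", name = "s"))
  idx <- genome_index(masked)
  for (b in c("C", "T")) {
    rd <- paste0(strrep("A", 30), b, strrep("G", 30))
    a <- align_read(rd, idx)
    expect_equal(a$identity, 1)
  }
})

test_that("pair selection applies the length/identity/coverage rule", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  good <- substr(g$sequence, 401, 550)

  # both mates exactly 100 nt: "longer than 100 nt" is strict -> rejected
  p100 <- data.frame(id = "a", mate1_seq = substr(good, 1, 100),
                     mate2_seq = substr(good, 51, 150))
  expect_equal(nrow(select_organellar_pairs(p100, idx)$pairs), 0)

  # one alignable mate suffices
  p1 <- data.frame(id = "b", mate1_seq = good,
                   mate2_seq = strrep("ACGTT", 30))
  expect_equal(nrow(select_organellar_pairs(p1, idx)$pairs), 1)

  # identity 0.80 on the only alignable mate -> rejected
  ch <- strsplit(good, "")[[1]]
  ch[1:30] <- vapply(ch[1:30], function(b) setdiff(c("A","C","G","T"), b)[1], "")
  p2 <- data.frame(id = "c", mate1_seq = paste(ch, collapse = ""),
                   mate2_seq = strrep("ACGTT", 30))
  sel2 <- select_organellar_pairs(p2, idx)
  expect_equal(nrow(sel2$pairs), 0)
})

test_that("selection is monotone in the identity threshold", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  spec <- simulation_spec("cp", n_pairs = 60, error_rate = 0.02, seed = 9)
  pairs <- simulate_reads(g, spec)
  kept <- lapply(c(0.7, 0.85, 0.95), function(mi) {
    select_organellar_pairs(pairs, idx, min_identity = mi)$pairs$id
  })
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("pileups count bases per strand and collapse duplicates", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  read <- substr(g$sequence, 401, 550)
  pairs <- data.frame(id = c("r1", "r2"), mate1_seq = read, mate2_seq = read)
  sel <- select_organellar_pairs(pairs, idx)

  pu <- build_pileup(sel$alignments, g, collapse_duplicates = FALSE)
  expect_equal(unname(rowSums(pu$counts)[450]), 4)  # 2 pairs x 2 identical mates
  pc <- build_pileup(sel$alignments, g, collapse_duplicates = TRUE)
  expect_equal(unname(rowSums(pc$counts)[450]), 2)  # one per mate after collapse

  # conservation: row sums equal coverage column in the data.frame view
  df <- as.data.frame(pu)
  expect_equal(df$coverage,
               unname(rowSums(df[, c("A+","C+","G+","T+","A-","C-","G-","T-")])))
})

test_that("error-free unedited reads leave no non-reference bases", {
  g <- toy_plus_genome(len = 2000)
  idx <- genome_index(g)
  pairs <- simulate_reads(g, simulation_spec("cp", n_pairs = 80,
                                             error_rate = 0, seed = 13))
  sel <- select_organellar_pairs(pairs, idx)
  pu <- build_pileup(sel$alignments, g)
  gch <- strsplit(g$sequence, "")[[1]]
  base_col <- c(A = 1, C = 2, G = 3, T = 4)
  covered <- which(rowSums(pu$counts) > 0)
  for (p in covered) {
    ref <- base_col[gch[p]]
    expect_equal(sum(pu$counts[p, -c(ref, ref + 4)]), 0)
  }
})
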