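toy_protein <- function(classes, aa5, aa_last, aa2 = NA) {
  ppr_protein("toy", data.frame(index = seq_along(classes), mclass = classes,
                                aa2 = aa2, aa5 = aa5, aa_last = aa_last,
                                stringsAsFactors = FALSE))
}

test_that("binding prediction is a pure code-table lookup", {
  code <- load_code_table()
  p <- toy_protein(c("S1", "L1", "SS", "P1"),
                   aa5 = c("T", "V", "T", "Q"),
                   aa_last = c("N", "N", "D", "Q"))
  pred <- predict_binding(p, code)
  expect_equal(pred, c("A", "AU", "G", "n.p."))

  # permuting rule insertion order changes nothing
  shuffled <- code[rev(seq_len(nrow(code))), ]
  class(shuffled) <- class(code)
  expect_equal(predict_binding(p, shuffled), pred)

  # unknown amino acids are not predictable
  p2 <- toy_protein("P1", NA_character_, "N")
  expect_equal(predict_binding(p2, code), "n.p.")
})

test_that("anchoring places the last motif at -4 and counts backwards", {
  p15 <- toy_protein(rep("P1", 15), rep("T", 15), rep("N", 15))
  a <- anchor_alignment(p15)
  expect_equal(unname(a[c("1", "15")]), c(-18, -4))
  expect_equal(unname(a["9"]), -10)
  expect_equal(unname(a["7"]), -12)

  p1 <- toy_protein("P1", "T", "N")
  expect_equal(unname(anchor_alignment(p1)), -4)

  p30 <- toy_protein(rep("P1", 30), rep("T", 30), rep("N", 30))
  expect_error(anchor_alignment(p30), "footprint")
})

test_that("cis-element scoring tallies mismatches over the motif footprint", {
  code <- load_code_table()
  p <- toy_protein(rep("S1", 15), rep("T", 15), rep("N", 15))  # all predict A
  pred <- predict_binding(p, code)
  anch <- anchor_alignment(p)

  perfect <- cis_element("perfect",
                         paste0(strrep("A", 17), "AAAC", "AAAAA"))
  sc0 <- score_cis_element(perfect, pred, anch)
  expect_equal(sc0$total_mismatches, 0)
  expect_equal(sc0$n_evaluable, 15)

  # one violation at an evaluated position (-10)
  seq1 <- perfect$sequence
  substr(seq1, 11, 11) <- "G"
  one <- cis_element("one", seq1)
  sc1 <- score_cis_element(one, pred, anch)
  expect_equal(sc1$total_mismatches, 1)
  expect_equal(sc1$verdicts$verdict[sc1$verdicts$position == -10], "mismatch")
  # positions outside the footprint are never counted
  expect_true(all(sc1$verdicts$verdict[sc1$verdicts$position > -4] == "unaligned"))

  # a fully unpredictable protein is flagged: zero evaluable positions
  pnp <- toy_protein(rep("P1", 15), rep("Q", 15), rep("Q", 15))
  scnp <- score_cis_element(perfect, predict_binding(pnp, code), anch)
  expect_equal(scnp$total_mismatches, 0)
  expect_equal(scnp$n_evaluable, 0)
})

test_that("scorecard totals match an exhaustive per-position oracle", {
  code <- load_code_table()
  withr::with_seed(42, {
    for (rep in 1:5) {
      aa5 <- sample(c("T", "S", "N", "Q"), 15, replace = TRUE)
      aal <- sample(c("N", "D", "S", "Q"), 15, replace = TRUE)
      p <- toy_protein(rep("P1", 15), aa5, aal)
      pred <- predict_binding(p, code)
      anch <- anchor_alignment(p)
      seq <- paste(c(sample(c("A","C","G","U"), 20, replace = TRUE), "C",
                     sample(c("A","C","G","U"), 5, replace = TRUE)),
                   collapse = "")
      cis <- cis_element(paste0("r", rep), seq)
      sc <- score_cis_element(cis, pred, anch)
      # oracle: walk every motif position and compare by hand
      mm <- 0
      for (k in 1:15) {
        pos <- unname(anch[as.character(k)])
        b <- substr(seq, pos + 21, pos + 21)
        if (pred[k] != "n.p." && !grepl(b, pred[k], fixed = TRUE)) mm <- mm + 1
      }
      expect_equal(sc$total_mismatches, mm)
    }
  })
})

test_that("set scoring marginals are mutually consistent", {
  code <- load_code_table()
  p <- toy_protein(rep("S1", 15),
                   sample(c("T", "S", "N"), 15, replace = TRUE),
                   sample(c("N", "D", "S"), 15, replace = TRUE))
  withr::with_seed(7, {
    els <- lapply(1:6, function(i) {
      cis_element(paste0("s", i),
                  paste(c(sample(c("A","C","G","U"), 20, TRUE), "C",
                          sample(c("A","C","G","U"), 5, TRUE)), collapse = ""))
    })
  })
  res <- score_cis_set(els, p, code)
  expect_equal(sum(res$per_site_mismatches), sum(res$per_motif_mismatches))
  expect_equal(unname(res$per_site_mismatches),
               unname(rowSums(res$verdicts == "mismatch")))
})

test_that("frequency matrices tally bases and columns sum to one", {
  two <- rep("ACGUA", 2)
  fm <- frequency_matrix(two, span = c(-2, 2))
  expect_true(all(apply(fm$freq, 2, max) == 1))
  expect_equal(unname(colSums(fm$freq)), rep(1, 5))

  four <- c("A", "C", "G", "U")
  fm4 <- frequency_matrix(four, span = c(0, 0))
  expect_equal(unname(fm4$freq[, 1]), rep(0.25, 4))

  withr::with_seed(3, {
    seqs <- replicate(24, paste(sample(c("A","C","G","U"), 10, TRUE), collapse = ""))
    fm24 <- frequency_matrix(seqs, span = c(1, 10))
    mat <- do.call(rbind, strsplit(seqs, ""))
    for (j in 1:10) {
      expect_equal(unname(fm24$counts[, j]),
                   unname(as.integer(table(factor(mat[, j], levels = c("A","C","G","U"))))))
    }
  })
})

test_that("degenerate consensus uses IUPAC codes and pins the edited C", {
  fm <- list(freq = matrix(c(1, 0, 0, 0), 4, 1,
                           dimnames = list(c("A","C","G","U"), "1")))
  expect_equal(degenerate_consensus(fm, 0.2), "A")
  fm$freq[, 1] <- c(0.5, 0, 0, 0.5)
  expect_equal(degenerate_consensus(fm, 0.2), "W")
  fm$freq[, 1] <- rep(0.25, 4)
  expect_equal(degenerate_consensus(fm, 0.2), "N")
  colnames(fm$freq) <- "0"
  expect_equal(degenerate_consensus(fm, 0.2), "C")
})
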