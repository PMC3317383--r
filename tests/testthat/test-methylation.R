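make_calls <- function(...) {
  sets <- list(...)
  purrr::imap_dfr(sets, function(pos, name) {
    tibble::tibble(predictor = name, position = as.integer(pos),
                   residue = "R")
  })
}

test_that("consensus keeps sites called by at least min_agree predictors", {
  calls <- make_calls(p1 = c(248, 250, 264), p2 = c(248, 250, 266),
                      p3 = c(248, 250, 264, 266))
  expect_equal(consensus_calls(calls, 2)$position,
               c(248L, 250L, 264L, 266L))
  expect_equal(consensus_calls(calls, 1)$position,
               sort(unique(calls$position)))           # union
  expect_equal(consensus_calls(calls, 3)$position, c(248L, 250L))  # intersect
  expect_error(consensus_calls(calls, 4), class = "ptmtalk_usage_error")
})

test_that("consensus shrinks monotonically as min_agree grows", {
  calls <- gen_callsets(true_sites = seq(10, 200, by = 10),
                        n_predictors = 4, sensitivity = 0.8, fpr = 0.05,
                        eligible_positions = 1:200, seed = 3)
  sizes <- vapply(1:4, function(k) nrow(consensus_calls(calls, k)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("calls are validated against the sequence when given", {
  calls <- tibble::tibble(predictor = "p", position = 2L, residue = "K")
  expect_error(consensus_calls(calls, 1, record = "MRT"),
               class = "ptmtalk_validation_error")
  expect_equal(nrow(consensus_calls(
    tibble::tibble(predictor = "p", position = 2L, residue = "R"),
    1, record = "MRT")), 1)
})

test_that("fixture call sets reach the nine-site consensus", {
  cons <- consensus_calls(foxo3_methylation_calls(), 2,
                          record = foxo3_record())
  expect_equal(nrow(cons), 9)
  expect_equal(cons$position[cons$residue == "R"],
               c(248L, 250L, 264L, 266L))
  expect_equal(cons$position[cons$residue == "K"],
               c(149L, 207L, 270L, 271L, 569L))
  # the single-predictor decoys drop out
  expect_false(any(c(249, 262) %in% cons$position))
})

test_that("global alignment reproduces known toy optima", {
  sm <- toy_submat(c("M", "K", "T", "A"))
  aln <- align_global("MKTA", "MKA", substitution_matrix = sm,
                      gap_open = 0, gap_extend = 2)
  expect_equal(aln$score, 1)  # 3 matches - one gap
  expect_equal(nchar(aln$a_aln), 4)
  expect_equal(aln$b_aln, sub("T", "-", aln$a_aln))

  ident <- align_global("MKTAY", "MKTAY", substitution_matrix = sm <-
                          toy_submat(c("M", "K", "T", "A", "Y")),
                        gap_open = 0, gap_extend = 2)
  expect_equal(ident$a_aln, "MKTAY")
  expect_equal(ident$b_aln, "MKTAY")

  tail_gap <- align_global("MKTA", "MKTAC",
                           substitution_matrix =
                             toy_submat(c("M", "K", "T", "A", "C")),
                           gap_open = 0, gap_extend = 2)
  expect_equal(tail_gap$a_aln, "MKTA-")
})

test_that("alignment scores match the brute-force DP oracle", {
  sm <- toy_submat(c("A", "C", "D"))
  withr::with_seed(17, {
    for (i in 1:150) {
      a <- paste(sample(c("A", "C", "D"), sample(1:8, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "D"), sample(1:8, 1), replace = TRUE),
                 collapse = "")
      got <- align_global(a, b, substitution_matrix = sm, gap_open = 0,
                          gap_extend = 2)$score
      expect_equal(got, oracle_nw_score(a, b, 1, -1, 2),
                   info = paste(a, b))
    }
  })
})

test_that("alignment score is symmetric in its arguments", {
  sm <- toy_submat(c("A", "C", "D"))
  withr::with_seed(23, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "C", "D"), sample(2:8, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "D"), sample(2:8, 1), replace = TRUE),
                 collapse = "")
      expect_equal(
        align_global(a, b, substitution_matrix = sm, gap_open = 0,
                     gap_extend = 2)$score,
        align_global(b, a, substitution_matrix = sm, gap_open = 0,
                     gap_extend = 2)$score)
    }
  })
})

test_that("empty sequences are rejected", {
  expect_error(align_global("", "MKT"), class = "ptmtalk_usage_error")
})

test_that("site transfer maps through the alignment", {
  # identity transfer
  tr <- transfer_sites("MKRTAYRK", "MKRTAYRK", c(3, 7))
  expect_equal(tr$dst_pos, c(3L, 7L))
  expect_true(all(tr$residue_match))

  # a site opposite a gap transfers to nothing
  aln <- align_global("MKTA", "MKA",
                      substitution_matrix = toy_submat(c("M", "K", "T", "A")),
                      gap_open = 0, gap_extend = 2)
  tr_gap <- transfer_sites("MKTA", "MKA", c(3), alignment = aln)
  expect_true(is.na(tr_gap$dst_pos))
  expect_false(tr_gap$residue_match)

  # a substituted site maps but does not match
  tr_sub <- transfer_sites("MKRT", "MKST", 3,
                           substitution_matrix = toy_submat(
                             c("M", "K", "R", "S", "T")),
                           gap_open = 0, gap_extend = 2)
  expect_equal(tr_sub$dst_pos, 3L)
  expect_equal(tr_sub$dst_residue, "S")
  expect_false(tr_sub$residue_match)
})

test_that("FoxO1 methyl-arginines transfer onto the FoxO3 AKT motif", {
  tr <- transfer_sites(foxo1_record(), foxo3_record(), c(248L, 250L))
  expect_equal(tr$dst_pos, c(248L, 250L))
  expect_equal(tr$src_residue, c("R", "R"))
  expect_true(all(tr$residue_match))
})
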