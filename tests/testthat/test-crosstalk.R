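test_that("classifier agrees with the truth-table oracle on all cells", {
  cats <- c("above", "near", "below")
  grid <- expand.grid(phos = cats, glyc = cats,
                      conserved = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  got <- classify_site(grid$phos, grid$glyc, grid$conserved)
  want <- mapply(oracle_classify, grid$phos, grid$glyc, grid$conserved)
  expect_equal(got, unname(want))
  # tyrosine encoding: absent glyc channel reaches only phospho_only/none
  expect_equal(classify_site(cats, NA_character_, TRUE),
               c("phospho_only", "none", "none"))
})

test_that("categorical and numeric potentials classify identically", {
  params <- crosstalk_params(epsilon = 0.1)
  scores <- tibble::tibble(
    position = 1:4,
    residue = c("S", "T", "S", "S"),
    phos_potential = c(0.9, 0.55, 0.43, 0.2),
    glyc_potential = c(0.61, 0.44, 0.7, 0.49),
    conserved = c(TRUE, TRUE, FALSE, FALSE)
  )
  got <- classify_sites(scores, params)
  expect_equal(got$phos_cat, c("above", "above", "near", "below"))
  expect_equal(got$glyc_cat, c("above", "near", "above", "near"))
  expect_equal(got$classification,
               c("yy_positive", "yy_false_negative", "glyc_only", "none"))
})

test_that("channel encodings are validated", {
  expect_error(classify_site("high", "above", TRUE),
               class = "ptmtalk_validation_error")
  expect_error(classify_site(NA_character_, "above", TRUE),
               class = "ptmtalk_validation_error")
  scores <- tibble::tibble(position = 1L, residue = "Y",
                           phos_cat = "above", glyc_cat = "above",
                           conserved = TRUE)
  expect_error(classify_sites(scores), class = "ptmtalk_validation_error")
})

test_that("fixture rows classify to their published calls", {
  ann <- foxo3_annotations()
  cls <- function(p) ann$classification[ann$position == p]
  expect_equal(cls(253), "yy_positive")        # AKT-motif serine
  expect_equal(cls(32), "yy_false_negative")   # AKT-verified threonine
  expect_equal(cls(12), "phospho_only")
  expect_equal(cls(276), "glyc_only")
  expect_equal(cls(30), "none")
})

test_that("selection parameters gate on EV, conservation and SA", {
  ann <- foxo3_annotations()
  s294 <- ann[ann$position == 294, ]
  expect_true(s294$ev_support && s294$conserved && s294$accessible)
  expect_true(is.na(ann$accessible[ann$position == 7]))  # no SA -> unknown
  expect_true(ann$accepted[ann$position == 7])   # still a positive call
  expect_false(ann$ev_support[ann$position == 26])

  low_sa <- annotate_sites(
    tibble::tibble(position = 5L, residue = "S", phos_cat = "above",
                   glyc_cat = "below", sa = 0.4, conserved = TRUE))
  expect_false(low_sa$accessible)
  expect_false(low_sa$accepted)
})

test_that("EV residue mismatches are fixture errors, not silent misses", {
  scores <- tibble::tibble(position = 10L, residue = "S",
                           phos_cat = "above", glyc_cat = "below",
                           conserved = TRUE)
  ev <- tibble::tibble(position = 10L, residue = "T")
  expect_error(annotate_sites(scores, ev),
               class = "ptmtalk_validation_error")
})

test_that("classification counts are exhaustive, exclusive and conserved", {
  gen <- gen_site_scores(
    gen_protein(600, seed = 7),
    planted = c(yy_positive = 10, yy_false_negative = 4,
                phospho_only = 20, glyc_only = 5, none = 5),
    seed = 7)
  ann <- annotate_sites(gen$scores)
  got <- table(factor(ann$classification,
                      levels = c("yy_positive", "yy_false_negative",
                                 "phospho_only", "glyc_only", "none")))
  expect_equal(unname(as.integer(got)), c(10L, 4L, 20L, 5L, 5L))
  counts <- summarize_classifications(ann)
  expect_equal(sum(counts$n), nrow(ann))
  # every FN site is conserved
  expect_true(all(ann$conserved[ann$classification == "yy_false_negative"]))
})

test_that("summaries reject duplicate positions and handle empty input", {
  dup <- tibble::tibble(position = c(1L, 1L), residue = "S",
                        classification = "none")
  expect_error(summarize_classifications(dup),
               class = "ptmtalk_validation_error")
  empty <- tibble::tibble(position = integer(), residue = character(),
                          classification = character())
  expect_equal(sum(summarize_classifications(empty)$n), 0)
})

test_that("growing epsilon never loses false-negative calls", {
  gen <- gen_site_scores(
    gen_protein(800, seed = 5),
    planted = c(yy_positive = 8, yy_false_negative = 6,
                phospho_only = 15, glyc_only = 10, none = 10),
    params = crosstalk_params(epsilon = 0.1), seed = 13)
  scores <- gen$scores
  scores$conserved <- TRUE  # isolate the epsilon effect
  n_fn <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(eps) {
    cl <- classify_sites(scores, crosstalk_params(epsilon = eps))
    sum(cl$classification == "yy_false_negative")
  }, numeric(1))
  expect_true(all(diff(n_fn) >= 0))
})

test_that("kinase cross-tabulation recovers the fixture assignments", {
  ann <- foxo3_annotations()
  ct <- kinase_crosstab(ann)
  expect_equal(ct$positions[[which(ct$kinase == "Cdk5")]],
               c(43L, 173L, 294L, 355L, 425L))
  akt <- ct$positions[[which(ct$kinase == "AKT")]]
  expect_setequal(akt, c(12L, 32L, 253L, 315L, 413L))
  # Ser173 carries the top surface accessibility among Cdk5 sites
  expect_equal(ct$max_sa_position[ct$kinase == "Cdk5"], 173L)
  expect_equal(ct$max_sa[ct$kinase == "Cdk5"], 3.6)
})

test_that("external assignments at non-site positions are dropped loudly", {
  ann <- foxo3_annotations()
  assignments <- tibble::tibble(kinase = c("AKT", "AKT"),
                                position = c(253L, 9999L))
  expect_warning(ct <- kinase_crosstab(ann, assignments), "9999")
  expect_equal(ct$positions[[1]], 253L)
  expect_equal(nrow(kinase_crosstab(ann[0, ], assignments[0, ])), 0)
})

test_that("re-annotating the fixture is deterministic", {
  expect_identical(tidy(foxo3_annotations()), tidy(foxo3_annotations()))
})
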