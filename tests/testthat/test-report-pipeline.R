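test_that("domain assignment follows the interval map", {
  dom <- foxo3_domains()
  expect_equal(assign_domains(253, dom)$domain, "DBD")
  expect_setequal(assign_domains(250, dom)$domain, c("DBD", "NLS"))
  expect_setequal(assign_domains(390, dom)$domain, c("NES", "TAD"))
  expect_equal(nrow(assign_domains(100, dom)), 0)  # N-terminal tail
  expect_error(assign_domains(9999, dom), class = "ptmtalk_position_error")
})

test_that("neighbor crosstalk pairs cross-modification sites in range", {
  pairs <- neighbor_crosstalk(phospho_sites = 253,
                              methyl_sites = c(248, 250), radius = 5)
  expect_equal(pairs$methyl_pos, c(248L, 250L))
  expect_equal(pairs$distance, c(5L, 3L))

  mst1 <- neighbor_crosstalk(209, 207, radius = 5)
  expect_equal(mst1$distance, 2L)

  expect_equal(nrow(neighbor_crosstalk(c(10, 20), c(30, 40), radius = 0)),
               0)
  expect_error(neighbor_crosstalk(1, 2, radius = -1),
               class = "ptmtalk_usage_error")
})

test_that("neighbor pairing is symmetric up to role labels", {
  a <- c(10, 14, 100)
  b <- c(12, 105, 300)
  ab <- neighbor_crosstalk(a, b, radius = 6)
  ba <- neighbor_crosstalk(b, a, radius = 6)
  expect_setequal(paste(ab$methyl_pos, ab$phospho_pos),
                  paste(ba$phospho_pos, ba$methyl_pos))
})

test_that("report bundle round-trips the annotation set", {
  withr::with_seed(31, {
    for (i in 1:5) {
      gen <- gen_site_scores(
        gen_protein(400, seed = i),
        planted = c(yy_positive = 5, yy_false_negative = 3,
                    phospho_only = 8, glyc_only = 4, none = 4),
        seed = i)
      ann <- annotate_sites(gen$scores)
      out <- withr::local_tempdir()
      files <- write_reports(ann, out_dir = out)
      back <- read_site_annotations(files[["site_table"]])
      expect_equal(tidy(back), tidy(ann), tolerance = 1e-12)
    }
  })
})

test_that("summary.json mirrors summarize_classifications", {
  ann <- foxo3_annotations()
  out <- withr::local_tempdir()
  methyl <- consensus_calls(foxo3_methylation_calls(), 2)
  files <- write_reports(ann, methyl = methyl, domains = foxo3_domains(),
                         out_dir = out, record = foxo3_record())
  js <- jsonlite::read_json(files[["summary"]])
  counts <- summarize_classifications(ann)
  for (cl in c("yy_positive", "yy_false_negative", "phospho_only",
               "glyc_only", "none")) {
    expect_equal(js$classifications[[cl]],
                 sum(counts$n[counts$classification == cl]))
  }
  expect_equal(js$phospho_predicted$total,
               sum(ann$phos_cat == "above"))
  expect_equal(js$methylation_consensus$total, 9)
  # methyl table carries published flanking windows
  mt <- readr::read_tsv(files[["methyl_table"]], show_col_types = FALSE)
  expect_equal(mt$flank[mt$position == 264], "NKYTKS[R]GRAAKK")
})

test_that("empty annotation sets produce headers-only reports", {
  empty <- annotate_sites(tibble::tibble(
    position = integer(), residue = character(),
    phos_cat = character(), glyc_cat = character(),
    conserved = logical()))
  out <- withr::local_tempdir()
  files <- write_reports(empty, out_dir = out)
  expect_equal(nrow(readr::read_tsv(files[["site_table"]],
                                    show_col_types = FALSE)), 0)
  js <- jsonlite::read_json(files[["summary"]])
  expect_equal(js$n_sites, 0)
})

test_that("the packaged pipeline runs end to end and is deterministic", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res1 <- run_pipeline(foxo3_config(out1))
  res2 <- run_pipeline(foxo3_config(out2))
  expect_equal(glance(res1$annotations)$n_phospho_pred, 72)
  expect_equal(res1$transfers$dst_pos, c(248L, 250L))
  # conservation recomputed from the alignment agrees with the curated flags
  expect_equal(res1$annotations$conserved,
               foxo3_site_scores()$conserved)
  for (f in names(res1$files)) {
    expect_identical(readLines(res1$files[[f]]), readLines(res2$files[[f]]))
  }
  # published neighbor pairs fall out of the reports
  expect_true(all(c(248, 250) %in% res1$neighbors$methyl_pos))
  expect_true(any(res1$neighbors$methyl_pos == 207 &
                    res1$neighbors$phospho_pos == 209))
})

test_that("pipeline configs are validated", {
  cfg <- foxo3_config(withr::local_tempdir())
  cfg$min_agree <- 4
  expect_error(run_pipeline(cfg), class = "ptmtalk_usage_error")

  cfg2 <- foxo3_config(withr::local_tempdir())
  cfg2$site_scores <- "/nonexistent/scores.tsv"
  expect_error(run_pipeline(cfg2), "scores.tsv",
               class = "ptmtalk_io_error")

  cfg3 <- foxo3_config(withr::local_tempdir())
  cfg3$bogus_key <- 1
  expect_error(run_pipeline(cfg3), "bogus_key",
               class = "ptmtalk_usage_error")
})

test_that("yaml configs load like lists", {
  out <- withr::local_tempdir()
  cfg <- foxo3_config(out)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  res <- run_pipeline(path)
  expect_equal(glance(res$annotations)$n_yy_positive, 19)
})

test_that("result objects expose tidy, glance and autoplot", {
  ann <- foxo3_annotations()
  td <- tidy(ann)
  expect_false(inherits(td, "yy_annotation"))
  expect_type(td$kinases, "character")
  gl <- glance(ann)
  expect_equal(gl$n_sites, 97)
  p1 <- ggplot2::autoplot(ann, domains = foxo3_domains())
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(conservation_profile(foxo3_msa()))
  expect_s3_class(p2, "ggplot")
  p3 <- plot_classification_summary(summarize_classifications(ann))
  expect_s3_class(p3, "ggplot")
})
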