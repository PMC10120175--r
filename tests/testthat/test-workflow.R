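test_that("config validation rejects bad enums, pairs and dpi", {
  expect_error(study_config(procedure = "XXX"), "arg")
  expect_error(study_config(design = "triple"), "arg")
  expect_error(study_config(stability_pair = c(3, 2)), "increasing")
  expect_error(study_config(stability_pair = c(1, 9)), "1..5")
  expect_error(study_config(dpi_panel = 0), "dpi")
})

test_that("a single-group run computes all panels and no between-group statistics", {
  tr <- simulate_trial("trial2", dir = withr::local_tempdir(), n_eyes = 30, seed = 101)
  res <- run_analysis(tr$paths[1], config = tr$config)
  expect_s3_class(res, "refr_run")
  expect_named(res$panels, LETTERS[1:10])
  expect_true(all(is.na(tidy(res)$p_value)))
  expect_equal(nrow(glance(res)), 1)
})

test_that("a paired two-group run attaches paired tests to the analysis panels", {
  tr <- simulate_trial("trial1", dir = withr::local_tempdir(), n_eyes = 30, seed = 102)
  res <- run_analysis(tr$paths[1], tr$paths[2], config = tr$config)
  st <- tidy(res)
  with_test <- st[!is.na(st$p_value), ]
  expect_setequal(with_test$panel, c("A", "B", "C", "D", "F", "G", "I", "J"))
  expect_true(all(with_test$test %in% c("paired-t", "wilcoxon-signed-rank")))
  expect_equal(res$panels$F$variant, "stability")
})

test_that("design/file mismatches are rejected", {
  tr <- simulate_trial("trial3", dir = withr::local_tempdir(), n_eyes = 10, seed = 103)
  expect_error(
    run_analysis(tr$paths[1], config = study_config(design = "unpaired")),
    "two cohorts"
  )
  expect_error(
    run_analysis(tr$paths[1], tr$paths[2], config = study_config(design = "single")),
    "one cohort"
  )
})

test_that("the cataract baseline switch compares UDVA to postoperative CDVA", {
  d <- simulate_cohort(scenario(
    n_eyes = 40,
    preop_cdva_lines = c(32, 40), preop_cdva_probs = c(0.5, 0.5),
    cdva_change_probs = c("2" = 1), # everyone gains two lines of CDVA
    seed = 104
  ))
  lvc <- run_analysis(d, config = study_config(procedure = "LVC", design = "single"))
  cat_run <- run_analysis(d, config = study_config(procedure = "CAT", design = "single"))
  eff_lvc <- lvc$panels$B$annotations[[1]]$efficacy_index
  eff_cat <- cat_run$panels$B$annotations[[1]]$efficacy_index
  # against the better postop CDVA baseline the index must drop
  expect_lt(eff_cat, eff_lvc)
  expect_equal(
    cat_run$cohorts[[1]]$baseline_cdva_logmar,
    cat_run$cohorts[[1]]$postop_cdva_logmar
  )
  # RLE keeps the preop baseline
  rle <- run_analysis(d, config = study_config(procedure = "RLE", design = "single"))
  expect_equal(eff_lvc, rle$panels$B$annotations[[1]]$efficacy_index)
})

test_that("runs are deterministic end to end", {
  tr <- simulate_trial("trial3", dir = withr::local_tempdir(), n_eyes = 25, seed = 105)
  r1 <- run_analysis(tr$paths[1], tr$paths[2], config = tr$config)
  r2 <- run_analysis(tr$paths[1], tr$paths[2], config = tr$config)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$panels, r2$panels)
})

test_that("rendering writes per-panel and composite TIFFs with the configured resolution", {
  tr <- simulate_trial("trial3", dir = withr::local_tempdir(), n_eyes = 20, seed = 106)
  out <- withr::local_tempdir()
  cfg <- tr$config
  cfg$dpi_panel <- 96
  cfg$dpi_composite <- 150 # small for a fast unit check; defaults exercised in acceptance
  res <- run_analysis(tr$paths[1], tr$paths[2], config = cfg, out_dir = out)

  m <- res$manifest
  expect_equal(sum(m$panel %in% LETTERS[1:10]), 10)
  expect_equal(sum(m$panel == "composite"), 1)
  expect_true(all(file.exists(m$file)))
  expect_true(all(grepl("Biometer", basename(m$file[m$panel == "A"]))))

  img <- tiff::readTIFF(m$file[m$panel == "A"], info = TRUE)
  expect_equal(attr(img, "x.resolution"), 96)
  comp <- tiff::readTIFF(m$file[m$panel == "composite"], info = TRUE)
  expect_equal(attr(comp, "x.resolution"), 150)

  expect_true(file.exists(file.path(out, "stats_summary.csv")))
  st <- readr::read_csv(file.path(out, "stats_summary.csv"), show_col_types = FALSE)
  expect_true(all(c("panel", "variable", "test", "p_value", "effect_size_d") %in% names(st)))
})

test_that("panel and run autoplot methods return plottable objects", {
  d <- add_derived_outcomes(perfect_cohort(15, seed = 107))
  panels <- compute_panels(list(G1 = d), study_config(design = "single"))
  for (id in c("A", "C", "E", "I")) {
    expect_s3_class(autoplot(panels[[id]]), "ggplot")
  }
  res <- run_analysis(perfect_cohort(15, seed = 108),
                      config = study_config(design = "single"))
  expect_s3_class(autoplot(res), "patchwork")
})

test_that("the command-line wrapper script is shipped and well-formed", {
  script <- system.file("scripts", "analyze.R", package = "refracto")
  expect_true(nzchar(script))
  expect_no_error(parse(script))
})
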