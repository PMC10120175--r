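two_cohorts <- function(n = 40, seeds = c(81, 82), ...) {
  list(
    A = add_derived_outcomes(simulate_cohort(scenario(n_eyes = n, seed = seeds[1], ...))),
    B = add_derived_outcomes(simulate_cohort(scenario(n_eyes = n, seed = seeds[2], ...)))
  )
}

test_that("threshold binning counts |value| <= t inclusively", {
  w <- within_thresholds(c(0, 0.25, -0.30, 0.60), c(0.25, 0.5, 0.75, 1))
  expect_equal(w$percent, c(50, 75, 100, 100))
  expect_equal(within_thresholds(rep(0, 9), c(0.25, 0.5))$percent, c(100, 100))
  expect_error(within_thresholds(numeric(0), 0.5), "non-empty")
  expect_error(within_thresholds(1, c(0.5, 0.25)), "ascending")
})

test_that("cumulative acuity curves count each line or better and are monotone", {
  cfg <- acuity_config()
  all2020 <- cumulative_va(rep(0, 12), cfg)
  expect_equal(all2020$percent[all2020$line == 16], 0)
  expect_equal(all2020$percent[all2020$line == 20], 100)
  expect_equal(all2020$percent[all2020$line == 25], 100)

  mixed <- cumulative_va(snellen_to_logmar(c(16, 25), 0), cfg)
  expect_equal(mixed$percent[mixed$line == 16], 50)
  expect_equal(mixed$percent[mixed$line == 20], 50)
  expect_equal(mixed$percent[mixed$line == 25], 100)

  for (s in 1:5) {
    lm_rand <- withr::with_seed(s, runif(50, -0.2, 1))
    expect_true(all(diff(cumulative_va(lm_rand, cfg)$percent) >= 0))
  }
})

test_that("line-change histograms bin into the five standard categories", {
  expect_equal(
    line_change_histogram(rep(0L, 7)),
    tibble::tibble(
      bin = factor(refracto:::line_change_bins(), refracto:::line_change_bins()),
      percent = c(0, 0, 100, 0, 0)
    )
  )
  one_each <- line_change_histogram(c(-4L, -1L, 0L, 1L, 3L))
  expect_equal(one_each$percent, rep(20, 5))
  expect_equal(sum(one_each$percent), 100)
})

test_that("stability series reports per-timepoint summaries and strict >0.50 D changes", {
  d <- simulate_cohort(scenario(
    n_eyes = 10, n_timepoints = 5,
    seq_bias = 0, seq_sd = 0, ci_mean = 1, ci_sd = 0, axis_error_sd = 0,
    drift_per_timepoint = 0, stability_noise_sd = 0, seed = 83
  ))
  s <- stability_series(d, selected_pair = c(2, 5))
  expect_equal(s$changed$percent, 0)
  expect_equal(nrow(s$series), 6) # preop + 5 timepoints
  expect_equal(s$series$n, rep(10L, 6))

  # shift 3 of 10 eyes by 0.75 D after timepoint 2; a 0.50 D change is NOT counted
  d2 <- d
  d2$seq_5[1:3] <- d2$seq_5[1:3] + 0.75
  d2$seq_5[4] <- d2$seq_5[4] + 0.50
  s2 <- stability_series(d2, selected_pair = c(2, 5))
  expect_equal(s2$changed$percent, 30)

  expect_error(stability_series(d, selected_pair = c(1, 9)), "stability pair")
  expect_error(
    stability_series(simulate_cohort(scenario(n_eyes = 5, seed = 84))),
    "time points"
  )
})

test_that("every histogram partition sums to 100 percent of included eyes", {
  cohorts <- two_cohorts()
  cfg <- study_config(design = "unpaired")
  panels <- compute_panels(cohorts, cfg)
  for (id in c("B", "C", "I", "J")) {
    sums <- dplyr::summarize(
      dplyr::group_by(panels[[id]]$series, group),
      s = sum(percent)
    )
    expect_equal(sums$s, rep(100, 2), tolerance = 0.01, info = id)
  }
})

test_that("panel content honors thresholds, group count and test attachment", {
  cohorts <- two_cohorts()
  cfg <- study_config(design = "unpaired")
  g <- compute_panel("G", cohorts, cfg)
  expect_equal(unique(g$series$threshold), c(0.5, 0.75, 1))
  f <- compute_panel("F", cohorts, cfg)
  expect_equal(f$variant, "deq")
  expect_equal(unique(f$series$threshold), c(0.25, 0.5, 0.75, 1, 2))
  expect_s3_class(g$stat, "refr_compare")

  single <- compute_panels(cohorts["A"], study_config(design = "single"))
  expect_true(all(vapply(single, function(p) is.null(p$stat), logical(1))))

  expect_error(compute_panel("Z", cohorts, cfg), "Unknown panel")
})

test_that("panel computation is deterministic", {
  cohorts <- two_cohorts()
  cfg <- study_config(design = "unpaired")
  expect_identical(compute_panels(cohorts, cfg), compute_panels(cohorts, cfg))
})

test_that("CDVA cumulative curve dominates UDVA when every eye's CDVA is at least as good", {
  d <- add_derived_outcomes(simulate_cohort(scenario(n_eyes = 60, seed = 85)))
  expect_true(all(d$postop_cdva_logmar <= d$postop_udva_logmar + 1e-9))
  cfg <- acuity_config()
  cdva_curve <- cumulative_va(d$postop_cdva_logmar, cfg)$percent
  udva_curve <- cumulative_va(d$postop_udva_logmar, cfg)$percent
  expect_true(all(cdva_curve >= udva_curve))
})

test_that("a perfect cohort drives every panel to its ideal", {
  cohorts <- list(P = add_derived_outcomes(perfect_cohort(30, seed = 86)))
  cfg <- study_config(design = "single")
  panels <- compute_panels(cohorts, cfg)

  expect_equal(panels$B$annotations$P$efficacy_index, 1, tolerance = 1e-9)
  expect_equal(panels$C$annotations$P$safety_index, 1, tolerance = 1e-9)
  expect_equal(panels$D$series$percent[1], 100) # all within 0.25 D
  expect_equal(panels$G$series$percent[1], 100) # all within 0.50 D
  expect_equal(panels$E$annotations$P$fit$slope, 1, tolerance = 1e-9)
  expect_equal(panels$E$annotations$P$fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(panels$I$annotations$P$ci$mean, 1, tolerance = 1e-9)
  expect_equal(panels$J$annotations$P$aoe$mean, 0, tolerance = 1e-9)
})

test_that("excluded zero-TIA eyes are counted separately on the CI and AoE panels", {
  d <- perfect_cohort(20, seed = 87)
  # make 4 eyes spherical pre and post: no intended astigmatic change
  for (col in c("preop_cylinder", "postop_cylinder")) d[[col]][1:4] <- 0
  dd <- add_derived_outcomes(d)
  panels <- compute_panels(list(P = dd), study_config(design = "single"))
  expect_equal(panels$I$annotations$P$n_excluded, 4)
  expect_equal(panels$I$annotations$P$n, 16)
  expect_equal(panels$J$annotations$P$n_excluded, 4)
})
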