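test_that("normality screen accepts normal samples and rejects skewed ones", {
  hits <- withr::with_seed(61, {
    vapply(1:100, function(i) normality_p(rnorm(500)) > 0.05, logical(1))
  })
  expect_gte(mean(hits), 0.95)

  rejections <- withr::with_seed(62, {
    vapply(1:100, function(i) normality_p(rexp(500)) < 0.05, logical(1))
  })
  expect_gte(mean(rejections), 0.99)

  expect_true(is.na(normality_p(rep(1, 50)))) # degenerate variance
  expect_true(is.na(normality_p(c(1, 2, 3, 4)))) # too small to assess
})

test_that("test dispatch picks the parametric branch only when both samples pass", {
  norm_a <- withr::with_seed(63, rnorm(100))
  norm_b <- withr::with_seed(64, rnorm(100))
  skew <- withr::with_seed(65, rexp(100))

  expect_equal(compare_samples(norm_a, norm_b, "unpaired")$test, "unpaired-t")
  expect_equal(compare_samples(norm_a, skew, "unpaired")$test, "mann-whitney-u")
  expect_equal(compare_samples(skew, skew + 0.1, "unpaired")$test, "mann-whitney-u")
  expect_equal(compare_samples(norm_a, norm_b, "paired")$test, "paired-t")
  expect_equal(compare_samples(skew, norm_a, "paired")$test, "wilcoxon-signed-rank")
})

test_that("identical paired samples give a null result, not an error", {
  a <- withr::with_seed(66, rnorm(30))
  r <- compare_samples(a, a, "paired")
  expect_equal(r$p_value, 1)
  expect_equal(r$effect_size_d, 0)
})

test_that("a d = 1 shift at n = 200 is detected with high power", {
  rejected <- withr::with_seed(67, {
    vapply(1:50, function(i) {
      compare_samples(rnorm(200), rnorm(200, 1), "unpaired")$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejected), 0.99)
})

test_that("Cohen's d follows the pooled-SD and paired definitions", {
  x <- withr::with_seed(68, rnorm(40))
  expect_equal(cohens_d(x, x, "unpaired"), 0)
  # worked example: pooled SD sqrt(2.5), mean difference -2
  expect_equal(
    cohens_d(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7), "unpaired"),
    -2 / sqrt(2.5),
    tolerance = 1e-9
  )
  expect_equal(round(cohens_d(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7), "unpaired"), 3), -1.265)
  # sign convention follows mean(a) - mean(b)
  expect_gt(cohens_d(x + 1, x, "unpaired"), 0)
  # constant non-zero paired difference: not computable
  expect_true(is.na(cohens_d(x + 1, x, "paired")))
})

test_that("line fits match the closed-form normal equations", {
  x <- withr::with_seed(69, runif(50, -3, 3))
  f <- fit_line(x, x)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_line(x, 2 * x + 1)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)

  y <- withr::with_seed(70, rnorm(50, 0.5, 2))
  fr <- fit_line(x, y)
  sxx <- sum((x - mean(x))^2)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(fr$slope, beta, tolerance = 1e-10)
  expect_equal(fr$intercept, mean(y) - beta * mean(x), tolerance = 1e-10)

  ynull <- withr::with_seed(71, rnorm(1000))
  xnull <- withr::with_seed(72, rnorm(1000))
  expect_lt(fit_line(xnull, ynull)$r_squared, 0.01)
  expect_error(fit_line(rep(1, 10), rnorm(10)), "constant x")
})

test_that("descriptive summaries use the n-1 sample SD", {
  expect_equal(summarize_sample(c(1, 1, 1)), tibble::tibble(mean = 1, sd = 0, n = 3L, single = FALSE))
  s <- summarize_sample(c(0, 2))
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  s1 <- summarize_sample(5)
  expect_equal(s1$sd, 0)
  expect_true(s1$single)
  expect_error(summarize_sample(numeric(0)), "empty")
})

test_that("tidy and glance expose the comparison in broom shape", {
  r <- compare_samples(withr::with_seed(73, rnorm(50)), withr::with_seed(74, rnorm(50)), "unpaired")
  td <- tidy(r)
  expect_named(td, c("test", "statistic", "p.value", "effect.size.d", "n.a", "n.b"))
  gl <- glance(r)
  expect_true(all(c("normality.p.a", "mean.a", "sd.b") %in% names(gl)))
})
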