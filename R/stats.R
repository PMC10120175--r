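#' Normality screening p-value
#'
#' P-value of a Kolmogorov-Smirnov-type test of composite normality with the
#' Lilliefors small-sample correction (the naive KS test with estimated mean
#' and SD is anticonservative). Samples that cannot be assessed — fewer than
#' 5 observations or zero variance — return `NA` and are treated as
#' non-normal by the dispatcher.
#'
#' @param x Numeric sample.
#' @return A single p-value, or `NA_real_` if the sample is not assessable.
#' @export
normality_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5 || sd(x) < 1e-12) return(NA_real_)
  nortest::lillie.test(x)$p.value
}

#' Compare two samples with automatic test dispatch
#'
#' Screens both samples for normality with [normality_p()] at `alpha`; if
#' both pass, the parametric test is used (unpaired or paired t-test,
#' matching `design`), otherwise the corresponding nonparametric test
#' (Mann-Whitney U, or Wilcoxon signed-rank for paired data). Tests are
#' two-sided. Cohen's d is always attached, computed from means and SDs
#' regardless of the branch taken, so effect sizes remain comparable across
#' panels.
#'
#' @param a,b Numeric samples. Paired designs require equal lengths with
#'   aligned rows; rows where either value is missing are dropped pairwise.
#' @param design `"unpaired"` or `"paired"`.
#' @param alpha Significance level for the normality screen (and the
#'   conventional p < 0.05 significance threshold).
#' @return A one-row tibble of class `refr_compare`: `test`, `statistic`,
#'   `p_value`, `effect_size_d`, `n_a`, `n_b`, `normality_p_a`,
#'   `normality_p_b`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @examples
#' compare_samples(rnorm(50), rnorm(50, 1), design = "unpaired")
#' @export
compare_samples <- function(a, b, design = c("unpaired", "paired"), alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(a) != length(b)) {
      abort("Paired comparison requires equal-length, row-aligned samples.")
    }
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]
    b <- b[ok]
  } else {
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
  }
  if (length(a) < 2 || length(b) < 2) {
    abort("Each sample needs at least 2 finite observations.")
  }
  np_a <- normality_p(a)
  np_b <- normality_p(b)
  both_normal <- !is.na(np_a) && !is.na(np_b) && np_a >= alpha && np_b >= alpha

  if (design == "unpaired") {
    if (both_normal) {
      ht <- t.test(a, b, var.equal = FALSE)
      test <- "unpaired-t"
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      test <- "mann-whitney-u"
    }
  } else {
    d <- a - b
    if (sd(d) < 1e-12) {
      # identical pairs: no evidence of any effect
      ht <- list(statistic = c(stat = 0), p.value = 1)
      test <- "paired-t"
    } else if (both_normal) {
      ht <- t.test(a, b, paired = TRUE)
      test <- "paired-t"
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
      test <- "wilcoxon-signed-rank"
    }
  }

  out <- tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    effect_size_d = cohens_d(a, b, design),
    n_a = length(a),
    n_b = length(b),
    normality_p_a = np_a,
    normality_p_b = np_b,
    mean_a = mean(a),
    sd_a = sd(a),
    mean_b = mean(b),
    sd_b = sd(b)
  )
  class(out) <- c("refr_compare", class(out))
  out
}

#' Cohen's d effect size
#'
#' Unpaired: difference in means over the pooled SD (n - 1 weights); the
#' sign follows `mean(a) - mean(b)`. Paired: mean of the differences over
#' their SD. A degenerate (zero) denominator yields `NA` — not computable —
#' rather than an infinite effect.
#'
#' @inheritParams compare_samples
#' @return A single signed d (interpretation: |d| < 0.20 is conventionally
#'   not clinically relevant).
#' @export
cohens_d <- function(a, b, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(a) != length(b)) abort("Paired d requires equal-length samples.")
    d <- a - b
    s <- sd(d)
    if (!is.finite(s) || s < 1e-12) {
      # identical pairs are a genuine null effect; a constant non-zero
      # difference has no spread to scale by and is not computable
      return(if (abs(mean(d)) < 1e-12) 0 else NA_real_)
    }
    mean(d) / s
  } else {
    na <- length(a)
    nb <- length(b)
    pooled <- sqrt(((na - 1) * sd(a)^2 + (nb - 1) * sd(b)^2) / (na + nb - 2))
    if (!is.finite(pooled) || pooled < 1e-12) return(NA_real_)
    (mean(a) - mean(b)) / pooled
  }
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` and reports the squared Pearson
#' correlation, for the attempted-vs-achieved scattergrams.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("Line fit needs at least 3 complete observations.")
  if (sd(x) < 1e-12) abort("Line fit is undefined for constant x.")
  fit <- lm(y ~ x)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = cor(x, y)^2,
    n = length(x)
  )
}

#' Mean, SD and count
#'
#' The descriptive summary displayed on every panel: arithmetic mean, sample
#' standard deviation (n - 1 denominator; reported as 0 when n = 1, with the
#' `single` flag set) and the number of observations.
#'
#' @param x Numeric sample (non-empty after removing missing values).
#' @return A one-row tibble: `mean`, `sd`, `n`, `single`.
#' @export
summarize_sample <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) abort("Cannot summarize an empty sample.")
  tibble::tibble(
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    n = length(x),
    single = length(x) == 1
  )
}
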