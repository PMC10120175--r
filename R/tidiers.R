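#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-sample comparison
#'
#' @param x A `refr_compare` row from [compare_samples()].
#' @param ... Unused.
#' @return A one-row tibble with `test`, `statistic`, `p.value`,
#'   `effect.size.d`, `n.a`, `n.b`.
#' @method tidy refr_compare
#' @export
tidy.refr_compare <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    p.value = x$p_value,
    effect.size.d = x$effect_size_d,
    n.a = x$n_a,
    n.b = x$n_b
  )
}

#' @rdname tidy.refr_compare
#' @method glance refr_compare
#' @export
glance.refr_compare <- function(x, ...) {
  tibble::tibble(
    normality.p.a = x$normality_p_a,
    normality.p.b = x$normality_p_b,
    mean.a = x$mean_a, sd.a = x$sd_a,
    mean.b = x$mean_b, sd.b = x$sd_b
  )
}

#' Tidy an analysis run
#'
#' `tidy()` returns the per-panel statistics table (one row per panel:
#' analysis variable, dispatched test, p-value, Cohen's d, group sizes);
#' `glance()` a one-row-per-group summary of the headline quantities
#' (efficacy and safety indices, mean SEQ error, mean correction index).
#'
#' @param x A `refr_run` from [run_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy refr_run
#' @export
tidy.refr_run <- function(x, ...) {
  x$stats
}

#' @rdname tidy.refr_run
#' @method glance refr_run
#' @export
glance.refr_run <- function(x, ...) {
  purrr::imap_dfr(x$cohorts, function(d, g) {
    ann_b <- x$panels$B$annotations[[g]]
    ann_c <- x$panels$C$annotations[[g]]
    tibble::tibble(
      group = g,
      n = nrow(d),
      efficacy.index = ann_b$efficacy_index,
      safety.index = ann_c$safety_index,
      mean.seq.error = mean(d$seq_error),
      mean.correction.index = mean(d$correction_index, na.rm = TRUE)
    )
  })
}

#' One-page figure of all panels
#'
#' Assembles the ten panel plots of a run into the fixed 2 x 5 composite
#' grid (a ggplot/patchwork object; print or save it).
#'
#' @param object A `refr_run`.
#' @param ... Unused.
#' @return A patchwork object.
#' @method autoplot refr_run
#' @export
autoplot.refr_run <- function(object, ...) {
  plots <- purrr::map(object$panels, autoplot, config = object$config)
  patchwork::wrap_plots(plots, ncol = 2, byrow = TRUE)
}
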