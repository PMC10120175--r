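# Panel content computation: everything a standard graph displays, computed
# and binned, decoupled from rendering. Panels are identified A..J:
#   A cumulative UDVA/CDVA        B UDVA vs baseline CDVA difference
#   C CDVA line change            D SEQ accuracy to target
#   E attempted vs achieved SEQ   F SEQ stability (or DEQ accuracy)
#   G postop refractive astigmatism  H TIA vs SIA
#   I correction index            J angle of error

panel_ids <- function() LETTERS[1:10]

#' Percentage of eyes within accuracy thresholds
#'
#' For each threshold `t`, the percentage of eyes with `|value| <= t`
#' (inclusive boundary), as displayed on the SEQ, DEQ and astigmatism
#' accuracy histograms.
#'
#' @param values Numeric vector of signed errors or magnitudes, diopters.
#' @param thresholds Positive ascending thresholds, diopters.
#' @return A tibble with `threshold`, `percent`.
#' @export
within_thresholds <- function(values, thresholds) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("Threshold binning needs a non-empty sample.")
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be positive and ascending.")
  }
  tibble::tibble(
    threshold = thresholds,
    percent = vapply(thresholds, function(t) 100 * mean(abs(values) <= t), numeric(1))
  )
}

#' Cumulative Snellen acuity distribution
#'
#' For each configured chart line, the percentage of eyes seeing that line
#' or better (LogMAR at or below the line's threshold, with a small
#' tolerance so an eye exactly on a line counts). Monotone non-decreasing
#' from best to worst line.
#'
#' @param logmars Numeric vector of LogMAR acuities.
#' @param cfg An [acuity_config()]; its `snellen_lines` define the x-axis.
#' @return A tibble with `line` (denominator), `logmar_threshold`,
#'   `percent`.
#' @export
cumulative_va <- function(logmars, cfg = acuity_config()) {
  logmars <- logmars[is.finite(logmars)]
  if (!length(logmars)) abort("Cumulative acuity needs a non-empty sample.")
  thr <- log10(cfg$snellen_lines / 20)
  tibble::tibble(
    line = cfg$snellen_lines,
    logmar_threshold = thr,
    percent = vapply(thr, function(t) 100 * mean(logmars <= t + 1e-9), numeric(1))
  )
}

line_change_bins <- function() c("<=-2", "-1", "0", "+1", ">=+2")

#' Line-change histogram
#'
#' Bins per-eye line changes into the standard five categories with
#' open-ended extremes: two or more lines lost, one lost, unchanged, one
#' gained, two or more gained.
#'
#' @param changes Integer vector of per-eye line changes (positive = gained).
#' @return A tibble with `bin` (ordered factor) and `percent`; percentages
#'   sum to 100 over the included eyes.
#' @export
line_change_histogram <- function(changes) {
  changes <- changes[is.finite(changes)]
  if (!length(changes)) abort("Line-change histogram needs a non-empty sample.")
  binned <- cut(changes, breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf), labels = line_change_bins())
  counts <- table(binned)
  tibble::tibble(
    bin = factor(line_change_bins(), levels = line_change_bins()),
    percent = 100 * as.numeric(counts) / length(changes)
  )
}

#' SEQ stability over time
#'
#' Per-timepoint mean, SD and N of the spherical equivalent — the
#' preoperative SEQ followed by up to five postoperative time points — plus
#' the percentage of eyes whose SEQ changed by strictly more than 0.50 D
#' between two selected time points (computed over eyes present at both).
#'
#' @param data A cohort tibble with populated `seq_1`..`seq_5` columns.
#' @param selected_pair Integer pair of postoperative timepoint indices
#'   (1-5) to compare, e.g. `c(2, 5)` for 3 vs 24 months under a
#'   1/3/6/12/24-month schedule.
#' @param change_threshold Diopters; the change counted is strictly greater
#'   than this (default 0.50).
#' @return A list with `series` (tibble: `timepoint`, `label`, `mean`, `sd`,
#'   `n`) and `changed` (list: `percent`, `n`, `pair`).
#' @export
stability_series <- function(data, selected_pair = NULL, change_threshold = 0.5) {
  cols <- paste0("seq_", 1:5)
  populated <- cols[vapply(cols, function(c) any(is.finite(data[[c]])), logical(1))]
  if (length(populated) < 2) {
    abort("Stability needs at least 2 populated postoperative SEQ time points.")
  }
  preop_seq <- spherical_equivalent(data$preop_sphere, data$preop_cylinder)
  series <- dplyr::bind_rows(
    dplyr::mutate(summarize_sample(preop_seq), timepoint = 0L, label = "preop"),
    purrr::map_dfr(populated, function(c) {
      dplyr::mutate(summarize_sample(data[[c]]),
        timepoint = as.integer(sub("seq_", "", c)), label = c
      )
    })
  )
  series <- dplyr::select(series, "timepoint", "label", "mean", "sd", "n")

  if (is.null(selected_pair)) {
    idx <- as.integer(sub("seq_", "", populated))
    selected_pair <- c(idx[1], idx[length(idx)])
  }
  pair_cols <- paste0("seq_", selected_pair)
  if (!all(pair_cols %in% populated)) {
    abort(paste0(
      "Selected stability pair (", paste(selected_pair, collapse = ", "),
      ") refers to unpopulated time points; populated: ",
      paste(sub("seq_", "", populated), collapse = ", "), "."
    ))
  }
  s1 <- data[[pair_cols[1]]]
  s2 <- data[[pair_cols[2]]]
  both <- is.finite(s1) & is.finite(s2)
  delta <- s2[both] - s1[both]
  list(
    series = series,
    changed = list(
      percent = 100 * mean(abs(delta) > change_threshold),
      n = sum(both),
      pair = selected_pair,
      deltas = delta
    )
  )
}

#' Per-eye derived outcomes used by the panels
#'
#' Appends to a cohort tibble every per-eye quantity the standard graphs
#' consume: spherical and defocus equivalents (at the plane chosen by
#' `seq_plane`), SEQ error to target, attempted/achieved SEQ change, line
#' changes against the design baseline, and the Alpins vector outcomes
#' (always at the corneal plane).
#'
#' @param data A cohort tibble from [read_cohort()] or [simulate_cohort()].
#' @param baseline `"preop"` (LVC/RLE/ICL) or `"postop"` (cataract): which
#'   CDVA the UDVA-difference panel and efficacy index are measured against.
#' @param seq_plane `"entered"` (the vertex the user recorded, the default)
#'   or `"corneal"`: the plane at which SEQ-based panels are computed.
#' @return The input tibble with derived columns appended.
#' @export
add_derived_outcomes <- function(data, baseline = c("preop", "postop"),
                                 seq_plane = c("entered", "corneal")) {
  baseline <- match.arg(baseline)
  seq_plane <- match.arg(seq_plane)

  blocks <- list(
    preop = c("preop_sphere", "preop_cylinder"),
    target = c("target_sphere", "target_cylinder"),
    postop = c("postop_sphere", "postop_cylinder")
  )
  sc <- purrr::imap(blocks, function(cols, prefix) {
    if (seq_plane == "corneal") {
      p <- propagate_vertex(
        data[[cols[1]]], data[[cols[2]]],
        data[[paste0(prefix, "_axis")]], data[[paste0(prefix, "_vertex")]],
        target_vertex = 0
      )
      list(sphere = p$sphere, cylinder = p$cylinder)
    } else {
      list(sphere = data[[cols[1]]], cylinder = data[[cols[2]]])
    }
  })

  baseline_logmar <- if (baseline == "preop") data$preop_cdva_logmar else data$postop_cdva_logmar

  data <- dplyr::mutate(
    data,
    preop_seq = spherical_equivalent(sc$preop$sphere, sc$preop$cylinder),
    attempted_seq = spherical_equivalent(sc$target$sphere, sc$target$cylinder) - .data$preop_seq,
    achieved_seq = spherical_equivalent(sc$postop$sphere, sc$postop$cylinder) - .data$preop_seq,
    seq_error = spherical_equivalent(sc$postop$sphere, sc$postop$cylinder) -
      spherical_equivalent(sc$target$sphere, sc$target$cylinder),
    postop_deq = defocus_equivalent(sc$postop$sphere, sc$postop$cylinder),
    baseline_cdva_logmar = baseline_logmar,
    udva_line_diff = line_change(baseline_logmar, .data$postop_udva_logmar),
    cdva_line_change = line_change(.data$preop_cdva_logmar, .data$postop_cdva_logmar)
  )
  add_vector_outcomes(data)
}

#' Compute the content of one standard panel
#'
#' Assembles the series and annotations of a single panel for one or two
#' groups. Two-group runs attach the automatic comparison ([compare_samples()])
#' on the panel's analysis variable where one is defined (A/B: postop UDVA
#' LogMAR; C: CDVA line change; D: SEQ error; F: stability-pair SEQ change
#' or DEQ; G: postop astigmatism magnitude; I: correction index; J: angle of
#' error; E and H carry regressions, not tests).
#'
#' @param panel_id One of `"A"`..`"J"`.
#' @param cohorts A named list of one or two cohort tibbles that already
#'   carry derived outcomes ([add_derived_outcomes()]).
#' @param config A [study_config()].
#' @return A `panel_data` object: a list with `panel_id`, `title`, `y_axis`,
#'   `series` (tibble with a `group` column), `annotations` (named list per
#'   group), `stat` (a `refr_compare` row or NULL), `excluded` (per-group
#'   counts of eyes excluded from this panel).
#' @export
compute_panel <- function(panel_id, cohorts, config = study_config()) {
  if (!panel_id %in% panel_ids()) {
    abort(paste0("Unknown panel id \"", panel_id, "\"; expected one of A..J."))
  }
  builder <- switch(panel_id,
    A = panel_cumulative_va,
    B = panel_udva_diff,
    C = panel_cdva_change,
    D = panel_seq_accuracy,
    E = panel_attempted_achieved,
    F = panel_stability_or_deq,
    G = panel_astig_accuracy,
    H = panel_tia_sia,
    I = panel_correction_index,
    J = panel_angle_of_error
  )
  out <- builder(cohorts, config)
  out$panel_id <- panel_id
  out$groups <- names(cohorts)
  class(out) <- "panel_data"
  out
}

#' Compute all ten standard panels
#'
#' @inheritParams compute_panel
#' @return A named list of `panel_data` objects, `A`..`J`.
#' @export
compute_panels <- function(cohorts, config = study_config()) {
  out <- purrr::map(panel_ids(), compute_panel, cohorts = cohorts, config = config)
  stats::setNames(out, panel_ids())
}

two_group <- function(cohorts) length(cohorts) == 2

panel_stat <- function(cohorts, config, var, paired_complete = FALSE) {
  if (!two_group(cohorts)) return(NULL)
  a <- cohorts[[1]][[var]]
  b <- cohorts[[2]][[var]]
  design <- if (config$design == "paired") "paired" else "unpaired"
  if (design == "paired" && paired_complete) {
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]
    b <- b[ok]
  }
  tryCatch(compare_samples(a, b, design = design),
    error = function(e) NULL
  )
}

group_annotations <- function(cohorts, f) {
  purrr::map(cohorts, f)
}

panel_cumulative_va <- function(cohorts, config) {
  cfg <- config$acuity
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    dplyr::bind_rows(
      dplyr::mutate(cumulative_va(d$postop_udva_logmar, cfg), measure = "Postop UDVA"),
      dplyr::mutate(cumulative_va(d$baseline_cdva_logmar, cfg), measure = "Baseline CDVA")
    ) |> dplyr::mutate(group = g)
  })
  list(
    title = "Cumulative Snellen visual acuity",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      list(
        n = nrow(d),
        preop_cdva = summarize_sample(d$preop_cdva_logmar),
        postop_cdva = summarize_sample(d$postop_cdva_logmar),
        postop_udva = summarize_sample(d$postop_udva_logmar)
      )
    }),
    stat = panel_stat(cohorts, config, "postop_udva_logmar")
  )
}

panel_udva_diff <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    dplyr::mutate(line_change_histogram(d$udva_line_diff), group = g)
  })
  list(
    title = "Postop UDVA vs baseline CDVA (lines)",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      list(
        n = nrow(d),
        efficacy_index = efficacy_index(
          d$postop_udva_logmar, d$baseline_cdva_logmar,
          per_eye = config$per_eye_index
        )
      )
    }),
    stat = panel_stat(cohorts, config, "postop_udva_logmar")
  )
}

panel_cdva_change <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    dplyr::mutate(line_change_histogram(d$cdva_line_change), group = g)
  })
  list(
    title = "Change in lines of CDVA",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      list(
        n = nrow(d),
        safety_index = safety_index(
          d$postop_cdva_logmar, d$baseline_cdva_logmar,
          per_eye = config$per_eye_index
        )
      )
    }),
    stat = panel_stat(cohorts, config, "cdva_line_change")
  )
}

panel_seq_accuracy <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    dplyr::mutate(within_thresholds(d$seq_error, config$seq_thresholds), group = g)
  })
  list(
    title = "SEQ accuracy to intended target",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      list(n = nrow(d), seq_error = summarize_sample(d$seq_error))
    }),
    stat = panel_stat(cohorts, config, "seq_error")
  )
}

panel_attempted_achieved <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    tibble::tibble(x = d$attempted_seq, y = d$achieved_seq, group = g)
  })
  list(
    title = "Attempted vs achieved SEQ",
    y_axis = "diopters",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      fit <- tryCatch(fit_line(d$attempted_seq, d$achieved_seq), error = function(e) NULL)
      list(
        n = nrow(d),
        fit = fit,
        attempted = summarize_sample(d$attempted_seq),
        attempted_range = range(d$attempted_seq, finite = TRUE)
      )
    }),
    stat = NULL
  )
}

panel_stability_or_deq <- function(cohorts, config) {
  stability <- all(vapply(cohorts, has_stability, logical(1)))
  if (stability) {
    per_group <- purrr::map(
      cohorts, stability_series,
      selected_pair = config$stability_pair,
      change_threshold = config$stability_threshold
    )
    series <- purrr::imap_dfr(per_group, ~ dplyr::mutate(.x$series, group = .y))
    # two-group comparison on the selected-pair SEQ change
    stat <- NULL
    if (two_group(cohorts)) {
      deltas <- purrr::map(per_group, ~ .x$changed$deltas)
      design <- if (config$design == "paired") "paired" else "unpaired"
      stat <- tryCatch(
        compare_samples(deltas[[1]], deltas[[2]], design = design),
        error = function(e) NULL
      )
    }
    list(
      title = "SEQ stability over time",
      y_axis = "diopters",
      variant = "stability",
      series = series,
      annotations = purrr::map(per_group, function(s) {
        list(n = max(s$series$n), changed = s$changed)
      }),
      stat = stat
    )
  } else {
    series <- purrr::imap_dfr(cohorts, function(d, g) {
      dplyr::mutate(within_thresholds(d$postop_deq, config$deq_thresholds), group = g)
    })
    list(
      title = "Postoperative defocus equivalent",
      y_axis = "percent",
      variant = "deq",
      series = series,
      annotations = group_annotations(cohorts, function(d) {
        list(n = nrow(d), deq = summarize_sample(d$postop_deq))
      }),
      stat = panel_stat(cohorts, config, "postop_deq")
    )
  }
}

panel_astig_accuracy <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    dplyr::mutate(within_thresholds(d$postop_astig, config$astig_thresholds), group = g)
  })
  list(
    title = "Postoperative refractive astigmatism",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      list(n = nrow(d), astig = summarize_sample(d$postop_astig))
    }),
    stat = panel_stat(cohorts, config, "postop_astig")
  )
}

panel_tia_sia <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    tibble::tibble(x = d$tia_magnitude, y = d$sia_magnitude, group = g)
  })
  list(
    title = "TIA vs SIA magnitude",
    y_axis = "diopters",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      fit <- tryCatch(fit_line(d$tia_magnitude, d$sia_magnitude), error = function(e) NULL)
      list(
        n = nrow(d),
        fit = fit,
        tia = summarize_sample(d$tia_magnitude),
        sia = summarize_sample(d$sia_magnitude)
      )
    }),
    stat = NULL
  )
}

histogram_from_values <- function(values, width, center0 = TRUE) {
  values <- values[is.finite(values)]
  lo <- floor(min(values) / width) * width
  hi <- ceiling(max(values) / width) * width
  if (hi <= lo) hi <- lo + width
  breaks <- seq(lo, hi, by = width)
  if (length(breaks) < 2) breaks <- c(lo, lo + width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = TRUE, include.lowest = TRUE)
  tibble::tibble(
    mid = h$mids,
    percent = 100 * h$counts / length(values)
  )
}

panel_correction_index <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    ci <- d$correction_index[is.finite(d$correction_index)]
    dplyr::mutate(histogram_from_values(ci, config$ci_bin_width), group = g)
  })
  list(
    title = "Correction index",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      ci <- d$correction_index
      list(
        n = sum(is.finite(ci)),
        n_excluded = sum(!is.finite(ci)),
        ci = if (any(is.finite(ci))) summarize_sample(ci) else NULL
      )
    }),
    stat = panel_stat(cohorts, config, "correction_index", paired_complete = TRUE),
    excluded = purrr::map(cohorts, ~ sum(!is.finite(.x$correction_index)))
  )
}

panel_angle_of_error <- function(cohorts, config) {
  series <- purrr::imap_dfr(cohorts, function(d, g) {
    aoe <- d$angle_of_error[is.finite(d$angle_of_error)]
    dplyr::mutate(histogram_from_values(aoe, config$aoe_bin_width), group = g)
  })
  list(
    title = "Angle of error",
    y_axis = "percent",
    series = series,
    annotations = group_annotations(cohorts, function(d) {
      aoe <- d$angle_of_error
      list(
        n = sum(is.finite(aoe)),
        n_excluded = sum(!is.finite(aoe)),
        aoe = if (any(is.finite(aoe))) summarize_sample(aoe) else NULL
      )
    }),
    stat = panel_stat(cohorts, config, "angle_of_error", paired_complete = TRUE),
    excluded = purrr::map(cohorts, ~ sum(!is.finite(.x$angle_of_error)))
  )
}

#' @export
print.panel_data <- function(x, ...) {
  cat("Panel ", x$panel_id, ": ", x$title, "\n", sep = "")
  print(x$series, n = 6)
  if (!is.null(x$stat)) {
    cat(sprintf(
      "  %s: p = %.4g, d = %.3f\n",
      x$stat$test, x$stat$p_value, x$stat$effect_size_d
    ))
  }
  invisible(x)
}
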