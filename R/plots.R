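# Rendering of computed panel content with ggplot2, and TIFF export.

fmt_d <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

stat_caption <- function(stat) {
  if (is.null(stat)) return(NULL)
  sprintf(
    "%s: p = %s, d = %s (n = %d/%d)",
    stat$test,
    format.pval(stat$p_value, digits = 3, eps = 1e-4),
    fmt_d(stat$effect_size_d), stat$n_a, stat$n_b
  )
}

refr_theme <- function() {
  ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(
      panel.grid.minor = ggplot2::element_blank(),
      plot.title = ggplot2::element_text(face = "bold", size = 10),
      plot.caption = ggplot2::element_text(size = 7),
      legend.position = "bottom",
      legend.title = ggplot2::element_blank()
    )
}

group_fill <- function(config, groups) {
  cols <- rep_len(config$group_colors, length(groups))
  ggplot2::scale_fill_manual(values = stats::setNames(cols, groups))
}
group_color <- function(config, groups) {
  cols <- rep_len(config$group_colors, length(groups))
  ggplot2::scale_color_manual(values = stats::setNames(cols, groups))
}

#' Plot a standard panel
#'
#' Renders one computed panel ([compute_panel()]) as a ggplot: cumulative
#' acuity and accuracy histograms as grouped bars, scattergrams with the
#' identity and fitted lines, the stability panel as a mean +/- SD time
#' series. Annotations (N, indices, mean +/- SD, regression text, p and
#' Cohen's d) are placed in the subtitle/caption.
#'
#' @param object A `panel_data` object.
#' @param config A [study_config()] (colors, thresholds).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_data
#' @export
autoplot.panel_data <- function(object, config = study_config(), ...) {
  p <- object
  groups <- unique(p$series$group)
  ann <- p$annotations
  sub <- switch(p$panel_id,
    A = paste(vapply(names(ann), function(g) {
      sprintf(
        "%s (n=%d): UDVA %s, CDVA %s logMAR", g, ann[[g]]$n,
        fmt_d(ann[[g]]$postop_udva$mean), fmt_d(ann[[g]]$postop_cdva$mean)
      )
    }, character(1)), collapse = "  |  "),
    B = paste(vapply(names(ann), function(g) {
      sprintf("%s (n=%d): efficacy index %s", g, ann[[g]]$n, fmt_d(ann[[g]]$efficacy_index))
    }, character(1)), collapse = "  |  "),
    C = paste(vapply(names(ann), function(g) {
      sprintf("%s (n=%d): safety index %s", g, ann[[g]]$n, fmt_d(ann[[g]]$safety_index))
    }, character(1)), collapse = "  |  "),
    D = paste(vapply(names(ann), function(g) {
      sprintf(
        "%s (n=%d): SEQ error %s ± %s D", g, ann[[g]]$n,
        fmt_d(ann[[g]]$seq_error$mean), fmt_d(ann[[g]]$seq_error$sd)
      )
    }, character(1)), collapse = "  |  "),
    E = paste(vapply(names(ann), function(g) {
      f <- ann[[g]]$fit
      if (is.null(f)) return(sprintf("%s (n=%d)", g, ann[[g]]$n))
      sprintf(
        "%s: y = %s + %sx, R² = %s; attempted %s D [%s, %s]",
        g, fmt_d(f$intercept), fmt_d(f$slope), fmt_d(f$r_squared, 3),
        fmt_d(ann[[g]]$attempted$mean),
        fmt_d(ann[[g]]$attempted_range[1]), fmt_d(ann[[g]]$attempted_range[2])
      )
    }, character(1)), collapse = "\n"),
    F = if (identical(p$variant, "stability")) {
      paste(vapply(names(ann), function(g) {
        ch <- ann[[g]]$changed
        sprintf(
          "%s: %s%% changed > 0.50 D (t%d vs t%d, n=%d)",
          g, fmt_d(ch$percent, 1), ch$pair[1], ch$pair[2], ch$n
        )
      }, character(1)), collapse = "  |  ")
    } else {
      paste(vapply(names(ann), function(g) {
        sprintf(
          "%s (n=%d): DEQ %s ± %s D", g, ann[[g]]$n,
          fmt_d(ann[[g]]$deq$mean), fmt_d(ann[[g]]$deq$sd)
        )
      }, character(1)), collapse = "  |  ")
    },
    G = paste(vapply(names(ann), function(g) {
      sprintf(
        "%s (n=%d): astigmatism %s ± %s D", g, ann[[g]]$n,
        fmt_d(ann[[g]]$astig$mean), fmt_d(ann[[g]]$astig$sd)
      )
    }, character(1)), collapse = "  |  "),
    H = paste(vapply(names(ann), function(g) {
      f <- ann[[g]]$fit
      if (is.null(f)) return(sprintf("%s (n=%d)", g, ann[[g]]$n))
      sprintf(
        "%s: y = %s + %sx, R² = %s; TIA %s, SIA %s D",
        g, fmt_d(f$intercept), fmt_d(f$slope), fmt_d(f$r_squared, 3),
        fmt_d(ann[[g]]$tia$mean), fmt_d(ann[[g]]$sia$mean)
      )
    }, character(1)), collapse = "\n"),
    I = paste(vapply(names(ann), function(g) {
      s <- ann[[g]]$ci
      sprintf(
        "%s (n=%d, excluded %d): CI %s ± %s", g, ann[[g]]$n,
        ann[[g]]$n_excluded,
        if (is.null(s)) "-" else fmt_d(s$mean),
        if (is.null(s)) "-" else fmt_d(s$sd)
      )
    }, character(1)), collapse = "  |  "),
    J = paste(vapply(names(ann), function(g) {
      s <- ann[[g]]$aoe
      sprintf(
        "%s (n=%d, excluded %d): AoE %s ± %s°", g, ann[[g]]$n,
        ann[[g]]$n_excluded,
        if (is.null(s)) "-" else fmt_d(s$mean, 1),
        if (is.null(s)) "-" else fmt_d(s$sd, 1)
      )
    }, character(1)), collapse = "  |  ")
  )

  gg <- switch(p$panel_id,
    A = {
      df <- dplyr::mutate(p$series,
        line_label = factor(paste0("20/", .data$line), levels = paste0("20/", sort(unique(.data$line)))),
        series_id = paste(.data$group, .data$measure)
      )
      ggplot2::ggplot(df, ggplot2::aes(
        x = .data$line_label, y = .data$percent,
        group = .data$series_id, color = .data$group, linetype = .data$measure
      )) +
        ggplot2::geom_line() +
        ggplot2::geom_point(size = 1.4) +
        group_color(config, groups) +
        ggplot2::labs(x = "Snellen line (20/x or better)", y = "% of eyes")
    },
    B = ,
    C = ggplot2::ggplot(p$series, ggplot2::aes(
      x = .data$bin, y = .data$percent, fill = .data$group
    )) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
      group_fill(config, groups) +
      ggplot2::labs(x = "Change in Snellen lines", y = "% of eyes"),
    D = ,
    G = threshold_bar(p, config, groups,
      xlab = if (p$panel_id == "D") "Within (D of target)" else "Postop astigmatism ≤ (D)"
    ),
    E = ,
    H = scatter_identity(p, config, groups,
      xlab = if (p$panel_id == "E") "Attempted SEQ change (D)" else "TIA magnitude (D)",
      ylab = if (p$panel_id == "E") "Achieved SEQ change (D)" else "SIA magnitude (D)"
    ),
    F = if (identical(p$variant, "stability")) {
      ggplot2::ggplot(p$series, ggplot2::aes(
        x = .data$timepoint, y = .data$mean, color = .data$group, group = .data$group
      )) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
        ), width = 0.15) +
        group_color(config, groups) +
        ggplot2::labs(x = "Time point (0 = preop)", y = "SEQ (D)")
    } else {
      threshold_bar(p, config, groups, xlab = "Postop DEQ ≤ (D)")
    },
    I = ,
    J = ggplot2::ggplot(p$series, ggplot2::aes(
      x = .data$mid, y = .data$percent, fill = .data$group
    )) +
      ggplot2::geom_col(
        position = "identity", alpha = 0.65, width = 0.9 *
          (if (p$panel_id == "I") config$ci_bin_width else config$aoe_bin_width)
      ) +
      group_fill(config, groups) +
      ggplot2::labs(
        x = if (p$panel_id == "I") "Correction index" else "Angle of error (°)",
        y = "% of eyes"
      )
  )

  gg + refr_theme() +
    ggplot2::labs(
      title = paste0(p$panel_id, ". ", p$title),
      subtitle = sub,
      caption = stat_caption(p$stat)
    ) +
    ggplot2::theme(plot.subtitle = ggplot2::element_text(size = 7))
}

threshold_bar <- function(p, config, groups, xlab) {
  df <- dplyr::mutate(p$series,
    thr = factor(fmt_d(.data$threshold), levels = fmt_d(sort(unique(.data$threshold))))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$thr, y = .data$percent, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_text(
      ggplot2::aes(label = fmt_d(.data$percent, 0)),
      position = ggplot2::position_dodge(width = 0.8), vjust = -0.4, size = 2.6
    ) +
    group_fill(config, groups) +
    ggplot2::coord_cartesian(ylim = c(0, 105)) +
    ggplot2::labs(x = xlab, y = "% of eyes")
}

scatter_identity <- function(p, config, groups, xlab, ylab) {
  df <- p$series[is.finite(p$series$x) & is.finite(p$series$y), ]
  rng <- range(c(df$x, df$y), finite = TRUE)
  pad <- diff(rng) * 0.1
  if (!is.finite(pad) || pad == 0) pad <- 0.5
  lims <- rng + c(-pad, pad)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, color = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1.3) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    group_color(config, groups) +
    ggplot2::coord_cartesian(xlim = lims, ylim = lims) +
    ggplot2::labs(x = xlab, y = ylab)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

tiff_device <- function(filename, width, height, dpi) {
  grDevices::tiff(
    filename = filename, width = width, height = height, units = "in",
    res = dpi, compression = "lzw",
    type = if (capabilities("cairo")) "cairo" else NULL
  )
}

#' Render and export all panels as TIFF figures
#'
#' Writes one TIFF per panel at `config$dpi_panel` (default 400 dpi) and a
#' composite one-page figure with all ten panels in a fixed 2 x 5 grid at
#' `config$dpi_composite` (default 1200 dpi). Resolution metadata is
#' embedded in each file. File names carry the panel letter and the group
#' names.
#'
#' @param panels Named list of `panel_data` objects from [compute_panels()].
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble: `file`, `panel`, `dpi`.
#' @export
render_panels <- function(panels, config = study_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
  }
  groups <- panels[[1]]$groups %||% "group"
  tag <- gsub("[^A-Za-z0-9_-]+", "_", paste(groups, collapse = "-"))
  plots <- purrr::map(panels, autoplot, config = config)

  files <- purrr::imap_chr(plots, function(gg, id) {
    f <- file.path(out_dir, paste0("panel_", id, "_", tag, ".tiff"))
    tiff_device(f, width = 5, height = 4, dpi = config$dpi_panel)
    print(gg)
    grDevices::dev.off()
    f
  })

  composite <- file.path(out_dir, paste0("composite_", tag, ".tiff"))
  page <- patchwork::wrap_plots(plots, ncol = 2, byrow = TRUE)
  tiff_device(composite, width = 5, height = 12.5, dpi = config$dpi_composite)
  print(page)
  grDevices::dev.off()

  tibble::tibble(
    file = c(unname(files), composite),
    panel = c(names(plots), "composite"),
    dpi = c(rep(config$dpi_panel, length(files)), config$dpi_composite)
  )
}
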