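#' Simulation scenario for synthetic cohorts
#'
#' Defines the population and treatment model of a synthetic cohort in the
#' exact quantities the standard-graph analysis later estimates. Preop
#' refractions are drawn at the corneal plane in negative-cylinder notation;
#' the treatment is applied in doubled-angle vector space — the intended
#' astigmatic change (TIA) is scaled by a per-eye correction index drawn
#' from `N(ci_mean, ci_sd)` and rotated by a per-eye axis error drawn from
#' `N(0, axis_error_sd)` — so the generator's `ci_mean` and `seq_bias` are
#' exactly the mean correction index and mean SEQ error the pipeline should
#' recover. Records are written at `vertex` mm (default 12, the typical
#' spectacle plane).
#'
#' @param n_eyes Number of eyes.
#' @param sphere_mean,sphere_sd Preop sphere distribution (corneal plane,
#'   negative-cylinder notation), diopters.
#' @param cyl_mean,cyl_sd,cyl_min Preop cylinder magnitude distribution
#'   (diopters, truncated below at `cyl_min`).
#' @param target_seq Intended target SEQ (0 = plano; a monovision offset
#'   otherwise); the target cylinder is always 0.
#' @param ci_mean,ci_sd Per-eye astigmatic correction index distribution
#'   (truncated at 0).
#' @param axis_error_sd SD of the per-eye treatment axis error, degrees.
#' @param seq_bias,seq_sd Systematic and random error of the achieved SEQ
#'   relative to target (corneal plane), diopters.
#' @param vertex Vertex distance at which records are written, mm.
#' @param udva_k LogMAR of uncorrected acuity per diopter of residual
#'   defocus equivalent (default 0.3).
#' @param udva_sd LogMAR noise on the uncorrected acuity response.
#' @param preop_cdva_lines,preop_cdva_probs Distribution of preop corrected
#'   acuity over Snellen lines (default: all 20/20).
#' @param cdva_change_probs Named probabilities of CDVA line changes, names
#'   are integer changes (positive = gained); default 10% lose 1, 80%
#'   unchanged, 10% gain 1.
#' @param n_timepoints Number of populated postoperative SEQ stability
#'   columns (0-5; 0 = none, the DEQ panel is produced instead).
#' @param drift_per_timepoint Mean SEQ drift per time step, diopters.
#' @param stability_noise_sd Per-timepoint SEQ measurement noise, diopters.
#' @param shift_fraction,shift_amount,shift_between Inject an abrupt SEQ
#'   shift of `shift_amount` D in a fixed fraction of eyes, occurring
#'   between the two timepoint indices in `shift_between`.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `scenario`.
#' @export
scenario <- function(n_eyes = 100,
                     sphere_mean = -3, sphere_sd = 1.25,
                     cyl_mean = 1, cyl_sd = 0.5, cyl_min = 0.25,
                     target_seq = 0,
                     ci_mean = 0.95, ci_sd = 0.1,
                     axis_error_sd = 5,
                     seq_bias = -0.1, seq_sd = 0.25,
                     vertex = 12,
                     udva_k = 0.3, udva_sd = 0.04,
                     preop_cdva_lines = 20, preop_cdva_probs = 1,
                     cdva_change_probs = c("-1" = 0.1, "0" = 0.8, "1" = 0.1),
                     n_timepoints = 0,
                     drift_per_timepoint = 0.02,
                     stability_noise_sd = 0.05,
                     shift_fraction = 0, shift_amount = 0.75,
                     shift_between = c(2, 5),
                     seed = 1) {
  if (any(c(sphere_sd, cyl_sd, ci_sd, axis_error_sd, seq_sd, udva_sd,
            stability_noise_sd) < 0)) {
    abort("All scenario SDs must be >= 0.")
  }
  if (abs(sum(preop_cdva_probs) - 1) > 1e-9 || abs(sum(cdva_change_probs) - 1) > 1e-9) {
    abort("Probability vectors must sum to 1.")
  }
  if (n_timepoints < 0 || n_timepoints > 5) abort("`n_timepoints` must be in 0..5.")
  if (shift_fraction > 0 && n_timepoints > 0 &&
    (length(shift_between) != 2 || any(!shift_between %in% seq_len(n_timepoints)))) {
    abort("`shift_between` must name two populated timepoints.")
  }
  structure(as.list(environment()), class = "scenario")
}

sample_snellen_line <- function(n, lines, probs, cfg) {
  idx <- sample.int(length(lines), n, replace = TRUE, prob = probs)
  lines[idx]
}

snellen_token <- function(denominator, letter_offset) {
  denom <- ifelse(denominator == round(denominator),
    formatC(denominator, format = "d"),
    formatC(denominator, format = "fg")
  )
  suffix <- ifelse(letter_offset == 0, "",
    paste0(ifelse(letter_offset > 0, "+", "-"), abs(letter_offset))
  )
  paste0(denom, suffix)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a [scenario()] and returns it in the standard
#' 20-column record layout (plus parsed acuity columns, so the result is
#' directly usable by [run_analysis()]). Deterministic given the scenario
#' seed. With all SDs, bias and drift zero the generated cohort is perfect:
#' postop equals target and the correction index is 1 for every eye with a
#' non-zero intended correction.
#'
#' @param sc A [scenario()].
#' @param cfg An [acuity_config()] used to snap simulated acuities to chart
#'   lines.
#' @return A cohort tibble (see [read_cohort()] for columns), with the
#'   scenario attached as attribute `scenario`.
#' @export
simulate_cohort <- function(sc, cfg = acuity_config()) {
  if (!inherits(sc, "scenario")) abort("`sc` must be a scenario() object.")
  withr::with_seed(sc$seed, simulate_cohort_impl(sc, cfg))
}

simulate_cohort_impl <- function(sc, cfg) {
  n <- sc$n_eyes

  # preop at the corneal plane, negative-cylinder notation
  preop_sph <- rnorm(n, sc$sphere_mean, sc$sphere_sd)
  preop_cyl_mag <- pmax(sc$cyl_min, rnorm(n, sc$cyl_mean, sc$cyl_sd))
  preop_axis <- sample.int(180, n, replace = TRUE)

  # intended change in doubled-angle space: target cylinder is 0
  preop_pos_axis <- normalize_axis(preop_axis + 90) # positive-cyl axis
  tia <- double_angle(preop_cyl_mag, preop_pos_axis)
  tia$x <- -tia$x
  tia$y <- -tia$y

  # treatment: scale TIA by a sampled CI, rotate by a sampled axis error
  ci <- pmax(0, rnorm(n, sc$ci_mean, sc$ci_sd))
  axis_err <- rnorm(n, 0, sc$axis_error_sd)
  rot <- 2 * axis_err * pi / 180
  sia_x <- ci * (tia$x * cos(rot) - tia$y * sin(rot))
  sia_y <- ci * (tia$x * sin(rot) + tia$y * cos(rot))

  # residual postop astigmatism vector and SEQ (corneal plane)
  post_x <- -tia$x + sia_x
  post_y <- -tia$y + sia_y
  post_mag <- vector_magnitude(post_x, post_y)
  post_pos_axis <- ifelse(post_mag > 1e-12, vector_axis(post_x, post_y), 180)
  post_seq <- sc$target_seq + sc$seq_bias + rnorm(n, 0, sc$seq_sd)

  # back to negative-cylinder sphero-cylinder; axes charted in whole degrees
  post_sph <- post_seq + post_mag / 2
  post_cyl <- -post_mag
  post_axis <- normalize_axis(round(normalize_axis(post_pos_axis + 90)))

  to_vertex <- function(sph, cyl, axis) {
    propagate_vertex(sph, cyl, axis, vertex = 0, target_vertex = sc$vertex)
  }
  preop_v <- to_vertex(preop_sph, -preop_cyl_mag, preop_axis)
  target_v <- to_vertex(rep(sc$target_seq, n), rep(0, n), rep(180, n))
  postop_v <- to_vertex(post_sph, post_cyl, post_axis)

  # acuities: preop CDVA drawn from chart lines; postop CDVA shifted by a
  # sampled line change; UDVA responds to the residual defocus equivalent
  preop_cdva_den <- sample_snellen_line(n, sc$preop_cdva_lines, sc$preop_cdva_probs, cfg)
  preop_cdva_lm <- snellen_to_logmar(preop_cdva_den, 0, cfg)
  changes <- as.integer(names(sc$cdva_change_probs))
  cdva_shift <- changes[sample.int(length(changes), n, replace = TRUE, prob = sc$cdva_change_probs)]
  post_cdva_lm_raw <- preop_cdva_lm - 0.1 * cdva_shift
  post_cdva <- logmar_to_snellen(post_cdva_lm_raw, cfg)
  post_deq <- abs(post_seq) + post_mag / 2
  udva_lm_raw <- pmax(post_cdva_lm_raw, pmax(0, sc$udva_k * post_deq) + rnorm(n, 0, sc$udva_sd))
  post_udva <- logmar_to_snellen(udva_lm_raw, cfg)

  r2 <- function(x) round_half_away(x, 2)
  out <- tibble::tibble(
    preop_sphere = r2(preop_v$sphere),
    preop_cylinder = r2(preop_v$cylinder),
    preop_axis = preop_v$axis,
    preop_vertex = sc$vertex,
    preop_cdva = snellen_token(preop_cdva_den, 0L),
    target_sphere = r2(target_v$sphere),
    target_cylinder = r2(target_v$cylinder),
    target_axis = ifelse(abs(target_v$cylinder) < 1e-9, 180, target_v$axis),
    target_vertex = sc$vertex,
    postop_sphere = r2(postop_v$sphere),
    postop_cylinder = r2(postop_v$cylinder),
    postop_axis = postop_v$axis,
    postop_vertex = sc$vertex,
    postop_cdva = snellen_token(post_cdva$denominator, post_cdva$letter_offset),
    postop_udva = snellen_token(post_udva$denominator, post_udva$letter_offset)
  )

  # stability series at the entered plane
  seq_entered <- spherical_equivalent(out$postop_sphere, out$postop_cylinder)
  shifted <- rep(FALSE, n)
  if (sc$n_timepoints > 0 && sc$shift_fraction > 0) {
    k <- round(sc$shift_fraction * n)
    shifted[sample.int(n, k)] <- TRUE
  }
  for (t in 1:5) {
    col <- paste0("seq_", t)
    if (t <= sc$n_timepoints) {
      v <- seq_entered + sc$drift_per_timepoint * (t - 1) +
        rnorm(n, 0, sc$stability_noise_sd)
      if (sc$shift_fraction > 0 && t >= sc$shift_between[2]) {
        v <- v + ifelse(shifted, sc$shift_amount, 0)
      }
      out[[col]] <- r2(v)
    } else {
      out[[col]] <- NA_real_
    }
  }

  pre_cdva <- parse_snellen(out$preop_cdva)
  po_cdva <- parse_snellen(out$postop_cdva)
  po_udva <- parse_snellen(out$postop_udva)
  out <- dplyr::mutate(out,
    preop_cdva_denominator = pre_cdva$denominator,
    preop_cdva_letters = pre_cdva$letter_offset,
    preop_cdva_logmar = snellen_to_logmar(pre_cdva$denominator, pre_cdva$letter_offset, cfg),
    postop_cdva_denominator = po_cdva$denominator,
    postop_cdva_letters = po_cdva$letter_offset,
    postop_cdva_logmar = snellen_to_logmar(po_cdva$denominator, po_cdva$letter_offset, cfg),
    postop_udva_denominator = po_udva$denominator,
    postop_udva_letters = po_udva$letter_offset,
    postop_udva_logmar = snellen_to_logmar(po_udva$denominator, po_udva$letter_offset, cfg),
    row = dplyr::row_number()
  )
  attr(out, "scenario") <- sc
  out
}

#' Write a cohort to the standard 20-column CSV layout
#'
#' Writes exactly the 20 data columns with the canonical header, blank cells
#' for absent optional values, and fixed two-decimal formatting — so a fixed
#' scenario seed yields a byte-identical file on rerun, and reading the file
#' back with [read_cohort()] reproduces the written records.
#'
#' @param data A cohort tibble.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  cols <- cohort_columns()
  fmt <- function(x, digits = 2) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  }
  out <- tibble::tibble(
    preop_sphere = fmt(data$preop_sphere),
    preop_cylinder = fmt(data$preop_cylinder),
    preop_axis = fmt(data$preop_axis, 0),
    preop_vertex = fmt(data$preop_vertex, 0),
    preop_cdva = data$preop_cdva,
    target_sphere = fmt(data$target_sphere),
    target_cylinder = fmt(data$target_cylinder),
    target_axis = fmt(data$target_axis, 0),
    target_vertex = fmt(data$target_vertex, 0),
    postop_sphere = fmt(data$postop_sphere),
    postop_cylinder = fmt(data$postop_cylinder),
    postop_axis = fmt(data$postop_axis, 0),
    postop_vertex = fmt(data$postop_vertex, 0),
    postop_cdva = data$postop_cdva,
    postop_udva = data$postop_udva
  )
  for (t in 1:5) out[[paste0("seq_", t)]] <- fmt(data[[paste0("seq_", t)]])
  names(out) <- cols
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Preset scenarios emulating three demonstration trials
#'
#' Plausible emulations (not reproductions — the originals' parameters are
#' not published) of three demonstration datasets:
#' `"trial1"`, a paired contralateral-eye laser vision correction study in
#' hyperopic astigmatism comparing two excimer lasers, with a populated
#' five-timepoint stability series; `"trial2"`, a single-group toric phakic
#' IOL cohort in hyperopic eyes with moderate-to-high astigmatism;
#' `"trial3"`, two unpaired cataract-surgery groups (two biometers) in
#' myopic-astigmatism eyes.
#'
#' @param name `"trial1"`, `"trial2"` or `"trial3"`.
#' @param group `"a"` or `"b"` (ignored for the single-group trial).
#' @param n_eyes Eyes per group.
#' @param seed Base seed; group B uses a derived seed so the two arms share
#'   design but not draws.
#' @return A [scenario()].
#' @export
trial_scenario <- function(name = c("trial1", "trial2", "trial3"),
                           group = c("a", "b"), n_eyes = 100, seed = 2023) {
  name <- match.arg(name)
  group <- match.arg(group)
  gseed <- seed + ifelse(group == "a", 0L, 101L)
  switch(name,
    trial1 = scenario(
      n_eyes = n_eyes,
      sphere_mean = 3, sphere_sd = 1,
      cyl_mean = 1.25, cyl_sd = 0.5, cyl_min = 0.5,
      ci_mean = if (group == "a") 0.98 else 0.92,
      ci_sd = 0.08, axis_error_sd = 4,
      seq_bias = if (group == "a") -0.05 else -0.20,
      seq_sd = 0.25,
      n_timepoints = 5, drift_per_timepoint = 0.02,
      stability_noise_sd = 0.05,
      seed = gseed
    ),
    trial2 = scenario(
      n_eyes = n_eyes,
      sphere_mean = 4, sphere_sd = 1.25,
      cyl_mean = 2.75, cyl_sd = 0.75, cyl_min = 1.5,
      ci_mean = 0.95, ci_sd = 0.1, axis_error_sd = 5,
      seq_bias = -0.10, seq_sd = 0.30,
      seed = gseed
    ),
    trial3 = scenario(
      n_eyes = n_eyes,
      sphere_mean = -4, sphere_sd = 1.5,
      cyl_mean = 1, cyl_sd = 0.5, cyl_min = 0.25,
      ci_mean = if (group == "a") 0.96 else 0.90,
      ci_sd = 0.1, axis_error_sd = 6,
      seq_bias = if (group == "a") -0.05 else -0.15,
      seq_sd = 0.35,
      preop_cdva_lines = c(20, 25, 32, 40),
      preop_cdva_probs = c(0.3, 0.35, 0.25, 0.1),
      cdva_change_probs = c("-1" = 0.03, "0" = 0.35, "1" = 0.40, "2" = 0.22),
      seed = gseed
    )
  )
}

#' Generate and write a full preset trial dataset
#'
#' Writes the group file(s) of a preset trial ([trial_scenario()]) to `dir`
#' and returns the matching [study_config()] and file paths, ready for
#' [run_analysis()].
#'
#' @inheritParams trial_scenario
#' @param dir Output directory.
#' @return A list with `paths`, `config`, `scenarios`.
#' @export
simulate_trial <- function(name = c("trial1", "trial2", "trial3"), dir = tempdir(),
                           n_eyes = 100, seed = 2023) {
  name <- match.arg(name)
  two <- name != "trial2"
  groups <- if (two) c("a", "b") else "a"
  scenarios <- purrr::map(groups, ~ trial_scenario(name, .x, n_eyes = n_eyes, seed = seed))
  paths <- purrr::map2_chr(scenarios, groups, function(sc, g) {
    p <- file.path(dir, paste0(name, "_group_", g, ".csv"))
    write_cohort(simulate_cohort(sc), p)
    p
  })
  config <- switch(name,
    trial1 = study_config(
      procedure = "LVC", design = "paired",
      group_names = c("Laser A", "Laser B"), stability_pair = c(2, 5)
    ),
    trial2 = study_config(procedure = "ICL", design = "single", group_names = "Toric PIOL"),
    trial3 = study_config(
      procedure = "CAT", design = "unpaired",
      group_names = c("Biometer A", "Biometer B")
    )
  )
  list(paths = paths, config = config, scenarios = scenarios)
}
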