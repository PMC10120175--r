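# Fixtures are generated in code at test time; nothing is stored on disk.

# A degenerate generator run: no bias, no noise, no acuity change -> every
# eye hits its target exactly and keeps 20/20.
perfect_scenario <- function(n = 20, seed = 7, n_timepoints = 0) {
  scenario(
    n_eyes = n,
    sphere_mean = -2, sphere_sd = 1,
    cyl_mean = 1.5, cyl_sd = 0.5, cyl_min = 0.5,
    ci_mean = 1, ci_sd = 0, axis_error_sd = 0,
    seq_bias = 0, seq_sd = 0,
    udva_sd = 0,
    cdva_change_probs = c("0" = 1),
    n_timepoints = n_timepoints,
    drift_per_timepoint = 0, stability_noise_sd = 0,
    seed = seed
  )
}

perfect_cohort <- function(n = 20, seed = 7, ...) {
  simulate_cohort(perfect_scenario(n, seed, ...))
}

random_refractions <- function(n, seed = 11) {
  withr::with_seed(seed, tibble::tibble(
    sphere = round(runif(n, -8, 6), 2),
    cylinder = round(-runif(n, 0, 4), 2),
    axis = sample(180, n, replace = TRUE),
    vertex = sample(c(0, 10, 12), n, replace = TRUE)
  ))
}

# Convert a written CSV cohort file to XLSX using the system Python/openpyxl
# (part of the same pre-installed stack); used only to exercise the XLSX
# reading path.
csv_to_xlsx <- function(csv_path, xlsx_path) {
  script <- "
import csv, sys
import openpyxl
wb = openpyxl.Workbook(); ws = wb.active
for row in csv.reader(open(sys.argv[1])):
    ws.append([cell if cell != '' else None for cell in row])
wb.save(sys.argv[2])
"
  status <- system2("python", c("-c", shQuote(script), shQuote(csv_path), shQuote(xlsx_path)))
  stopifnot(status == 0)
  xlsx_path
}

# XLSX with one acuity cell stored as a real date (the classic 25-2 ->
# 25-Feb spreadsheet accident).
xlsx_with_date_cell <- function(csv_path, xlsx_path) {
  script <- "
import csv, sys, datetime
import openpyxl
wb = openpyxl.Workbook(); ws = wb.active
for row in csv.reader(open(sys.argv[1])):
    ws.append([cell if cell != '' else None for cell in row])
ws.cell(row = 2, column = 5, value = datetime.date(2024, 2, 25))
wb.save(sys.argv[2])
"
  status <- system2("python", c("-c", shQuote(script), shQuote(csv_path), shQuote(xlsx_path)))
  stopifnot(status == 0)
  xlsx_path
}

# Independent crossed-cylinder oracle: combine two pure plus-cylinders via
# 2x2 dioptric power matrices and recover the resultant cylinder magnitude
# and axis from the eigen-decomposition.
power_matrix <- function(sphere, cylinder, axis_deg) {
  t <- axis_deg * pi / 180
  matrix(c(
    sphere + cylinder * sin(t)^2, -cylinder * sin(t) * cos(t),
    -cylinder * sin(t) * cos(t), sphere + cylinder * cos(t)^2
  ), nrow = 2)
}

matrix_resultant <- function(c1, a1, c2, a2) {
  m <- power_matrix(0, c1, a1) + power_matrix(0, c2, a2)
  e <- eigen(m, symmetric = TRUE)
  cyl <- max(e$values) - min(e$values)
  v <- e$vectors[, which.min(e$values)] # meridian of least power = cyl axis
  axis <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(cylinder = cyl, axis = ifelse(axis == 0, 180, axis))
}

quiet_validate <- function(...) {
  withCallingHandlers(
    validate_cohorts(...),
    warning = function(w) invokeRestart("muffleWarning")
  )
}
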