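test_that("a generated file round-trips through write_cohort/read_cohort", {
  d <- simulate_cohort(scenario(n_eyes = 25, n_timepoints = 3, seed = 41))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  back <- read_cohort(path)
  for (col in refracto:::cohort_columns()) {
    expect_equal(back[[col]], d[[col]], info = col)
  }
  expect_equal(attr(back, "n_input_rows"), 25)
  expect_equal(nrow(attr(back, "validation")), 0)
})

test_that("the same records read identically from CSV and XLSX", {
  d <- simulate_cohort(scenario(n_eyes = 10, seed = 42))
  csv <- withr::local_tempfile(fileext = ".csv")
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_cohort(d, csv)
  csv_to_xlsx(csv, xlsx)
  from_csv <- read_cohort(csv)
  from_xlsx <- read_cohort(xlsx)
  for (col in refracto:::cohort_columns()) {
    expect_equal(from_xlsx[[col]], from_csv[[col]], info = col)
  }
})

test_that("a date-coerced acuity cell in an XLSX is rejected with the remedial fix", {
  d <- simulate_cohort(scenario(n_eyes = 5, seed = 43))
  csv <- withr::local_tempfile(fileext = ".csv")
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_cohort(d, csv)
  xlsx_with_date_cell(csv, xlsx)
  expect_error(read_cohort(xlsx), "Text")
})

test_that("plano targets entered as 0,0,0 are accepted, axis 0 normalized to 180", {
  d <- simulate_cohort(scenario(n_eyes = 5, seed = 44))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  lines <- readLines(path)
  # force a literal "0" target axis on the first data row
  row <- strsplit(lines[2], ",")[[1]]
  row <- c(row, rep("", 20 - length(row)))
  row[6:8] <- c("0.00", "0.00", "0")
  lines[2] <- paste(row, collapse = ",")
  writeLines(lines, path)
  back <- read_cohort(path)
  expect_equal(back$target_sphere[1], 0)
  expect_equal(back$target_cylinder[1], 0)
  expect_equal(back$target_axis[1], 180)
})

test_that("rows with bad mandatory cells are dropped into the report, never silently", {
  d <- simulate_cohort(scenario(n_eyes = 8, seed = 45))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  lines <- readLines(path)
  r2 <- strsplit(lines[3], ",")[[1]]
  r2 <- c(r2, rep("", 20 - length(r2)))
  r2[1] <- "not-a-number"
  lines[3] <- paste(r2, collapse = ",")
  r5 <- strsplit(lines[6], ",")[[1]]
  r5 <- c(r5, rep("", 20 - length(r5)))
  r5[14] <- ""
  lines[6] <- paste(r5, collapse = ",")
  writeLines(lines, path)

  back <- read_cohort(path)
  report <- attr(back, "validation")
  expect_equal(nrow(back) + nrow(report), attr(back, "n_input_rows"))
  expect_equal(report$row, c(2L, 5L))
  expect_match(report$reason[1], "preop_sphere")
  expect_match(report$reason[2], "postop_cdva")
})

test_that("missing mandatory columns and empty files are schema errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c\n1,2,3", path)
  expect_error(read_cohort(path), "mandatory column")
  writeLines(paste(refracto:::cohort_columns(), collapse = ","), path)
  expect_error(read_cohort(path), "no data rows")
  expect_error(read_cohort(withr::local_tempfile(fileext = ".txt")), "not found|format")
})

test_that("blank optional stability columns mean absent, zero is a value", {
  d <- simulate_cohort(scenario(n_eyes = 6, n_timepoints = 2, seed = 46))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  back <- read_cohort(path)
  expect_true(all(is.finite(back$seq_1)))
  expect_true(all(is.na(back$seq_3)))

  d0 <- simulate_cohort(scenario(n_eyes = 6, seed = 46))
  write_cohort(d0, path)
  expect_false(refracto:::has_stability(read_cohort(path)))
})

test_that("design validation enforces pairing and emits the one-eye-per-patient reminder", {
  a <- simulate_cohort(scenario(n_eyes = 10, seed = 47))
  b <- simulate_cohort(scenario(n_eyes = 10, seed = 48))
  b9 <- simulate_cohort(scenario(n_eyes = 9, seed = 49))

  expect_warning(validate_cohorts(a, b, design = "paired"), "one eye per patient")
  expect_error(quiet_validate(a, b9, design = "paired"), "equal record counts")
  expect_error(quiet_validate(a, NULL, design = "unpaired"), "two cohorts")
  expect_error(quiet_validate(a, b, design = "single"), "one cohort")
  v <- quiet_validate(a, NULL, design = "single")
  expect_s3_class(v, "cohort_validation")
  expect_equal(unname(v$n["a"]), 10)
})

test_that("per-timepoint stability Ns shrink with missing later entries", {
  d <- simulate_cohort(scenario(n_eyes = 10, n_timepoints = 5, seed = 50))
  d$seq_5[1:3] <- NA
  v <- quiet_validate(d, NULL, design = "single")
  expect_equal(unname(v$stability_n$a["seq_1"]), 10L)
  expect_equal(unname(v$stability_n$a["seq_5"]), 7L)
})
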