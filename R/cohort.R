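# Canonical 20-column layout: identity is positional, header text advisory.
cohort_columns <- function() {
  c(
    "preop_sphere", "preop_cylinder", "preop_axis", "preop_vertex", "preop_cdva",
    "target_sphere", "target_cylinder", "target_axis", "target_vertex",
    "postop_sphere", "postop_cylinder", "postop_axis", "postop_vertex",
    "postop_cdva", "postop_udva",
    paste0("seq_", 1:5)
  )
}

mandatory_columns <- function() cohort_columns()[1:15]
acuity_columns <- function() c("preop_cdva", "postop_cdva", "postop_udva")

#' Read a group data file into a cohort tibble
#'
#' Reads one group's per-eye records from the standard 20-column layout
#' (first worksheet of an XLSX file, or a CSV with the same columns): five
#' preoperative columns (sphere, cylinder, axis, vertex, CDVA), four intended
#' target columns, six postoperative columns (refraction, CDVA, UDVA) and up
#' to five optional postoperative SEQ time points for the stability graph.
#' Columns are identified by position; header names are advisory.
#'
#' Refractions must be decimal diopters in negative-cylinder notation; a
#' plano target is entered as 0, 0, 0. Acuities are 20/XX Snellen tokens
#' (see [parse_snellen()]); cells that a spreadsheet coerced to dates are
#' rejected with the remedial instruction. Blank optional cells mean
#' "absent"; a zero is a value. Rows whose mandatory cells fail to parse are
#' dropped and collected into the validation report — never silently.
#'
#' @param path Path to an `.xlsx` or `.csv` file.
#' @param name Group name; defaults to the file name.
#' @param cfg An [acuity_config()].
#' @return A tibble with the standard columns plus `preop_cdva_logmar`,
#'   `postop_cdva_logmar`, `postop_udva_logmar`, and attributes
#'   `cohort_name`, `source`, `validation` (a tibble of dropped rows with
#'   reasons).
#' @export
read_cohort <- function(path, name = NULL, cfg = acuity_config()) {
  if (!file.exists(path)) abort(paste0("Input file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = read_cohort_xlsx(path),
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE),
    abort(paste0("Unsupported input format \".", ext, "\"; use .xlsx or .csv."))
  )
  if (nrow(raw) == 0) abort(paste0("Input file has no data rows: ", path))
  if (ncol(raw) < 15) {
    missing_idx <- (ncol(raw) + 1):15
    abort(paste0(
      "Input file is missing mandatory column(s) ",
      paste0(missing_idx, " (", mandatory_columns()[missing_idx], ")", collapse = ", "),
      "."
    ))
  }
  raw <- raw[, seq_len(min(ncol(raw), 20)), drop = FALSE]
  names(raw) <- cohort_columns()[seq_len(ncol(raw))]
  for (col in setdiff(cohort_columns(), names(raw))) raw[[col]] <- NA_character_

  parsed <- parse_cohort_rows(raw, cfg)
  records <- parsed$records
  if (nrow(records) == 0) {
    abort(paste0(
      "No valid rows in ", path, "; first problem: ",
      parsed$validation$reason[1]
    ))
  }
  attr(records, "cohort_name") <- name %||% tools::file_path_sans_ext(basename(path))
  attr(records, "source") <- path
  attr(records, "validation") <- parsed$validation
  attr(records, "n_input_rows") <- nrow(raw)
  records
}

read_cohort_xlsx <- function(path) {
  guessed <- readxl::read_xlsx(path, col_names = TRUE, .name_repair = "minimal")
  is_datetime <- vapply(guessed, function(x) inherits(x, c("POSIXct", "Date")), logical(1))
  acuity_idx <- c(5L, 14L, 15L)
  if (any(is_datetime[intersect(acuity_idx, seq_along(guessed))])) {
    abort(paste0(
      "An acuity column in ", basename(path), " was stored as dates by the ",
      "spreadsheet (e.g. 25-2 became 25-Feb). Type a leading apostrophe ",
      "('25-2) or set the column number format to \"Text\" and re-enter."
    ))
  }
  txt <- readxl::read_xlsx(path, col_names = TRUE, col_types = "text", .name_repair = "minimal")
  tibble::as_tibble(txt, .name_repair = "minimal")
}

# Parse a raw all-character table row-wise; failures are collected, not thrown.
parse_cohort_rows <- function(raw, cfg) {
  n <- nrow(raw)
  num_cols <- setdiff(cohort_columns(), acuity_columns())
  out <- tibble::tibble(.rows = n)
  problems <- character(n)

  note <- function(i, msg) {
    problems[i] <<- ifelse(problems[i] == "", msg, problems[i])
  }

  for (col in num_cols) {
    x <- stringr::str_trim(raw[[col]] %|NA|% "")
    val <- suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
    bad <- which(x != "" & is.na(val))
    for (i in bad) note(i, paste0("column ", col, ": cannot parse \"", raw[[col]][i], "\" as a number"))
    mandatory <- col %in% mandatory_columns()
    if (mandatory) {
      for (i in which(x == "" | is.na(raw[[col]]))) {
        note(i, paste0("column ", col, ": mandatory cell is blank"))
      }
    }
    out[[col]] <- val
  }

  for (col in acuity_columns()) {
    x <- raw[[col]] %|NA|% ""
    denom <- rep(NA_real_, n)
    offs <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (stringr::str_trim(x[i]) == "") {
        note(i, paste0("column ", col, ": mandatory cell is blank"))
        next
      }
      res <- tryCatch(parse_snellen(x[i]), error = function(e) conditionMessage(e))
      if (is.character(res)) {
        note(i, paste0("column ", col, ", row ", i, ": ", res))
      } else {
        denom[i] <- res$denominator
        offs[i] <- res$letter_offset
      }
    }
    out[[paste0(col, "_denominator")]] <- denom
    out[[paste0(col, "_letters")]] <- offs
    out[[paste0(col, "_logmar")]] <- snellen_to_logmar(denom, offs, cfg)
    out[[col]] <- x
  }

  for (ax in c("preop_axis", "target_axis", "postop_axis")) {
    out[[ax]] <- normalize_axis(out[[ax]])
  }
  for (vx in c("preop_vertex", "target_vertex", "postop_vertex")) {
    bad <- which(!is.na(out[[vx]]) & out[[vx]] < 0)
    for (i in bad) note(i, paste0("column ", vx, ": vertex distance must be >= 0"))
  }

  # a date-coerced acuity cell is a file-level formatting problem, not a
  # row to drop: surface the remedial instruction immediately
  date_hit <- grep("spreadsheet date", problems, value = TRUE)
  if (length(date_hit)) abort(date_hit[1])

  keep <- problems == ""
  validation <- tibble::tibble(
    row = which(!keep),
    reason = problems[!keep]
  )
  records <- out[keep, cohort_columns()[c(1:15)], drop = FALSE]
  records <- dplyr::bind_cols(
    records,
    out[keep, c(
      paste0("seq_", 1:5),
      paste0(acuity_columns(), "_denominator"),
      paste0(acuity_columns(), "_letters"),
      paste0(acuity_columns(), "_logmar")
    ), drop = FALSE]
  )
  records$row <- which(keep)
  list(records = tibble::as_tibble(records), validation = validation)
}

#' Validate one or two cohorts against a study design
#'
#' Checks that the cohorts match the declared design: a paired design
#' (e.g. a contralateral-eye study) requires two groups with equal record
#' counts in aligned row order; unpaired requires two groups; single exactly
#' one. Always emits a reminder that, for statistical validity, each group
#' should contain one eye per patient. Also tabulates per-timepoint Ns for
#' the stability columns.
#'
#' @param a A cohort tibble from [read_cohort()].
#' @param b Optional second cohort (required for two-group designs).
#' @param design One of `"single"`, `"unpaired"`, `"paired"`.
#' @return A list of class `cohort_validation` with elements `design`, `n`,
#'   `stability_n` and the per-cohort dropped-row reports.
#' @export
validate_cohorts <- function(a, b = NULL, design = c("single", "unpaired", "paired")) {
  design <- match.arg(design)
  if (design == "single" && !is.null(b)) {
    abort("Single-group design takes exactly one cohort.")
  }
  if (design != "single" && is.null(b)) {
    abort(paste0("Design \"", design, "\" requires two cohorts."))
  }
  if (design == "paired" && nrow(a) != nrow(b)) {
    abort(paste0(
      "Paired design requires equal record counts in aligned row order; got ",
      nrow(a), " and ", nrow(b), " eyes."
    ))
  }
  warn(paste0(
    "For statistical validity, include one eye per patient per group ",
    "(e.g. the dominant or a randomly selected eye)."
  ))
  cohorts <- list(a = a, b = b)
  stability_n <- purrr::map(
    purrr::compact(cohorts),
    ~ vapply(paste0("seq_", 1:5), function(col) sum(!is.na(.x[[col]])), integer(1))
  )
  structure(
    list(
      design = design,
      n = c(a = nrow(a), b = if (!is.null(b)) nrow(b) else NA_integer_),
      stability_n = stability_n,
      dropped = purrr::map(purrr::compact(cohorts), ~ attr(.x, "validation"))
    ),
    class = "cohort_validation"
  )
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation (", x$design, " design)\n", sep = "")
  cat("  N:", paste(stats::na.omit(x$n), collapse = " / "), "\n")
  for (nm in names(x$dropped)) {
    d <- x$dropped[[nm]]
    if (!is.null(d) && nrow(d)) {
      cat("  Group", nm, "dropped rows:", nrow(d), "\n")
      for (i in seq_len(min(nrow(d), 5))) {
        cat("    row ", d$row[i], ": ", d$reason[i], "\n", sep = "")
      }
    }
  }
  invisible(x)
}

cohort_name <- function(data, default = "Group") {
  attr(data, "cohort_name") %||% default
}

has_stability <- function(data) {
  any(vapply(paste0("seq_", 1:5), function(col) any(!is.na(data[[col]])), logical(1)))
}
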