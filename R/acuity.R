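#' Acuity configuration
#'
#' Settings shared by all Snellen/LogMAR conversions and the cumulative
#' acuity graphs.
#'
#' @param per_letter_increment LogMAR units per letter read beyond (or short
#'   of) a full line. Default 0.02, the conventional value for 5-letter lines.
#' @param snellen_lines Ordered Snellen denominators (the XX of 20/XX)
#'   displayed on cumulative graphs and used when snapping LogMAR values back
#'   to chart lines.
#' @param index_decimals Display precision for efficacy/safety indices.
#' @return A list of class `acuity_config`.
#' @export
acuity_config <- function(per_letter_increment = 0.02,
                          snellen_lines = c(10, 12.5, 16, 20, 25, 32, 40, 50, 63, 80, 100, 125, 160, 200),
                          index_decimals = 2) {
  if (per_letter_increment <= 0) abort("`per_letter_increment` must be > 0.")
  if (any(diff(snellen_lines) <= 0)) abort("`snellen_lines` must be strictly increasing.")
  structure(
    list(
      per_letter_increment = per_letter_increment,
      snellen_lines = snellen_lines,
      index_decimals = index_decimals
    ),
    class = "acuity_config"
  )
}

#' Parse Snellen acuity tokens
#'
#' Parses acuity entries written as 20/XX Snellen denominators with an
#' optional signed letter suffix, e.g. `"20-1"`, `"15"`, `"20 + 2"`,
#' `"25-2"`. Tolerates surrounding whitespace, a leading apostrophe (the
#' spreadsheet trick that prevents date coercion) and en-dashes in place of
#' hyphens.
#'
#' Cells that a spreadsheet silently coerced to dates (ISO date strings or
#' bare Excel day serials) are rejected with a message pointing at the fix:
#' format the acuity columns as Text before entering values.
#'
#' @param token Character vector of acuity tokens.
#' @return A tibble with columns `denominator` (numeric, > 0) and
#'   `letter_offset` (integer in -4..4; letters beyond/short of the line).
#' @examples
#' parse_snellen(c("20-1", "15", "20 + 2"))
#' @export
parse_snellen <- function(token) {
  token <- as.character(token)
  cleaned <- stringr::str_squish(token)
  cleaned <- stringr::str_replace_all(cleaned, "[‒–—−]", "-")
  cleaned <- stringr::str_remove(cleaned, "^'")
  cleaned <- stringr::str_remove_all(cleaned, "\\s")

  date_like <- stringr::str_detect(cleaned, "^\\d{4}-\\d{2}-\\d{2}") |
    stringr::str_detect(cleaned, "^(\\d{1,2}-)?(Jan|Feb|Mar|Apr|May|Jun|Jul|Aug|Sep|Oct|Nov|Dec)") |
    stringr::str_detect(cleaned, "^\\d{5}(\\.0+)?$")
  if (any(date_like, na.rm = TRUE)) {
    bad <- which(date_like)[1]
    abort(paste0(
      "Acuity value \"", token[bad], "\" looks like a spreadsheet date, not a ",
      "Snellen token. Type a leading apostrophe (e.g. '25-2) or set the ",
      "column number format to \"Text\" before entering acuities."
    ))
  }

  m <- stringr::str_match(cleaned, "^(\\d+(?:\\.\\d+)?)(?:([+-])(\\d+))?$")
  bad <- which(!is.na(cleaned) & is.na(m[, 1]))
  if (length(bad)) {
    abort(paste0("Cannot parse Snellen acuity token \"", token[bad[1]], "\"."))
  }
  denominator <- as.numeric(m[, 2])
  offset <- ifelse(is.na(m[, 3]), 0L,
    as.integer(m[, 4]) * ifelse(m[, 3] == "-", -1L, 1L)
  )
  if (any(denominator <= 0, na.rm = TRUE)) abort("Snellen denominators must be > 0.")
  if (any(abs(offset) > 4, na.rm = TRUE)) {
    abort("Letter offsets beyond +/-4 are not valid Snellen suffixes.")
  }
  tibble::tibble(denominator = denominator, letter_offset = as.integer(offset))
}

#' Snellen / LogMAR / decimal acuity conversion
#'
#' `snellen_to_logmar()` maps a parsed Snellen measure to LogMAR:
#' `log10(denominator / 20) - letter_offset * per_letter_increment`.
#' `logmar_to_decimal()` is `10^(-logMAR)`; `snellen_to_decimal()` chains the
#' two. `logmar_to_snellen()` snaps a LogMAR value to the nearest
#' line-plus-letters representation on the configured chart lines (ties go to
#' the smaller letter offset), and inverts `snellen_to_logmar()` on exactly
#' representable values.
#'
#' @param denominator,letter_offset Parsed Snellen components, as returned by
#'   [parse_snellen()].
#' @param logmar Numeric vector of LogMAR values.
#' @param cfg An [acuity_config()].
#' @return Numeric vector (conversions) or a tibble with `denominator` and
#'   `letter_offset` (for `logmar_to_snellen()`).
#' @examples
#' snellen_to_logmar(40, 0)            # 0.301
#' logmar_to_decimal(0.301)            # ~0.5
#' logmar_to_snellen(0.301)            # 20/40
#' @export
snellen_to_logmar <- function(denominator, letter_offset = 0, cfg = acuity_config()) {
  log10(denominator / 20) - letter_offset * cfg$per_letter_increment
}

#' @rdname snellen_to_logmar
#' @export
logmar_to_decimal <- function(logmar) {
  10^(-logmar)
}

#' @rdname snellen_to_logmar
#' @export
snellen_to_decimal <- function(denominator, letter_offset = 0, cfg = acuity_config()) {
  logmar_to_decimal(snellen_to_logmar(denominator, letter_offset, cfg))
}

#' @rdname snellen_to_logmar
#' @export
logmar_to_snellen <- function(logmar, cfg = acuity_config()) {
  lines_logmar <- log10(cfg$snellen_lines / 20)
  pick <- function(v) {
    if (!is.finite(v)) return(c(NA_real_, NA_integer_))
    off <- round((lines_logmar - v) / cfg$per_letter_increment)
    off <- pmax(pmin(off, 4), -4)
    resid <- abs(lines_logmar - off * cfg$per_letter_increment - v)
    # nearest representable value; ties broken toward the smaller |offset|
    best <- order(round(resid, 12), abs(off))[1]
    c(cfg$snellen_lines[best], off[best])
  }
  out <- vapply(logmar, pick, numeric(2))
  tibble::tibble(
    denominator = out[1, ],
    letter_offset = as.integer(out[2, ])
  )
}

#' LogMAR to Snellen conversion table
#'
#' The bundled two-column conversion table (`logmar`, `snellen` token) for
#' users who chart in LogMAR: look up (or paste from) the nearest Snellen
#' token for each LogMAR value. The bundled table spans -0.30 to 1.00 in
#' letter steps and was produced with [logmar_to_snellen()] under the
#' default configuration.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return A tibble with columns `logmar` and `snellen`.
#' @export
logmar_snellen_table <- function(path = system.file("extdata", "logmar_snellen.csv",
                                                    package = "refracto")) {
  readr::read_csv(path, col_types = readr::cols(
    logmar = readr::col_double(), snellen = readr::col_character()
  ), progress = FALSE)
}

#' Change in acuity lines
#'
#' Number of whole lines gained (positive) or lost (negative) between two
#' acuity measurements, from the LogMAR difference at 0.1 per line with
#' half-away-from-zero rounding.
#'
#' @param pre_logmar,post_logmar LogMAR values before and after.
#' @return Integer vector of line changes.
#' @examples
#' line_change(snellen_to_logmar(25, 0), snellen_to_logmar(20, 0)) # +1
#' @export
line_change <- function(pre_logmar, post_logmar) {
  as.integer(round_half_away((pre_logmar - post_logmar) / 0.1))
}

#' Efficacy and safety indices
#'
#' The efficacy index is the mean postoperative uncorrected acuity (decimal)
#' divided by the mean baseline corrected acuity (decimal); the safety index
#' replaces the numerator with the postoperative corrected acuity. The
#' baseline is the preoperative CDVA except for cataract surgery, where
#' journal standards compare against the postoperative CDVA.
#'
#' Ratio-of-means is the default; set `per_eye = TRUE` for the mean of
#' per-eye ratios instead (requires equal-length, row-aligned vectors).
#'
#' @param numerator_logmar LogMAR values of the postop UDVA (efficacy) or
#'   postop CDVA (safety).
#' @param baseline_logmar LogMAR values of the baseline CDVA.
#' @param per_eye Use mean of per-eye ratios instead of ratio of means.
#' @return A single ratio.
#' @export
efficacy_index <- function(numerator_logmar, baseline_logmar, per_eye = FALSE) {
  if (!length(numerator_logmar) || !length(baseline_logmar)) {
    abort("Index computation needs non-empty acuity vectors.")
  }
  num <- logmar_to_decimal(numerator_logmar)
  den <- logmar_to_decimal(baseline_logmar)
  if (per_eye) {
    if (length(num) != length(den)) {
      abort("Per-eye index requires aligned vectors of equal length.")
    }
    mean(num / den)
  } else {
    mean(num) / mean(den)
  }
}

#' @rdname efficacy_index
#' @export
safety_index <- efficacy_index
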