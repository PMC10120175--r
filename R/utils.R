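# Internal helpers shared across modules.

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Normalize an axis in degrees to the clinical (0, 180] convention;
# an entered 0 means 180.
normalize_axis <- function(axis) {
  a <- axis %% 180
  ifelse(a == 0, 180, a)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
}
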