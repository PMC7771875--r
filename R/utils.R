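# Internal helpers shared across modules.

# Gyromagnetic ratio of 1H in MHz/T; Hz = ppm * GAMMA_HZ_PER_PPM_PER_T * B0[T].
GAMMA_MHZ_PER_T <- 42.576

#' @noRd
hz_to_ppm <- function(hz, field_strength_t) {
  hz / (GAMMA_MHZ_PER_T * field_strength_t)
}

#' @noRd
ppm_to_hz <- function(ppm, field_strength_t) {
  ppm * GAMMA_MHZ_PER_T * field_strength_t
}

# Trapezoidal integral over ordered abscissae.
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' @noRd
stopf <- function(fmt, ..., class = "aptwquant_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @noRd
warnf <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# Display rounding: half away from zero with a small fuzz so that values such
# as 0.935 (stored as 0.93499999...) render as printed clinical tables do.
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @noRd
fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "", formatC(round_half_up(x, digits), format = "f", digits = digits))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
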