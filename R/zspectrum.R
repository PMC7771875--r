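#' Z-spectrum object
#'
#' A sampled, \eqn{S_0}-normalized water saturation spectrum: signal
#' \eqn{S(\delta)/S_0} as a function of the saturation offset \eqn{\delta}
#' in ppm (positive downfield of water). Construct from raw intensities with
#' [normalize_zspectrum()].
#'
#' @param offsets_ppm Strictly increasing offsets in ppm.
#' @param signals Normalized signals, same length; values must lie in
#'   \[0, 1.1\] (small headroom above 1 for noise).
#' @param b0_shift_ppm Estimated B0 offset in ppm (0 until corrected).
#' @param corrected Logical; has [correct_b0()] been applied?
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets_ppm, signals, b0_shift_ppm = 0, corrected = FALSE) {
  if (length(offsets_ppm) != length(signals))
    stopf("offsets_ppm and signals must have equal length", class = "aptw_shape_error")
  if (any(diff(offsets_ppm) <= 0))
    stopf("offsets_ppm must be strictly increasing")
  if (any(!is.finite(signals)) || any(signals < 0) || any(signals > 1.1))
    stopf("signals must be finite and within [0, 1.1]")
  structure(
    list(
      offsets_ppm = as.numeric(offsets_ppm),
      signals = as.numeric(signals),
      b0_shift_ppm = b0_shift_ppm,
      corrected = isTRUE(corrected)
    ),
    class = "zspectrum"
  )
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf(
    "<zspectrum> %d offsets (%.2f .. %.2f ppm), min S/S0 = %.3f, %s (b0 = %+.3f ppm)\n",
    length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm), min(x$signals),
    if (x$corrected) "B0-corrected" else "uncorrected", x$b0_shift_ppm
  ))
  invisible(x)
}

#' Normalize raw saturation intensities into a Z-spectrum
#'
#' Divides each saturated acquisition by the unsaturated reference \eqn{S_0}
#' and converts the protocol's Hz offsets to ppm. Normalized values slightly
#' above 1 (noise) are clamped to 1.1 with a warning; negative raw intensities
#' are rejected.
#'
#' @param raw_signals Raw saturated intensities, one per protocol offset.
#' @param s0 Unsaturated reference intensity (> 0).
#' @param protocol A [saturation_protocol()].
#' @return An uncorrected [zspectrum()].
#' @export
#' @examples
#' p <- saturation_protocol()
#' z <- normalize_zspectrum(rep(80, 21), s0 = 100, p)
#' all(z$signals == 0.8)
normalize_zspectrum <- function(raw_signals, s0, protocol) {
  stopifnot(inherits(protocol, "saturation_protocol"))
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0)
    stopf("s0 must be a single positive intensity", class = "aptw_invalid_reference")
  if (length(raw_signals) != length(protocol$offsets_hz))
    stopf(
      "raw_signals has %d values but the protocol samples %d offsets",
      length(raw_signals), length(protocol$offsets_hz),
      class = "aptw_shape_error"
    )
  if (any(raw_signals < 0))
    stopf("negative raw intensities are not admissible")
  s <- raw_signals / s0
  if (any(s > 1.1)) {
    warnf("%d normalized signal(s) above 1.1 clamped", sum(s > 1.1))
    s <- pmin(s, 1.1)
  }
  zspectrum(protocol_offsets_ppm(protocol), s)
}

# Natural cubic spline interpolant of a z-spectrum's samples.
#' @noRd
zspec_spline <- function(z) {
  stats::splinefun(z$offsets_ppm, z$signals, method = "natural")
}

#' Correct a Z-spectrum for B0 inhomogeneity
#'
#' Locates the bottom of the Z-spectrum (direct water saturation) by cubic
#' spline interpolation on a fine grid centered on 0 ppm, refines the grid
#' argmin by one parabolic three-point fit, and re-centers the spectrum so
#' the minimum sits at 0 ppm. The corrected spectrum is resampled on the
#' nominal offset grid.
#'
#' A spectrum whose interpolated minimum falls on the boundary of the search
#' interval, or that has no interior dip, cannot be corrected and raises an
#' `aptw_uncorrectable` error.
#'
#' @param z An uncorrected [zspectrum()].
#' @param params An [asym_params()]; `fine_grid_step_ppm` and `b0_search_ppm`
#'   control the minimum search.
#' @return The corrected [zspectrum()] with `b0_shift_ppm` set to the located
#'   water-center offset \eqn{\delta_0}.
#' @export
correct_b0 <- function(z, params = asym_params()) {
  stopifnot(inherits(z, "zspectrum"), inherits(params, "asym_params"))
  if (z$corrected) stopf("zspectrum is already B0-corrected")
  step <- params$fine_grid_step_ppm
  half <- min(params$b0_search_ppm, -min(z$offsets_ppm), max(z$offsets_ppm))
  grid <- seq(-half, half, by = step)
  f <- zspec_spline(z)
  fg <- f(grid)
  i <- which.min(fg)
  if (i == 1L || i == length(grid))
    stopf(
      "no interior Z-spectrum minimum within +/- %.2f ppm: spectrum not correctable",
      half,
      class = "aptw_uncorrectable"
    )
  # parabolic sub-grid refinement of the argmin; degenerate (flat) fits keep
  # the grid node
  y1 <- fg[i - 1L]; y2 <- fg[i]; y3 <- fg[i + 1L]
  den <- y1 - 2 * y2 + y3
  d0 <- grid[i] + if (den > 0) 0.5 * step * (y1 - y3) / den else 0
  shifted <- f(z$offsets_ppm + d0)
  zspectrum(
    z$offsets_ppm,
    pmin(pmax(shifted, 0), 1.1),
    b0_shift_ppm = d0,
    corrected = TRUE
  )
}

#' MTRasym window integral (the APTw score)
#'
#' Computes the asymmetry of the Z-spectrum about water, averaged over the
#' amide window: the spectrum is interpolated on a fine grid, integrated by
#' trapezoid over \eqn{[-c-h, -c+h]} and \eqn{[c-h, c+h]} ppm
#' (defaults \eqn{c = 3.5}, \eqn{h = 0.4}), and the difference
#' upfield-minus-downfield is divided by the window width
#' `Deltafreq = 2h`. The result is a dimensionless fraction of \eqn{S_0};
#' multiply by 100 for percent.
#'
#' @param z A [zspectrum()], normally B0-corrected first.
#' @param params An [asym_params()].
#' @param allow_uncorrected Set `TRUE` to explicitly skip the corrected-flag
#'   check (e.g. for spectra known to be on-resonance).
#' @return APTw value as a fraction of \eqn{S_0}.
#' @export
#' @examples
#' p <- saturation_protocol()
#' d <- protocol_offsets_ppm(p)
#' z <- zspectrum(d, 1 - 0.8 / (1 + d^2))           # symmetric water line
#' abs(mtr_asym_integral(z, allow_uncorrected = TRUE)) < 1e-12
mtr_asym_integral <- function(z, params = asym_params(), allow_uncorrected = FALSE) {
  stopifnot(inherits(z, "zspectrum"), inherits(params, "asym_params"))
  if (!z$corrected && !allow_uncorrected)
    stopf("zspectrum is not B0-corrected; pass allow_uncorrected = TRUE to override")
  lo <- params$center_ppm - params$halfwidth_ppm
  hi <- params$center_ppm + params$halfwidth_ppm
  if (lo < min(z$offsets_ppm) || hi > max(z$offsets_ppm) ||
      -hi < min(z$offsets_ppm) || -lo > max(z$offsets_ppm))
    stopf(
      "asymmetry window [%.2f, %.2f] ppm not covered by sampled offsets",
      lo, hi,
      class = "aptw_coverage_error"
    )
  f <- zspec_spline(z)
  wplus <- seq(lo, hi, by = params$fine_grid_step_ppm)
  if (wplus[length(wplus)] < hi) wplus <- c(wplus, hi)
  wminus <- -rev(wplus)
  (trapz(wminus, f(wminus)) - trapz(wplus, f(wplus))) / (hi - lo)
}
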