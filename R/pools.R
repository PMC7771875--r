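#' Lorentzian saturation pool
#'
#' One exchanging (or direct-saturation) proton pool modeled as a Lorentzian
#' saturation line: at offset \eqn{\delta} it removes
#' \eqn{A / (1 + ((\delta - c) / (w/2))^2)} of the normalized water signal,
#' where \eqn{A} is the on-resonance saturation amplitude (fraction of
#' \eqn{S_0}), \eqn{c} the chemical shift and \eqn{w} the full width at half
#' maximum.
#'
#' @param center_ppm Pool chemical shift in ppm (positive downfield of water).
#' @param amplitude Saturation amplitude in \[0, 1).
#' @param fwhm_ppm Full width at half maximum in ppm (> 0).
#' @return An object of class `lorentzian_pool`.
#' @export
lorentzian_pool <- function(center_ppm, amplitude, fwhm_ppm) {
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude >= 1)
    stopf("amplitude must lie in [0, 1)")
  if (!is.numeric(fwhm_ppm) || fwhm_ppm <= 0)
    stopf("fwhm_ppm must be positive")
  structure(
    list(center_ppm = center_ppm, amplitude = amplitude, fwhm_ppm = fwhm_ppm),
    class = "lorentzian_pool"
  )
}

#' @noRd
lorentzian_value <- function(delta_ppm, pool) {
  h <- pool$fwhm_ppm / 2
  pool$amplitude / (1 + ((delta_ppm - pool$center_ppm) / h)^2)
}

# Exact average of a Lorentzian over [lo, hi] via its antiderivative
# A * h * atan((x - c)/h).
#' @noRd
lorentzian_window_average <- function(pool, lo, hi) {
  h <- pool$fwhm_ppm / 2
  pool$amplitude * h * (atan((hi - pool$center_ppm) / h) - atan((lo - pool$center_ppm) / h)) / (hi - lo)
}

#' Tissue pool set
#'
#' A labelled collection of [lorentzian_pool()]s describing one tissue class:
#' direct water saturation at 0 ppm, a broad semisolid magnetization-transfer
#' pool centered at -2.4 ppm, a relayed-NOE pool at -3.5 ppm and the amide
#' pool at +3.5 ppm whose amplitude carries the tumor-class contrast.
#'
#' @param label Tissue class label.
#' @param pools Named list of [lorentzian_pool()]s.
#' @return An object of class `tissue_pool_set`.
#' @seealso [make_pool_set()] for the calibrated class defaults.
#' @export
tissue_pool_set <- function(label, pools) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!all(vapply(pools, inherits, logical(1), "lorentzian_pool")))
    stopf("pools must be a list of lorentzian_pool objects")
  structure(list(label = label, pools = pools), class = "tissue_pool_set")
}

#' @export
print.tissue_pool_set <- function(x, ...) {
  cat(sprintf("<tissue_pool_set> %s (%d pools)\n", x$label, length(x$pools)))
  for (nm in names(x$pools)) {
    p <- x$pools[[nm]]
    cat(sprintf("  %-6s c = %+5.1f ppm  A = %.4f  fwhm = %4.1f ppm\n",
                nm, p$center_ppm, p$amplitude, p$fwhm_ppm))
  }
  invisible(x)
}

# Class targets in percent APTw; amide amplitudes are calibrated so the full
# sampling + B0 correction + asymmetry pipeline reproduces these on a clean
# spectrum. NAWM sits at 0 by construction of the asymmetry reference.
TISSUE_CLASS_TARGETS <- c(NAWM = 0.0, LGG = 1.49, HGG = 2.60, MET = 2.49, CSF = 0.0)

# Shared non-amide line parameters (amplitude, fwhm) for parenchymal classes.
#' @noRd
parenchyma_base_pools <- function() {
  list(
    water = lorentzian_pool(0, 0.85, 5.6),
    mt = lorentzian_pool(-2.4, 0.10, 25),
    noe = lorentzian_pool(-3.5, 0.03, 4.0)
  )
}

# First-order amide amplitude from the closed-form window averages: the
# asymmetry is linear in the amplitudes except for the weak dependence of the
# located B0 minimum on the pool set.
#' @noRd
amide_seed_amplitude <- function(target_fraction, base_pools, params, amide_fwhm) {
  lo <- params$center_ppm - params$halfwidth_ppm
  hi <- params$center_ppm + params$halfwidth_ppm
  g_other <- sum(vapply(base_pools, function(p) {
    lorentzian_window_average(p, lo, hi) - lorentzian_window_average(p, -hi, -lo)
  }, numeric(1)))
  unit <- lorentzian_pool(params$center_ppm, 0.5, amide_fwhm)
  g_amide <- (lorentzian_window_average(unit, lo, hi) -
                lorentzian_window_average(unit, -hi, -lo)) / 0.5
  (target_fraction - g_other) / g_amide
}

# Run the clean pipeline (no noise, no B0 offset) for a candidate amide
# amplitude and return the engine's APTw fraction.
#' @noRd
engine_response <- function(amide_amplitude, base_pools, protocol, params, amide_fwhm) {
  pools <- c(base_pools, list(amide = lorentzian_pool(params$center_ppm, amide_amplitude, amide_fwhm)))
  sim <- simulate_zspectrum(tissue_pool_set("calib", pools), protocol,
                            b0_shift_ppm = 0, noise_sd = 0)
  z <- correct_b0(normalize_zspectrum(sim$raw_signals, sim$s0, protocol), params)
  mtr_asym_integral(z, params)
}

#' Calibrate an amide amplitude against a target APTw value
#'
#' Solves for the amide-pool amplitude that makes the full quantification
#' pipeline (offset sampling, B0 correction, MTRasym window average) return
#' `target_percent` on a clean spectrum. A closed-form window-average seed is
#' refined by secant iteration through the engine itself, so the calibration
#' absorbs the pipeline's interpolation bias.
#'
#' @param target_percent Target APTw in percent of \eqn{S_0}.
#' @param base_pools Named list of the non-amide [lorentzian_pool()]s.
#' @param protocol A [saturation_protocol()].
#' @param params An [asym_params()].
#' @param amide_fwhm Amide line width in ppm; default 3.
#' @param tol Convergence tolerance on the APTw fraction; default 1e-9.
#' @return The calibrated amide amplitude (fraction of \eqn{S_0}).
#' @export
calibrate_amide_amplitude <- function(target_percent, base_pools,
                                      protocol = saturation_protocol(),
                                      params = asym_params(),
                                      amide_fwhm = 3.0, tol = 1e-9) {
  target <- target_percent / 100
  a0 <- max(amide_seed_amplitude(target, base_pools, params, amide_fwhm), 0)
  f0 <- engine_response(a0, base_pools, protocol, params, amide_fwhm) - target
  a1 <- a0 + 0.02
  f1 <- engine_response(a1, base_pools, protocol, params, amide_fwhm) - target
  for (it in seq_len(20)) {
    if (abs(f1) < tol || f1 == f0) break
    a2 <- a1 - f1 * (a1 - a0) / (f1 - f0)
    a2 <- max(a2, 0)
    a0 <- a1; f0 <- f1
    a1 <- a2
    f1 <- engine_response(a1, base_pools, protocol, params, amide_fwhm) - target
  }
  a1
}

# Calibration cache: label -> tissue_pool_set, filled lazily (the secant loop
# costs a few spectra per class).
.pool_cache <- new.env(parent = emptyenv())

#' Calibrated tissue pool sets
#'
#' Returns the default multi-pool model for a tissue class. Amide amplitudes
#' of the parenchymal classes are calibrated (see
#' [calibrate_amide_amplitude()]) so that a clean spectrum run through the
#' quantification pipeline yields the class's nominal APTw: 0\% for normal
#' appearing white matter, 1.49\% for low grade glioma, 2.60\% for high grade
#' glioma and 2.49\% for metastasis. The CSF-like class is a narrow water line
#' with no solute pools (APTw 0 by symmetry).
#'
#' @param label One of `"NAWM"`, `"LGG"`, `"HGG"`, `"MET"`, `"CSF"`.
#' @param protocol,params Acquisition and asymmetry settings the calibration
#'   targets; defaults are the package defaults.
#' @return A [tissue_pool_set()].
#' @export
#' @examples
#' ps <- make_pool_set("HGG")
#' ps$pools$amide$amplitude > make_pool_set("LGG")$pools$amide$amplitude
make_pool_set <- function(label, protocol = saturation_protocol(), params = asym_params()) {
  label <- match.arg(label, names(TISSUE_CLASS_TARGETS))
  key <- paste(label, protocol$field_strength, length(protocol$offsets_hz),
               params$center_ppm, params$halfwidth_ppm, sep = "|")
  cached <- .pool_cache[[key]]
  if (!is.null(cached)) return(cached)
  ps <- if (label == "CSF") {
    tissue_pool_set("CSF", list(water = lorentzian_pool(0, 0.95, 2.4)))
  } else {
    base <- parenchyma_base_pools()
    a <- calibrate_amide_amplitude(TISSUE_CLASS_TARGETS[[label]], base, protocol, params)
    tissue_pool_set(label, c(base, list(amide = lorentzian_pool(params$center_ppm, a, 3.0))))
  }
  .pool_cache[[key]] <- ps
  ps
}

#' Nominal APTw of a tissue class in percent
#'
#' The value the calibrated class pool set is constructed to produce.
#'
#' @param label Tissue class label.
#' @return APTw in percent.
#' @export
tissue_class_aptw <- function(label) {
  label <- match.arg(label, names(TISSUE_CLASS_TARGETS))
  TISSUE_CLASS_TARGETS[[label]]
}
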