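#' Saturation protocol for CEST acquisition
#'
#' Describes the off-resonance saturation scheme under which a Z-spectrum was
#' (or is to be) acquired: static field strength, saturation pulse train, the
#' sampled frequency offsets and the convention used for the unsaturated
#' reference acquisition \eqn{S_0}.
#'
#' The default values reproduce a clinical 3 T protocol: \eqn{B_1 = 2\,\mu T},
#' 21 equidistant offsets from \eqn{-610} to \eqn{+610} Hz (about
#' \eqn{\pm 4.78} ppm), five 100 ms hyperbolic-secant pulses separated by
#' 61 ms gaps, and an \eqn{S_0} reference acquired with far off-resonant
#' pre-saturation at \eqn{-150} ppm.
#'
#' @param field_strength Static field in tesla. Default 3.
#' @param b1_amplitude Saturation amplitude in microtesla. Default 2.
#' @param pulse_count Number of saturation pulses. Default 5.
#' @param pulse_duration Single pulse duration in ms. Default 100.
#' @param interpulse_delay Gap between pulses in ms. Default 61.
#' @param offsets_hz Strictly increasing saturation offsets in Hz relative to
#'   water. Default `seq(-610, 610, length.out = 21)`.
#' @param s0_offset_ppm Nominal offset (ppm) of the reference acquisition.
#'   Default -150.
#'
#' @return An object of class `saturation_protocol`.
#' @seealso [asym_params()], [normalize_zspectrum()]
#' @export
#' @examples
#' p <- saturation_protocol()
#' range(protocol_offsets_ppm(p))
saturation_protocol <- function(field_strength = 3,
                                b1_amplitude = 2,
                                pulse_count = 5,
                                pulse_duration = 100,
                                interpulse_delay = 61,
                                offsets_hz = seq(-610, 610, length.out = 21),
                                s0_offset_ppm = -150) {
  if (!is.numeric(field_strength) || length(field_strength) != 1L || field_strength <= 0)
    stopf("field_strength must be a single positive number (tesla)")
  if (!is_count(pulse_count))
    stopf("pulse_count must be a positive integer")
  if (!is.numeric(offsets_hz) || length(offsets_hz) < 3L || any(diff(offsets_hz) <= 0))
    stopf("offsets_hz must be a strictly increasing numeric vector (>= 3 offsets)")
  structure(
    list(
      field_strength = field_strength,
      b1_amplitude = b1_amplitude,
      pulse_count = as.integer(pulse_count),
      pulse_duration = pulse_duration,
      interpulse_delay = interpulse_delay,
      offsets_hz = as.numeric(offsets_hz),
      s0_offset_ppm = s0_offset_ppm
    ),
    class = "saturation_protocol"
  )
}

#' Saturation offsets of a protocol in ppm
#'
#' Converts the protocol's Hz offsets to ppm using the proton gyromagnetic
#' ratio (42.576 MHz/T); positive ppm is downfield of water.
#'
#' @param protocol A [saturation_protocol()].
#' @return Numeric vector of offsets in ppm, strictly increasing.
#' @export
protocol_offsets_ppm <- function(protocol) {
  stopifnot(inherits(protocol, "saturation_protocol"))
  hz_to_ppm(protocol$offsets_hz, protocol$field_strength)
}

#' @export
print.saturation_protocol <- function(x, ...) {
  cat(sprintf(
    "<saturation_protocol> %.1f T, B1 = %.2g uT, %d x %.0f ms pulses (%.0f ms gaps)\n",
    x$field_strength, x$b1_amplitude, x$pulse_count, x$pulse_duration, x$interpulse_delay
  ))
  cat(sprintf(
    "  %d offsets: %.0f .. %.0f Hz (%.2f .. %.2f ppm); S0 at %.0f ppm\n",
    length(x$offsets_hz), min(x$offsets_hz), max(x$offsets_hz),
    min(protocol_offsets_ppm(x)), max(protocol_offsets_ppm(x)), x$s0_offset_ppm
  ))
  invisible(x)
}

#' Asymmetry-analysis parameters
#'
#' Parameters of the MTRasym window integral: the window is
#' \eqn{[\Delta\omega - h, \Delta\omega + h]} mirrored about water, with
#' \eqn{\Delta\omega} = `center_ppm` and \eqn{h} = `halfwidth_ppm`, so the
#' full integration range `Deltafreq` is `2 * halfwidth_ppm` (0.8 ppm by
#' default). `fine_grid_step_ppm` controls the interpolation grid used both in
#' the B0 minimum search and in the window quadrature.
#'
#' @param center_ppm Window center \eqn{\Delta\omega} in ppm; default 3.5
#'   (amide protons).
#' @param halfwidth_ppm Window half width in ppm; default 0.4.
#' @param fine_grid_step_ppm Interpolation step in ppm; default 0.01.
#' @param b0_search_ppm Half width of the B0 minimum search interval about
#'   0 ppm; default 1.5.
#' @return An object of class `asym_params`.
#' @export
asym_params <- function(center_ppm = 3.5,
                        halfwidth_ppm = 0.4,
                        fine_grid_step_ppm = 0.01,
                        b0_search_ppm = 1.5) {
  if (!(halfwidth_ppm > 0 && halfwidth_ppm < center_ppm))
    stopf("need 0 < halfwidth_ppm < center_ppm")
  if (fine_grid_step_ppm <= 0)
    stopf("fine_grid_step_ppm must be positive")
  structure(
    list(
      center_ppm = center_ppm,
      halfwidth_ppm = halfwidth_ppm,
      fine_grid_step_ppm = fine_grid_step_ppm,
      b0_search_ppm = b0_search_ppm
    ),
    class = "asym_params"
  )
}

#' @export
print.asym_params <- function(x, ...) {
  cat(sprintf(
    "<asym_params> MTRasym(%.1f +/- %.1f ppm), Deltafreq = %.1f ppm, fine grid %.3g ppm\n",
    x$center_ppm, x$halfwidth_ppm, 2 * x$halfwidth_ppm, x$fine_grid_step_ppm
  ))
  invisible(x)
}

#' Read protocol and asymmetry parameters from a JSON config
#'
#' The JSON object may contain `protocol` and `asym` entries whose fields match
#' the arguments of [saturation_protocol()] and [asym_params()]; missing fields
#' fall back to the defaults. Unknown fields are rejected.
#'
#' @param path Path to a JSON file.
#' @return List with elements `protocol` and `asym`.
#' @export
read_protocol_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(cfg), c("protocol", "asym"))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  proto_args <- as.list(cfg$protocol %||% list())
  asym_args <- as.list(cfg$asym %||% list())
  bad_p <- setdiff(names(proto_args), names(formals(saturation_protocol)))
  bad_a <- setdiff(names(asym_args), names(formals(asym_params)))
  if (length(bad_p)) stopf("unknown protocol fields: %s", paste(bad_p, collapse = ", "))
  if (length(bad_a)) stopf("unknown asym fields: %s", paste(bad_a, collapse = ", "))
  list(
    protocol = do.call(saturation_protocol, proto_args),
    asym = do.call(asym_params, asym_args)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
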