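# Stored-intensity codec for APTw maps.
#
# APTw values (fraction of S0) are stored as 12-bit integers C(x,y) with
#   aptw = (C - 2048) / (scalefactor * 2000),   scalefactor = 10,
# i.e. one stored unit = 1/20000 = 0.005 percentage points, zero at code 2048.

APTW_CODE_OFFSET <- 2048L
APTW_SCALEFACTOR <- 10L
APTW_CODE_MAX <- 4095L

#' Encode APTw fractions as stored integer intensities
#'
#' `encode_aptw_intensity()` quantizes an APTw value (fraction of \eqn{S_0})
#' to the stored 12-bit code `round(aptw * 20000) + 2048`;
#' `decode_aptw_intensity()` inverts it. Values outside the representable
#' range (|aptw| > 0.1024, codes outside \[0, 4095\]) are clamped with a
#' saturation warning. The round trip `decode(encode(x))` is exact to within
#' half a quantization step (1/40000); `encode(decode(c)) == c` for every
#' stored code.
#'
#' @param aptw_fraction Numeric vector of APTw values as fractions of
#'   \eqn{S_0}.
#' @return Integer vector of stored codes in \[0, 4095\].
#' @export
#' @examples
#' decode_aptw_intensity(2568)   # 0.026, i.e. 2.6 percent
#' encode_aptw_intensity(0)      # 2048
encode_aptw_intensity <- function(aptw_fraction) {
  scale <- APTW_SCALEFACTOR * 2000
  code <- round(aptw_fraction * scale) + APTW_CODE_OFFSET
  out_of_range <- !is.na(code) & (code < 0 | code > APTW_CODE_MAX)
  if (any(out_of_range)) {
    warnf("%d APTw value(s) outside codec range clamped to saturation", sum(out_of_range))
    code <- pmin(pmax(code, 0), APTW_CODE_MAX)
  }
  as.integer(code)
}

#' @rdname encode_aptw_intensity
#' @param stored_integer Integer vector of stored codes.
#' @return `decode_aptw_intensity`: numeric vector of APTw fractions.
#' @export
decode_aptw_intensity <- function(stored_integer) {
  if (any(!is.na(stored_integer) &
          (stored_integer < 0 | stored_integer > APTW_CODE_MAX |
           stored_integer != floor(stored_integer))))
    stopf("stored codes must be integers in [0, %d]", APTW_CODE_MAX)
  (stored_integer - APTW_CODE_OFFSET) / (APTW_SCALEFACTOR * 2000)
}
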