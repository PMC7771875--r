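# Shared fixtures and independent oracles.

default_protocol <- saturation_protocol()
default_params <- asym_params()

final_cohort <- function() apply_exclusions(load_table1_fixture())

# Engine shortcut: pools -> APTw percent through the full pipeline.
engine_aptw_percent <- function(pools, b0 = 0, noise_sd = 0, seed = NULL) {
  sim <- simulate_zspectrum(pools, default_protocol, b0_shift_ppm = b0,
                            noise_sd = noise_sd, seed = seed)
  z <- correct_b0(normalize_zspectrum(sim$raw_signals, sim$s0, default_protocol),
                  default_params)
  100 * mtr_asym_integral(z, default_params)
}

# Independent fine-grid quadrature of a closed-form Lorentzian over a window.
lorentzian_window_quadrature <- function(center, amplitude, fwhm, lo, hi) {
  g <- seq(lo, hi, length.out = 4001)
  y <- amplitude / (1 + ((g - center) / (fwhm / 2))^2)
  sum(diff(g) * (y[-length(y)] + y[-1]) / 2) / (hi - lo)
}

# Brute-force maximal-mean ROI search: loops over every center on every
# slice, recomputing admissibility and the mean from scratch.
brute_force_max_roi <- function(values, lesion_mask, exclusion_mask, n_pixels) {
  offs <- disc_offsets(n_pixels)
  d <- dim(values)
  best <- NULL
  for (s in seq_len(d[3])) for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    rows <- r + offs[, 1]; cols <- cc + offs[, 2]
    if (any(rows < 1 | rows > d[1] | cols < 1 | cols > d[2])) next
    idx <- cbind(rows, cols, s)
    if (any(!lesion_mask[idx]) || any(exclusion_mask[idx]) || anyNA(values[idx])) next
    m <- mean(values[idx])
    if (is.null(best) || m > best$mean + 1e-15) {
      best <- list(slice = s, center = c(r, cc), mean = m)
    }
  }
  best
}

# Exhaustive likelihood grid search for logistic regression with one
# predictor (intercept + slope), refined over three zoom levels.
grid_search_logistic <- function(x, y) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta)))
  }
  center <- c(0, 0); width <- 20
  for (level in 1:6) {
    b0s <- seq(center[1] - width, center[1] + width, length.out = 41)
    b1s <- seq(center[2] - width, center[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    center <- unlist(grid[which.max(vals), ])
    width <- width / 10
  }
  center
}
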