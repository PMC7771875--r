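#' Simulate a raw saturation-offset acquisition for one voxel
#'
#' Evaluates the multi-pool Lorentzian model
#' \eqn{Z(\delta) = 1 - \sum_i L_i(\delta - \delta_{B0})} at the protocol
#' offsets, scales by the reference intensity and adds acquisition noise.
#' Gaussian noise (default) is added on the normalized signal; the Rician
#' option takes the magnitude of a complex signal with Gaussian noise in both
#' channels, the regime of low-SNR magnitude images.
#'
#' @param pools A [tissue_pool_set()].
#' @param protocol A [saturation_protocol()].
#' @param b0_shift_ppm Per-voxel B0 offset in ppm; default 0.
#' @param noise_sd Noise standard deviation as a fraction of \eqn{S_0};
#'   default 0.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param s0 Reference intensity; default 1000.
#' @param seed Optional integer; when given, the draw is deterministic and the
#'   caller's RNG state is untouched.
#' @return List with `raw_signals` (one per protocol offset) and `s0`.
#' @export
#' @examples
#' sim <- simulate_zspectrum(make_pool_set("HGG"), saturation_protocol(),
#'                           noise_sd = 0.005, seed = 1)
#' length(sim$raw_signals)
simulate_zspectrum <- function(pools, protocol = saturation_protocol(),
                               b0_shift_ppm = 0, noise_sd = 0,
                               noise_model = c("gaussian", "rician"),
                               s0 = 1000, seed = NULL) {
  stopifnot(inherits(pools, "tissue_pool_set"), inherits(protocol, "saturation_protocol"))
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  offs <- protocol_offsets_ppm(protocol)
  check <- seq(min(offs), max(offs), length.out = 201)
  sat <- rowSums(vapply(pools$pools, function(p) lorentzian_value(check - b0_shift_ppm, p),
                        numeric(length(check))))
  if (max(sat) >= 1)
    stopf("pool set saturates the water signal (sum of Lorentzians >= 1): invalid pool set")
  z <- 1 - rowSums(vapply(pools$pools, function(p) lorentzian_value(offs - b0_shift_ppm, p),
                          numeric(length(offs))))
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    z <- switch(noise_model,
      gaussian = z + stats::rnorm(length(z), sd = noise_sd),
      rician = sqrt((z + stats::rnorm(length(z), sd = noise_sd))^2 +
                    stats::rnorm(length(z), sd = noise_sd)^2)
    )
    z <- pmax(z, 0)
  }
  list(raw_signals = z * s0, s0 = s0)
}

#' Specification of a digital lesion phantom
#'
#' Describes a 3D phantom volume: a homogeneous background tissue class,
#' spherical lesion inserts (optionally with a necrotic core that is flagged
#' in the exclusion mask), a smooth polynomial B0 offset field and the noise
#' level.
#'
#' @param grid_dim Integer triplet, voxels per axis.
#' @param voxel_size_mm Numeric triplet, mm; default `c(2, 2, 4)`.
#' @param background Background tissue class label; default `"NAWM"`.
#' @param lesions List of lesions, each a list with `center` (voxel triplet),
#'   `radius` (voxels; a scalar sphere radius or per-axis semi-axes triplet
#'   for ellipsoids, matching anisotropic voxels), `class` (tissue label) and
#'   optional `necrotic_core_radius` (same convention).
#' @param b0_coef Coefficients `c(intercept, x, y, z)` of a linear-in-space
#'   B0 field in ppm over coordinates normalized to \[-1, 1\]; default no
#'   offset.
#' @param noise_sd Noise sd as a fraction of \eqn{S_0}; default 0.005.
#' @param seed Integer seed for the phantom's noise; default 1.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim, voxel_size_mm = c(2, 2, 4), background = "NAWM",
                         lesions = list(), b0_coef = c(0, 0, 0, 0),
                         noise_sd = 0.005, seed = 1) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 1L), length(b0_coef) == 4L)
  for (les in lesions) {
    if (is.null(les$center) || is.null(les$radius) || is.null(les$class))
      stopf("each lesion needs center, radius and class")
    r <- rep(les$radius, length.out = 3)
    if (any(les$center < 1) || any(les$center > grid_dim))
      stopf("lesion center outside the grid")
    if (any(les$center - r < 0.5) || any(les$center + r > grid_dim + 0.5))
      stopf("lesion of radius (%s) at (%s) extends outside the grid",
            paste(r, collapse = ", "), paste(les$center, collapse = ", "))
  }
  structure(
    list(grid_dim = grid_dim, voxel_size_mm = voxel_size_mm, background = background,
         lesions = lesions, b0_coef = as.numeric(b0_coef), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Build a digital lesion phantom
#'
#' Realizes a [phantom_spec()] as a synthetic acquisition: a 4D
#' saturation-offset stack, the \eqn{S_0} reference volume, the lesion and
#' exclusion (necrotic core) masks and a truth table with each lesion's class
#' and nominal APTw. Every voxel's spectrum is drawn from its tissue class's
#' calibrated pool set at the voxel's B0 offset; noise is independent across
#' voxels and offsets and deterministic under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param protocol A [saturation_protocol()].
#' @return List with `offset_stack` (4D array x,y,z,offset), `s0_volume` (3D),
#'   `lesion_mask`, `exclusion_mask` (3D logical), `class_map` (3D character)
#'   and `truth` (data frame: lesion, class, expected_aptw_percent).
#' @export
build_lesion_phantom <- function(spec, protocol = saturation_protocol()) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_dim
  n_off <- length(protocol$offsets_hz)

  class_map <- array(spec$background, dim = dm)
  lesion_mask <- array(FALSE, dim = dm)
  exclusion_mask <- array(FALSE, dim = dm)

  ax <- function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n)
  coords <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))

  ellipsoid <- function(center, radius) {
    r <- rep(radius, length.out = 3)
    ((coords$x - center[1]) / r[1])^2 + ((coords$y - center[2]) / r[2])^2 +
      ((coords$z - center[3]) / r[3])^2 <= 1
  }
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    inside <- ellipsoid(les$center, les$radius)
    if (any(lesion_mask[inside] | exclusion_mask[inside]))
      stopf("lesions overlap")
    class_map[inside] <- les$class
    core <- les$necrotic_core_radius
    if (!is.null(core) && all(core > 0)) {
      in_core <- ellipsoid(les$center, core)
      exclusion_mask[in_core] <- TRUE
      lesion_mask[inside & !in_core] <- TRUE
      class_map[in_core] <- "CSF"  # fluid-like necrotic content
    } else {
      lesion_mask[inside] <- TRUE
    }
  }

  b0 <- spec$b0_coef[1] +
    spec$b0_coef[2] * ax(dm[1])[coords$x] +
    spec$b0_coef[3] * ax(dm[2])[coords$y] +
    spec$b0_coef[4] * ax(dm[3])[coords$z]

  offs <- protocol_offsets_ppm(protocol)
  s0_ref <- 1000
  n_vox <- nrow(coords)
  signal <- matrix(0, n_vox, n_off)
  for (cls in unique(as.vector(class_map))) {
    ps <- make_pool_set(cls, protocol)
    idx <- which(as.vector(class_map) == cls)
    # offsets relative to each voxel's shifted water center
    delta <- outer(-b0[idx], offs, "+")
    z <- 1
    for (p in ps$pools) z <- z - lorentzian_value(delta, p)
    signal[idx, ] <- z
  }
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    signal <- pmax(signal + matrix(stats::rnorm(length(signal), sd = spec$noise_sd),
                                   nrow(signal)), 0)
  }
  offset_stack <- array(signal * s0_ref, dim = c(dm, n_off))
  s0_volume <- array(s0_ref, dim = dm)

  truth <- data.frame(
    lesion = seq_along(spec$lesions),
    class = vapply(spec$lesions, `[[`, character(1), "class"),
    expected_aptw_percent = vapply(spec$lesions,
                                   function(l) tissue_class_aptw(l$class), numeric(1)),
    stringsAsFactors = FALSE
  )
  list(offset_stack = offset_stack, s0_volume = s0_volume, lesion_mask = lesion_mask,
       exclusion_mask = exclusion_mask, class_map = class_map, truth = truth)
}
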