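#' APTw map object
#'
#' A voxel grid of APTw values stored as fractions of \eqn{S_0}
#' (multiply by 100 for percent), with voxel size metadata and a QC summary
#' of voxels that could not be quantified.
#'
#' @param values 3D numeric array of APTw fractions (`NA` = not quantifiable).
#' @param voxel_size_mm Numeric triplet, mm.
#' @param qc Optional list with QC counts.
#' @return An object of class `aptw_map`.
#' @export
aptw_map <- function(values, voxel_size_mm = c(2, 2, 4), qc = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  structure(list(values = values, voxel_size_mm = voxel_size_mm, qc = qc),
            class = "aptw_map")
}

#' @export
print.aptw_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<aptw_map> %s voxels (%.1fx%.1fx%.1f mm), APTw %.2f .. %.2f %%, %d missing\n",
              paste(dim(v), collapse = "x"),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              100 * min(v, na.rm = TRUE), 100 * max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Compute an APTw map from a saturation-offset stack
#'
#' Runs the single-spectrum pipeline — normalization by \eqn{S_0}, B0
#' correction from the bottom of the Z-spectrum, MTRasym window average — in
#' every voxel of a 4D offset stack. Voxels with a non-positive reference or
#' an uncorrectable spectrum are set to `NA` and counted in the QC summary.
#'
#' @param offset_stack 4D array (x, y, z, offset), raw intensities.
#' @param s0_volume 3D array of reference intensities on the same grid.
#' @param protocol A [saturation_protocol()].
#' @param params An [asym_params()].
#' @param voxel_size_mm Voxel size metadata for the result.
#' @return An [aptw_map()]; its `qc` lists `n_voxels`, `n_bad_reference`,
#'   `n_uncorrectable`.
#' @export
compute_aptw_map <- function(offset_stack, s0_volume,
                             protocol = saturation_protocol(),
                             params = asym_params(),
                             voxel_size_mm = c(2, 2, 4)) {
  d <- dim(offset_stack)
  if (length(d) != 4L)
    stopf("offset_stack must be 4D (x, y, z, offset)", class = "aptw_shape_error")
  if (!identical(d[1:3], dim(s0_volume)))
    stopf("offset_stack and s0_volume grids differ", class = "aptw_shape_error")
  if (d[4] != length(protocol$offsets_hz))
    stopf("offset_stack has %d offsets but the protocol samples %d",
          d[4], length(protocol$offsets_hz), class = "aptw_shape_error")

  n_vox <- prod(d[1:3])
  sig <- matrix(offset_stack, nrow = n_vox, ncol = d[4])
  s0 <- as.vector(s0_volume)
  out <- rep(NA_real_, n_vox)
  n_bad_ref <- 0L
  n_uncorrectable <- 0L
  for (v in seq_len(n_vox)) {
    if (!is.finite(s0[v]) || s0[v] <= 0) {
      n_bad_ref <- n_bad_ref + 1L
      next
    }
    res <- tryCatch({
      z <- normalize_zspectrum(pmin(sig[v, ], s0[v] * 1.1), s0[v], protocol)
      mtr_asym_integral(correct_b0(z, params), params)
    },
    aptw_uncorrectable = function(e) NA_real_)
    if (is.na(res)) n_uncorrectable <- n_uncorrectable + 1L
    out[v] <- res
  }
  aptw_map(array(out, dim = d[1:3]), voxel_size_mm,
           qc = list(n_voxels = n_vox, n_bad_reference = n_bad_ref,
                     n_uncorrectable = n_uncorrectable))
}

APTW_NIFTI_TAG <- "APTw int codec offset=2048 scalefactor=10"

#' Write / read APTw maps as NIfTI-1
#'
#' With `encode = TRUE` (default) the map is stored as 16-bit integers using
#' the stored-intensity codec (code 2048 = 0, 1 unit = 1/20000 of \eqn{S_0});
#' the codec is flagged in the NIfTI description field and undone
#' transparently by `read_aptw_nifti()`. `NA` voxels encode as code 0 minus
#' flag; they are stored as code 0 and restored as `NA` when the voxel equals
#' the saturation floor and `na_floor = TRUE`.
#'
#' @param map An [aptw_map()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param encode Store codec integers (default) or raw fractions as float.
#' @export
write_aptw_nifti <- function(map, path, encode = TRUE) {
  stopifnot(inherits(map, "aptw_map"))
  v <- map$values
  if (encode) {
    vals <- v
    vals[is.na(vals)] <- -0.1024  # saturates to code 0
    codes <- array(suppressWarnings(encode_aptw_intensity(vals)), dim = dim(v))
    attr(codes, "pixdim") <- map$voxel_size_mm
    img <- RNifti::asNifti(codes, datatype = "int16")
    img$descrip <- APTW_NIFTI_TAG
    RNifti::writeNifti(img, path)
  } else {
    vv <- v
    attr(vv, "pixdim") <- map$voxel_size_mm
    RNifti::writeNifti(RNifti::asNifti(vv, datatype = "double"), path)
  }
  invisible(path)
}

#' @rdname write_aptw_nifti
#' @param na_floor Treat stored code 0 as missing when decoding.
#' @export
read_aptw_nifti <- function(path, na_floor = TRUE) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  v <- as.array(img)
  # NIfTI readers may drop trailing singleton dimensions
  if (length(dim(v)) < 3L) dim(v) <- c(dim(v), rep(1L, 3L - length(dim(v))))
  vox <- hdr$pixdim[2:4]
  if (identical(trimws(hdr$descrip), APTW_NIFTI_TAG)) {
    dec <- decode_aptw_intensity(v)
    if (na_floor) dec[v == 0] <- NA_real_
    aptw_map(array(dec, dim = dim(v)), vox)
  } else {
    aptw_map(array(as.numeric(v), dim = dim(v)), vox)
  }
}

#' Write a logical mask or a volume as NIfTI-1
#'
#' Masks are stored as 8-bit integers (0/1); plain volumes as float.
#'
#' @param x 3D array (logical or numeric).
#' @param path Output path.
#' @param voxel_size_mm Voxel size triplet.
#' @export
write_volume_nifti <- function(x, path, voxel_size_mm = c(2, 2, 4)) {
  dt <- if (is.logical(x)) "uint8" else "double"
  y <- array(as.numeric(x), dim = dim(x))
  attr(y, "pixdim") <- voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(y, datatype = dt), path)
  invisible(path)
}
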