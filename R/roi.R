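#' Digital disc of a given pixel count
#'
#' The in-plane ROI shape used for quantification: the `n_pixels` voxels
#' nearest the center by Euclidean distance, ties broken by row offset then
#' column offset (ascending). Deterministic, so a "10-pixel ROI" is the same
#' set of offsets everywhere.
#'
#' @param n_pixels Number of member pixels (>= 1).
#' @return Integer matrix with columns `dr`, `dc` (row/column offsets from
#'   the center), `n_pixels` rows.
#' @export
#' @examples
#' disc_offsets(5)   # center plus the 4-neighborhood
disc_offsets <- function(n_pixels) {
  if (!is_count(n_pixels)) stopf("n_pixels must be a positive integer")
  r <- ceiling(sqrt(n_pixels / pi)) + 2L
  cand <- expand.grid(dr = -r:r, dc = -r:r)
  cand$d2 <- cand$dr^2 + cand$dc^2
  cand <- cand[order(cand$d2, cand$dr, cand$dc), ]
  m <- as.matrix(cand[seq_len(n_pixels), c("dr", "dc")])
  dimnames(m) <- list(NULL, c("dr", "dc"))
  m
}

#' @noRd
map_values <- function(map) {
  if (inherits(map, "aptw_map")) map$values else map
}

#' Place the maximal-signal ROI inside a lesion
#'
#' Searches every slice for the admissible disc placement with the highest
#' mean APTw: all member voxels must lie inside the image and the lesion
#' mask, outside the exclusion mask (hemorrhagic / cystic / necrotic tissue),
#' and carry a quantified (non-missing) value. Ties are broken toward the
#' lowest slice, then row, then column, so the search is a deterministic,
#' reproducible surrogate for manual placement at the hottest part of the
#' lesion.
#'
#' @param map An [aptw_map()] or 3D array.
#' @param lesion_mask 3D logical array.
#' @param exclusion_mask Optional 3D logical array.
#' @param n_pixels ROI size in pixels; default 10.
#' @return A `roi_placement`: list with `slice`, `center` (row, col),
#'   `offsets`, `n_pixels`, `roi_mean` (percent).
#' @export
find_max_roi <- function(map, lesion_mask, exclusion_mask = NULL, n_pixels = 10) {
  v <- map_values(map)
  stopifnot(identical(dim(v), dim(lesion_mask)))
  if (is.null(exclusion_mask)) exclusion_mask <- array(FALSE, dim(v))
  offs <- disc_offsets(n_pixels)
  d <- dim(v)
  ok_value <- !is.na(v) & lesion_mask & !exclusion_mask

  best <- NULL
  for (s in seq_len(d[3])) {
    vs <- v[, , s, drop = TRUE]
    oks <- ok_value[, , s, drop = TRUE]
    dim(vs) <- d[1:2]; dim(oks) <- d[1:2]
    # admissible centers and ROI sums, accumulated over the disc offsets by
    # index shifting
    adm <- matrix(TRUE, d[1], d[2])
    tot <- matrix(0, d[1], d[2])
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      shifted_ok <- matrix(FALSE, d[1], d[2])
      shifted_val <- matrix(0, d[1], d[2])
      r_src <- max(1, 1 + dr):min(d[1], d[1] + dr)
      c_src <- max(1, 1 + dc):min(d[2], d[2] + dc)
      if (length(r_src) && length(c_src)) {
        r_dst <- r_src - dr; c_dst <- c_src - dc
        shifted_ok[r_dst, c_dst] <- oks[r_src, c_src]
        shifted_val[r_dst, c_dst] <- ifelse(is.na(vs[r_src, c_src]), 0, vs[r_src, c_src])
      }
      adm <- adm & shifted_ok
      tot <- tot + shifted_val
    }
    if (!any(adm)) next
    means <- ifelse(adm, tot / n_pixels, -Inf)
    m <- max(means)
    if (is.null(best) || m > best$mean + 1e-15) {
      # first admissible argmax in column-major order = lowest col then row;
      # enforce row-then-col tie-break explicitly
      idx <- which(means >= m - 1e-15, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      best <- list(slice = s, center = unname(idx[1, ]), mean = m)
    }
  }
  if (is.null(best))
    stopf("no admissible ROI placement: lesion mask too small for a %d-pixel disc",
          n_pixels, class = "aptw_placement_error")
  structure(
    list(slice = best$slice, center = best$center, offsets = offs,
         n_pixels = n_pixels, roi_mean = 100 * best$mean),
    class = "roi_placement"
  )
}

#' @export
print.roi_placement <- function(x, ...) {
  cat(sprintf("<roi_placement> slice %d, center (%d, %d), %d pixels, ROI mean %.2f%%\n",
              x$slice, x$center[1], x$center[2], x$n_pixels, x$roi_mean))
  invisible(x)
}

#' @noRd
placement_values <- function(map, placement) {
  v <- map_values(map)
  rows <- placement$center[1] + placement$offsets[, 1]
  cols <- placement$center[2] + placement$offsets[, 2]
  if (any(rows < 1 | rows > dim(v)[1] | cols < 1 | cols > dim(v)[2]))
    stopf("ROI placement extends outside the image")
  v[cbind(rows, cols, placement$slice)]
}

#' @noRd
make_roi_stats <- function(values_percent) {
  structure(
    list(mean = mean(values_percent), max = max(values_percent),
         min = min(values_percent), range = max(values_percent) - min(values_percent),
         n = length(values_percent)),
    class = "roi_stats"
  )
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> n = %d: mean %.2f%%, max %.2f%%, min %.2f%%, range %.2f%%\n",
              x$n, x$mean, x$max, x$min, x$range))
  invisible(x)
}

#' ROI summary statistics
#'
#' Mean, maximum, minimum and range (max - min) of the APTw signal over the
#' member voxels of a placement, in percent of \eqn{S_0}.
#'
#' @param map An [aptw_map()] or 3D array of fractions.
#' @param placement A `roi_placement` from [find_max_roi()].
#' @return A `roi_stats` object (fields `mean`, `max`, `min`, `range`, `n`,
#'   percent).
#' @export
roi_stats <- function(map, placement) {
  stopifnot(inherits(placement, "roi_placement"))
  vals <- placement_values(map, placement)
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    stopf("ROI member voxel(s) %s have no quantified value",
          paste(bad, collapse = ", "))
  }
  make_roi_stats(100 * vals)
}

#' Whole-lesion single-slice statistics
#'
#' The whole-lesion variant of ROI quantification: statistics over every
#' admissible lesion voxel on one slice (exclusion mask subtracted, missing
#' voxels dropped are an error).
#'
#' @param map An [aptw_map()] or 3D array.
#' @param lesion_mask 3D logical array.
#' @param slice Slice index.
#' @param exclusion_mask Optional 3D logical array.
#' @return A `roi_stats` object (percent).
#' @export
whole_lesion_stats <- function(map, lesion_mask, slice, exclusion_mask = NULL) {
  v <- map_values(map)
  stopifnot(identical(dim(v), dim(lesion_mask)))
  if (is.null(exclusion_mask)) exclusion_mask <- array(FALSE, dim(v))
  sel <- lesion_mask[, , slice] & !exclusion_mask[, , slice]
  if (!any(sel))
    stopf("no admissible lesion voxels on slice %d", slice,
          class = "aptw_placement_error")
  vals <- v[, , slice][sel]
  if (anyNA(vals))
    stopf("%d lesion voxel(s) on slice %d have no quantified value",
          sum(is.na(vals)), slice)
  make_roi_stats(100 * vals)
}
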