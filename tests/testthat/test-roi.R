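test_that("disc offsets are the nearest pixels with deterministic tie-breaks", {
  expect_identical(disc_offsets(1), matrix(c(0L, 0L), 1, dimnames = list(NULL, c("dr", "dc"))))
  # n = 5: center plus 4-neighborhood, by brute-force nearest-neighbor oracle
  d5 <- disc_offsets(5)
  oracle <- expand.grid(dr = -3:3, dc = -3:3)
  oracle <- oracle[order(oracle$dr^2 + oracle$dc^2, oracle$dr, oracle$dc), ][1:5, ]
  expect_equal(unname(as.matrix(d5)), unname(as.matrix(oracle)))
  expect_setequal(apply(d5, 1, paste, collapse = ","),
                  c("0,0", "-1,0", "0,-1", "0,1", "1,0"))
  # n = 10 is stable across calls
  expect_identical(disc_offsets(10), disc_offsets(10))
  expect_equal(nrow(disc_offsets(10)), 10)
  expect_error(disc_offsets(0))
})

test_that("maximal ROI search agrees with exhaustive search on random instances", {
  set.seed(101)
  for (i in 1:6) {
    d <- c(sample(12:20, 1), sample(12:20, 1), sample(2:4, 1))
    v <- array(runif(prod(d), -0.01, 0.04), dim = d)
    lesion <- array(runif(prod(d)) < 0.7, dim = d)
    excl <- array(runif(prod(d)) < 0.05, dim = d)
    v[sample(prod(d), 5)] <- NA
    oracle <- brute_force_max_roi(v, lesion, excl, 10)
    if (is.null(oracle)) {
      expect_error(find_max_roi(v, lesion, excl, 10), class = "aptw_placement_error")
    } else {
      got <- find_max_roi(v, lesion, excl, 10)
      expect_equal(got$slice, oracle$slice)
      expect_equal(got$center, oracle$center)
      expect_equal(got$roi_mean, 100 * oracle$mean, tolerance = 1e-10)
    }
  }
})

test_that("ties resolve to the first admissible placement in scan order", {
  v <- array(0.02, dim = c(8, 8, 2))
  lesion <- array(TRUE, dim = c(8, 8, 2))
  got <- find_max_roi(v, lesion, n_pixels = 10)
  oracle <- brute_force_max_roi(v, lesion, array(FALSE, dim(v)), 10)
  expect_equal(got$slice, oracle$slice)
  expect_equal(got$center, oracle$center)
})

test_that("a hot insert attracts the ROI center", {
  d <- c(24, 24, 3)
  v <- array(0.005, dim = d)
  cx <- 15; cy <- 10
  for (r in 1:d[1]) for (cc in 1:d[2]) {
    if ((r - cx)^2 + (cc - cy)^2 <= 25) v[r, cc, 2] <- 0.03
  }
  lesion <- array(TRUE, dim = d)
  got <- find_max_roi(v, lesion, n_pixels = 10)
  expect_equal(got$slice, 2)
  expect_lte((got$center[1] - cx)^2 + (got$center[2] - cy)^2, 25)
})

test_that("masks too small for the disc raise a placement error", {
  v <- array(0.01, dim = c(8, 8, 1))
  lesion <- array(FALSE, dim = c(8, 8, 1))
  lesion[4, 4:6, 1] <- TRUE  # 3 voxels
  expect_error(find_max_roi(v, lesion, n_pixels = 10), class = "aptw_placement_error")
})

test_that("the found placement is never beaten by a random admissible one", {
  set.seed(77)
  d <- c(16, 16, 2)
  v <- array(runif(prod(d), 0, 0.05), dim = d)
  lesion <- array(TRUE, dim = d)
  best <- find_max_roi(v, lesion, n_pixels = 10)
  offs <- disc_offsets(10)
  for (i in 1:50) {
    ctr <- c(sample(3:14, 1), sample(3:14, 1))
    s <- sample(1:2, 1)
    m <- mean(v[cbind(ctr[1] + offs[, 1], ctr[2] + offs[, 2], s)])
    expect_lte(100 * m, best$roi_mean + 1e-12)
  }
})

test_that("ROI statistics are exact over the member voxels, in percent", {
  v <- array(0.02, dim = c(8, 8, 1))
  lesion <- array(TRUE, dim = c(8, 8, 1))
  pl <- find_max_roi(v, lesion, n_pixels = 10)
  st <- roi_stats(v, pl)
  expect_equal(st$mean, 2); expect_equal(st$max, 2)
  expect_equal(st$min, 2); expect_equal(st$range, 0)

  # hand-arithmetic oracle: members 0.1% .. 1.0%
  v2 <- array(0, dim = c(9, 9, 1))
  offs <- disc_offsets(10)
  for (k in 1:10) v2[5 + offs[k, 1], 5 + offs[k, 2], 1] <- k / 1000
  pl2 <- structure(list(slice = 1, center = c(5, 5), offsets = offs, n_pixels = 10),
                   class = "roi_placement")
  st2 <- roi_stats(v2, pl2)
  expect_equal(st2$mean, 0.55)
  expect_equal(st2$range, 0.9)

  v2[5, 5, 1] <- NA
  expect_error(roi_stats(v2, pl2), "no quantified value")
})

test_that("whole-lesion single-slice statistics summarize the admissible voxels", {
  v <- array(0.02, dim = c(10, 10, 2))
  mask <- array(TRUE, dim = c(10, 10, 2))
  st <- whole_lesion_stats(v, mask, slice = 1)
  expect_equal(st$mean, 2); expect_equal(st$range, 0)

  v2 <- array(rep(c(0.01, 0.03), each = 50), dim = c(10, 10, 1))
  st2 <- whole_lesion_stats(v2, array(TRUE, dim = c(10, 10, 1)), slice = 1)
  expect_equal(st2$mean, 2); expect_equal(st2$range, 2)

  empty <- array(FALSE, dim = c(10, 10, 2))
  expect_error(whole_lesion_stats(v, empty, slice = 1), class = "aptw_placement_error")
})

test_that("whole-lesion mean lies within any sub-ROI envelope on the slice", {
  set.seed(5)
  v <- array(runif(200, 0, 0.05), dim = c(10, 10, 2))
  mask <- array(TRUE, dim = c(10, 10, 2))
  wl <- whole_lesion_stats(v, mask, slice = 1)
  pl <- find_max_roi(v[, , 1, drop = FALSE], mask[, , 1, drop = FALSE], n_pixels = 10)
  sub <- roi_stats(v[, , 1, drop = FALSE], pl)
  expect_gte(wl$mean, wl$min); expect_lte(wl$mean, wl$max)
  expect_lte(wl$min, sub$min + 1e-12); expect_gte(wl$max, sub$max - 1e-12)
})
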