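test_that("calibrated pool sets reproduce their nominal class APTw", {
  expect_lt(abs(engine_aptw_percent(make_pool_set("HGG")) - 2.60), 0.2)
  expect_lt(abs(engine_aptw_percent(make_pool_set("LGG")) - 1.49), 0.2)
  expect_lt(abs(engine_aptw_percent(make_pool_set("MET")) - 2.49), 0.2)
  expect_error(make_pool_set("bone"))
})

test_that("amide amplitudes order NAWM < LGG < HGG", {
  a <- vapply(c("NAWM", "LGG", "HGG"),
              function(l) make_pool_set(l)$pools$amide$amplitude, numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("a symmetric pool set without amide gives zero APTw", {
  ps <- tissue_pool_set("sym", list(
    water = lorentzian_pool(0, 0.85, 5.6),
    noe_dn = lorentzian_pool(-3.5, 0.03, 4.0),
    noe_up = lorentzian_pool(3.5, 0.03, 4.0)   # mirrored partner
  ))
  expect_lt(abs(engine_aptw_percent(ps)), 1e-10)
})

test_that("spectrum simulation is deterministic under a seed and leaves the RNG alone", {
  ps <- make_pool_set("LGG")
  s1 <- simulate_zspectrum(ps, noise_sd = 0.01, seed = 7)
  set.seed(123); before <- runif(1)
  s2 <- simulate_zspectrum(ps, noise_sd = 0.01, seed = 7)
  set.seed(123); expect_identical(runif(1), before)
  expect_identical(s1$raw_signals, s2$raw_signals)
})

test_that("noisy APTw estimates are unbiased against the noiseless oracle", {
  ps <- make_pool_set("HGG")
  clean <- engine_aptw_percent(ps)
  vals <- vapply(1:200, function(s) engine_aptw_percent(ps, noise_sd = 0.005, seed = s),
                 numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - clean), 2 * se + 1e-6)
})

test_that("over-saturating pool sets are rejected", {
  ps <- tissue_pool_set("bad", list(
    water = lorentzian_pool(0, 0.9, 4),
    mt = lorentzian_pool(0, 0.2, 30)
  ))
  expect_error(simulate_zspectrum(ps), "invalid pool set")
})

test_that("lesion phantoms honor their specification", {
  spec <- phantom_spec(c(16, 16, 3), noise_sd = 0,
                       lesions = list(list(center = c(8, 8, 2), radius = c(4, 4, 1),
                                           class = "HGG")))
  ph <- build_lesion_phantom(spec, default_protocol)
  expect_identical(dim(ph$offset_stack), c(16L, 16L, 3L, 21L))
  expect_true(sum(ph$lesion_mask) > 0)
  # lesion voxels carry the HGG spectrum: single-voxel oracle
  map <- compute_aptw_map(ph$offset_stack, ph$s0_volume, default_protocol)
  expect_lt(abs(100 * mean(map$values[ph$lesion_mask]) -
                ph$truth$expected_aptw_percent[1]), 0.1)
  expect_gt(mean(map$values[ph$lesion_mask]), mean(map$values[!ph$lesion_mask]))
})

test_that("an empty lesion list gives a pure background volume", {
  spec <- phantom_spec(c(6, 6, 2), noise_sd = 0)
  ph <- build_lesion_phantom(spec, default_protocol)
  expect_true(all(ph$class_map == "NAWM"))
  expect_false(any(ph$lesion_mask))
  expect_equal(nrow(ph$truth), 0)
})

test_that("necrotic cores populate the exclusion mask, disjoint from viable lesion", {
  spec <- phantom_spec(c(16, 16, 3), noise_sd = 0,
                       lesions = list(list(center = c(8, 8, 2), radius = c(5, 5, 1),
                                           class = "HGG",
                                           necrotic_core_radius = c(2, 2, 0.5))))
  ph <- build_lesion_phantom(spec, default_protocol)
  expect_gt(sum(ph$exclusion_mask), 0)
  expect_false(any(ph$exclusion_mask & ph$lesion_mask))
})

test_that("overlapping or out-of-grid lesions are rejected", {
  expect_error(build_lesion_phantom(phantom_spec(
    c(16, 16, 3),
    lesions = list(list(center = c(8, 8, 2), radius = c(4, 4, 1), class = "HGG"),
                   list(center = c(9, 9, 2), radius = c(4, 4, 1), class = "LGG"))
  )), "overlap")
  expect_error(phantom_spec(c(8, 8, 2),
                            lesions = list(list(center = c(7, 7, 1), radius = 4,
                                                class = "HGG"))),
               "outside the grid")
})

test_that("simulated cohorts respect the min <= mean <= max constraint and the seed", {
  coh <- simulate_cohort_table(cohort_sim_params(seed = 5))
  expect_true(all(coh$aptw_min <= coh$aptw_mean & coh$aptw_mean <= coh$aptw_max))
  coh2 <- simulate_cohort_table(cohort_sim_params(seed = 5))
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
  expect_equal(as.integer(table(coh$group)[c("HGG", "LGG", "MET")]), c(16L, 6L, 2L))
})

test_that("degenerate cohort settings behave as specified", {
  # zero dispersion with separated means: threshold scores separate perfectly
  p0 <- cohort_sim_params(n = c(HGG = 8, LGG = 8),
                          group_sds = list(HGG = c(0, 0, 0), LGG = c(0, 0, 0)),
                          seed = 3)
  coh <- simulate_cohort_table(p0)
  expect_equal(roc_curve(coh$aptw_mean, coh$group)$auc, 1.0)
  # a single group is a valid table
  one <- simulate_cohort_table(cohort_sim_params(n = c(HGG = 0, LGG = 6), seed = 2))
  expect_equal(nrow(one), 6)
  expect_true(all(one$group == "LGG"))
})

test_that("cohorts at the clinical effect sizes give high Mann-Whitney power", {
  p <- cohort_sim_params(n = c(HGG = 16, LGG = 6))
  reject <- vapply(1:500, function(s) {
    p$seed <- s
    coh <- simulate_cohort_table(p)
    mw <- mann_whitney(coh$aptw_mean[coh$group == "HGG"],
                       coh$aptw_mean[coh$group == "LGG"])
    mw$p_exact < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})
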