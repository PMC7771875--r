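test_that("Mann-Whitney U reproduces the clinical comparisons", {
  final <- final_cohort()
  hgg <- final[final$group == "HGG", ]; lgg <- final[final$group == "LGG", ]
  u <- function(col) mann_whitney(hgg[[col]], lgg[[col]])
  expect_equal(u("aptw_max")$u_statistic, 5)
  expect_equal(u("aptw_min")$u_statistic, 22)
  expect_equal(u("aptw_range")$u_statistic, 19)
  mw_mean <- u("aptw_mean")
  expect_equal(round(mw_mean$mean_rank_a, 2), 13.88)
  expect_equal(round(mw_mean$mean_rank_b, 2), 5.17)
  expect_equal(round(mw_mean$p_asymptotic, 3), 0.005)
  expect_equal(round(u("aptw_min")$p_asymptotic, 3), 0.055)
})

test_that("midranks give half credit for ties", {
  mw <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  # brute-force pair counting: wins + half-ties = 3 of 9 pairs tied, 3 won
  expect_equal(mw$u_statistic, 4.5)
  expect_equal(mw$mean_rank_a, mw$mean_rank_b)
  expect_error(mann_whitney(numeric(0), 1:3), "at least one")
})

test_that("exact p by enumeration matches the tie-free closed form and handles ties", {
  set.seed(21)
  a <- rnorm(7); b <- rnorm(5)
  mw <- mann_whitney(a, b)
  # independent check via the exact null distribution of U
  mu <- 7 * 5 / 2; d <- abs(mw$u_a - mu)
  want <- pwilcox(mu - d, 7, 5) + pwilcox(mu + d - 1, 7, 5, lower.tail = FALSE)
  expect_equal(mw$p_exact, min(1, want))
  # tied data: enumeration against a direct combn oracle
  a2 <- c(1, 2, 2, 3); b2 <- c(2, 3, 4)
  mw2 <- mann_whitney(a2, b2)
  r <- rank(c(a2, b2))
  cmb <- combn(7, 3)
  sums <- colSums(matrix(r[cmb], nrow = 3))
  u_all <- sums - 6
  mu2 <- 4 * 3 / 2
  expect_equal(mw2$p_exact, mean(abs(u_all - mu2) >= abs(mw2$u_b - mu2) - 1e-9))
})

test_that("exact and asymptotic p agree for moderately sized groups", {
  # the normal approximation (no continuity correction) targets the mid-p of
  # the discrete null: the exact p minus half the observed point mass
  set.seed(33)
  for (i in 1:20) {
    n1 <- sample(8:12, 1); n2 <- sample(8:12, 1)
    a <- rnorm(n1, mean = runif(1, 0, 1.5)); b <- rnorm(n2)
    mw <- mann_whitney(a, b)
    mu <- n1 * n2 / 2; d <- abs(mw$u_a - mu)
    point <- if (d == 0) dwilcox(mu, n1, n2) else
      dwilcox(mu - d, n1, n2) + dwilcox(mu + d, n1, n2)
    expect_lt(abs((mw$p_exact - point / 2) - mw$p_asymptotic), 0.02)
  }
})

test_that("ROC analysis reproduces the single-marker clinical table", {
  final <- final_cohort()
  r_mean <- roc_curve(final$aptw_mean, final$group)
  expect_equal(round(r_mean$auc, 3), 0.896)
  expect_equal(r_mean$optimal_cutoff, (1.72 + 2.07) / 2)  # midpoint -> 1.90
  expect_equal(round(100 * r_mean$sensitivity, 1), 93.8)
  expect_equal(round(100 * r_mean$specificity, 1), 83.3)
  r_max <- roc_curve(final$aptw_max, final$group)
  expect_equal(round(r_max$auc, 3), 0.948)
  expect_equal(r_max$optimal_cutoff, 2.48)
  expect_equal(r_max$specificity, 1)
})

test_that("ROC handles separation and degenerate class input", {
  r <- roc_curve(c(5, 6, 7, 1, 2), c("HGG", "HGG", "HGG", "LGG", "LGG"))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_error(roc_curve(1:4, rep("HGG", 4)), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  final <- final_cohort()
  for (col in c("aptw_mean", "aptw_max", "aptw_range")) {
    mine <- roc_curve(final[[col]], final$group)
    ref <- pROC::roc(response = final$group, predictor = final[[col]],
                     levels = c("LGG", "HGG"), direction = "<", quiet = TRUE)
    expect_equal(mine$auc, as.numeric(ref$auc), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(unname(mine$ci95["lower"]), max(0, ci[1]), tolerance = 1e-8)
    expect_equal(unname(mine$ci95["upper"]), min(1, ci[3]), tolerance = 1e-8)
  }
})

test_that("ROC cutoff sweep is consistent with the threshold classifier", {
  final <- final_cohort()
  r <- roc_curve(final$aptw_mean, final$group)
  for (i in which(r$coords$cutoff > 0)) {
    ct <- r$coords$cutoff[i]
    cls <- classify_cohort(final, threshold_rule("mean", ct))
    expect_equal(cls$sensitivity, r$coords$sensitivity[i])
    expect_equal(cls$specificity, r$coords$specificity[i])
  }
})

test_that("AUC equals the rank identity on tie-free data", {
  set.seed(13)
  for (i in 1:10) {
    pos <- rnorm(9, 1); neg <- rnorm(7)
    r <- roc_curve(c(pos, neg), rep(c("HGG", "LGG"), c(9, 7)))
    mw <- mann_whitney(pos, neg)
    expect_equal(r$auc, mw$u_a / (9 * 7), tolerance = 1e-14)
  }
})

test_that("logistic regression maximizes the likelihood (grid-search oracle)", {
  x <- c(-1.2, -0.4, 0.1, 0.8, 1.5, 2.0)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- logistic_fit(matrix(x, ncol = 1), y)
  oracle <- grid_search_logistic(x, y)
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-3)
  expect_gte(fit$ll_model, fit$ll_null)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("intercept-only fits return the class prevalence", {
  y <- c(1, 1, 0, 0, 0, 1, 0, 0)
  fit <- logistic_fit(matrix(numeric(0), nrow = 8, ncol = 0), y)
  expect_equal(fit$fitted, rep(mean(y), 8), tolerance = 1e-8)
  expect_equal(nagelkerke_r2(fit), 0, tolerance = 1e-8)
})

test_that("the combined clinical model matches its published diagnostics", {
  model <- fit_combined_model(final_cohort())
  expect_equal(round(roc_curve(model$fitted, model$groups)$auc, 3), 0.958)
  expect_lt(abs(nagelkerke_r2(model) - 0.722), 0.005)
  om <- omnibus_test(model)
  expect_equal(om$df, 3)
  expect_lt(om$p_value, 0.002)
  hl <- suppressWarnings(hosmer_lemeshow(model))
  expect_gte(hl$p_value, 0); expect_lte(hl$p_value, 1)
  expect_equal(sum(hl$table$n), 22)
})

test_that("Nagelkerke R2 approaches 1 on separable data", {
  x <- c(rep(0, 6), rep(5, 6)); y <- rep(c(0, 1), each = 6)
  fit <- suppressWarnings(logistic_fit(matrix(x, ncol = 1), y))
  expect_gt(nagelkerke_r2(fit), 0.95)
})

test_that("Hosmer-Lemeshow reduces groups when fitted probabilities repeat", {
  x <- rep(c(0, 1), each = 10); y <- c(rbinom(10, 1, 0.3), rbinom(10, 1, 0.7))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  fit <- suppressWarnings(logistic_fit(matrix(x, ncol = 1), y))
  expect_warning(hl <- hosmer_lemeshow(fit, groups = 10), "reducing")
  expect_lte(hl$groups, 3)
})

test_that("the normality screen is calibrated and detects skew", {
  hits <- vapply(1:200, function(s) {
    set.seed(s); shapiro_wilk(rnorm(50))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(42)
  expect_lt(shapiro_wilk(rexp(50))$p_value, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("molecular subgroup descriptives reproduce the clinical strata", {
  final <- final_cohort()
  mg <- subgroup_means(final, "mgmt")
  expect_equal(mg$n, c(10, 3))
  expect_equal(round(mg$mean, 2), c(2.38, 1.92))
  expect_false(mg$sufficient_for_testing[2])
  idh <- subgroup_means(final, "idh")
  expect_equal(idh$n, c(13, 7))
  expect_equal(round(idh$mean, 2), c(2.26, 2.30))
  expect_equal(attr(idh, "n_unknown"), 2)
  # empty stratum stays missing
  none <- cohort_table(data.frame(id = 1:3, group = "HGG", aptw_mean = 2,
                                  aptw_max = 3, aptw_min = 1,
                                  mgmt_status = "methylated"), "simulated")
  sm <- subgroup_means(none, "mgmt")
  expect_true(is.na(sm$mean[sm$stratum == "non-methylated"]))
})
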