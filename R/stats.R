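#' Mann-Whitney U test with tie handling and exact enumeration
#'
#' Rank-based two-group comparison using midranks for ties. The reported U is
#' taken from the smaller of the two group U values (the convention of common
#' clinical statistics software). The asymptotic p-value uses the
#' tie-corrected normal approximation without continuity correction; an exact
#' two-sided p-value (probability of a rank-sum at least as far from its null
#' mean, over all group assignments) is additionally computed when feasible:
#' via the exact tie-free null distribution when there are no ties, otherwise
#' by full enumeration of group assignments.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param exact_limit Enumeration is attempted while `n1 * n2` is at most
#'   this and the number of assignments is at most 2e5; default 1e5.
#' @return A `mann_whitney_result`: `u_statistic`, `u_a`, `u_b`,
#'   `mean_rank_a`, `mean_rank_b`, `z`, `p_asymptotic`, `p_exact` (`NA` when
#'   infeasible), `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(1, 2, 3))$u_statistic   # 4.5 with midranks
mann_whitney <- function(group_a, group_b, exact_limit = 1e5) {
  if (!length(group_a) || !length(group_b))
    stopf("both groups must contain at least one value")
  n1 <- length(group_a); n2 <- length(group_b); N <- n1 + n2
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  ra <- sum(r[seq_len(n1)]); rb <- sum(r) - ra
  u_a <- ra - n1 * (n1 + 1) / 2
  u_b <- rb - n2 * (n2 + 1) / 2
  u <- min(u_a, u_b)
  mu <- n1 * n2 / 2
  tie_sizes <- table(r)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (u_a - mu) / sqrt(sigma2) else NA_real_
  p_asym <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))

  has_ties <- any(tie_sizes > 1)
  p_exact <- NA_real_
  if (n1 * n2 <= exact_limit) {
    d <- abs(u_a - mu)
    if (!has_ties) {
      # exact tie-free null of U (symmetric about mu)
      p_exact <- min(1, stats::pwilcox(mu - d, n1, n2) +
                       stats::pwilcox(mu + d - 1, n1, n2, lower.tail = FALSE))
    } else {
      k <- min(n1, n2)
      if (choose(N, k) <= 2e5) {
        cmb <- utils::combn(N, k)
        sums <- colSums(matrix(r[cmb], nrow = k))
        u_all <- sums - k * (k + 1) / 2
        mu_k <- k * (N - k) / 2
        p_exact <- mean(abs(u_all - mu_k) >= d - 1e-9)
      }
    }
  }
  structure(
    list(u_statistic = u, u_a = u_a, u_b = u_b,
         mean_rank_a = ra / n1, mean_rank_b = rb / n2,
         z = z, p_asymptotic = p_asym, p_exact = p_exact,
         n_a = n1, n_b = n2, ties = has_ties),
    class = "mann_whitney_result"
  )
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("<mann_whitney_result> U = %.1f (n = %d vs %d), mean ranks %.2f / %.2f\n",
              x$u_statistic, x$n_a, x$n_b, x$mean_rank_a, x$mean_rank_b))
  cat(sprintf("  p (tie-corrected normal) = %.4g; p (exact) = %.4g\n",
              x$p_asymptotic, x$p_exact))
  invisible(x)
}

# DeLong variance of the empirical AUC (placements method).
#' @noRd
delong_ci <- function(pos, neg, auc, level = 0.95) {
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - zq * se), upper = min(1, auc + zq * se), se = se)
}

#' Empirical ROC curve with Youden-midpoint cutoff
#'
#' Builds the empirical ROC of a score against a binary label under the rule
#' "score strictly greater than the cutoff predicts positive". Candidate
#' cutoffs are the midpoints between adjacent distinct observed scores
#' (plus sentinels below and above all scores); the AUC is the concordance
#' probability (ties counted half), which equals the trapezoidal area; the
#' optimal cutoff maximizes the Youden index J = sensitivity + specificity -
#' 1, ties broken toward higher specificity. The 95\% CI uses the DeLong
#' variance; the p-value is the tie-corrected Mann-Whitney normal
#' approximation for the same comparison.
#'
#' @param scores Numeric vector.
#' @param labels Vector of class labels.
#' @param positive Label counted as positive; default `"HGG"`.
#' @return A `roc_result`: `auc`, `ci95` (DeLong), `p_value`,
#'   `optimal_cutoff`, `sensitivity`, `specificity` (at the optimal cutoff),
#'   `youden`, `coords` (data frame cutoff/sensitivity/specificity), `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' final <- apply_exclusions(load_table1_fixture())
#' r <- roc_curve(final$aptw_max, final$group)
#' round(r$auc, 3); r$optimal_cutoff
roc_curve <- function(scores, labels, positive = "HGG") {
  stopifnot(length(scores) == length(labels))
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos))
    stopf("both classes must be present to build a ROC curve")
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))

  s <- sort(unique(scores))
  cutoffs <- c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  sens <- vapply(cutoffs, function(ct) mean(pos > ct), numeric(1))
  spec <- vapply(cutoffs, function(ct) mean(neg <= ct), numeric(1))
  j <- sens + spec - 1
  # maximize J; among ties prefer higher specificity, then the lower cutoff
  best <- order(-j, -spec, cutoffs)[1]

  mw <- mann_whitney(pos, neg)
  structure(
    list(auc = auc,
         ci95 = delong_ci(pos, neg, auc),
         ci_method = "DeLong",
         p_value = mw$p_asymptotic,
         optimal_cutoff = cutoffs[best],
         sensitivity = sens[best], specificity = spec[best],
         youden = j[best],
         coords = data.frame(cutoff = cutoffs, sensitivity = sens, specificity = spec),
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f, DeLong), p = %.4g\n",
              x$auc, x$ci95["lower"], x$ci95["upper"], x$p_value))
  cat(sprintf("  optimal cutoff %.3f: sensitivity %.1f%%, specificity %.1f%%\n",
              x$optimal_cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Maximum-likelihood logistic regression
#'
#' Binary logistic regression fitted by iteratively reweighted least squares
#' (Newton-Raphson; log-likelihood tolerance 1e-8, at most 25 iterations).
#' A singular or aliased design is an error; complete or quasi-complete
#' separation (diverging coefficients, fitted probabilities at the
#' boundary) is flagged on the returned object with a warning, never
#' silently ignored.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param outcome 0/1 vector (both classes present).
#' @return A `logistic_model`: `coefficients` (intercept first), `fitted`,
#'   `ll_model`, `ll_null`, `converged`, `iterations`, `separation`, `n`,
#'   `n_predictors`, `outcome`, `design`.
#' @export
logistic_fit <- function(design, outcome) {
  x <- as.matrix(design)
  if (!is.numeric(x)) stopf("design must be numeric")
  y <- as.numeric(outcome)
  if (length(y) != nrow(x)) stopf("design and outcome sizes differ")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stopf("outcome must be binary with both classes present")
  if (ncol(x) > 0 && is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  fml <- if (ncol(x) > 0) .y ~ . else .y ~ 1
  fit <- suppressWarnings(stats::glm(
    fml, data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 25)
  ))
  if (any(is.na(stats::coef(fit))))
    stopf("singular or degenerate design (aliased coefficients)",
          class = "aptw_degenerate_model")
  eta <- stats::predict(fit, type = "link")
  separation <- any(abs(eta) > 30) || any(fit$fitted.values < 1e-10) ||
    any(fit$fitted.values > 1 - 1e-10)
  if (separation)
    warnf("possible complete separation: fitted probabilities at the boundary")
  if (!fit$converged)
    warnf("logistic fit did not converge in 25 iterations")
  ll_model <- as.numeric(stats::logLik(fit))
  p0 <- mean(y)
  ll_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(
    list(coefficients = stats::coef(fit),
         fitted = unname(fit$fitted.values),
         ll_model = ll_model, ll_null = ll_null,
         converged = fit$converged, iterations = fit$iter,
         separation = separation,
         n = length(y), n_predictors = ncol(x),
         outcome = y, design = x),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> n = %d, %d predictor(s), logLik %.3f (null %.3f)%s\n",
              x$n, x$n_predictors, x$ll_model, x$ll_null,
              if (x$separation) " [separation flagged]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Nagelkerke pseudo-R2
#'
#' Cox-Snell R2 rescaled by its maximum attainable value, bounded in
#' \[0, 1\].
#'
#' @param model A [logistic_fit()] result.
#' @return The Nagelkerke R2.
#' @export
nagelkerke_r2 <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  n <- model$n
  cox_snell <- 1 - exp(2 / n * (model$ll_null - model$ll_model))
  r2_max <- 1 - exp(2 / n * model$ll_null)
  cox_snell / r2_max
}

#' Omnibus likelihood-ratio test of a logistic model
#'
#' Likelihood-ratio chi-square of the fitted model against the
#' intercept-only model.
#'
#' @param model A [logistic_fit()] result.
#' @return List with `chisq`, `df`, `p_value`.
#' @export
omnibus_test <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  chisq <- 2 * (model$ll_model - model$ll_null)
  df <- model$n_predictors
  list(chisq = chisq, df = df, p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into bins by quantiles of the fitted probability (tied
#' probabilities stay together); compares observed and expected event counts
#' per bin by the usual chi-square with `g - 2` degrees of freedom. When
#' there are fewer distinct fitted probabilities than requested groups, the
#' group count is reduced with a warning. The statistic is binning-sensitive,
#' so treat the p-value as descriptive.
#'
#' @param model A [logistic_fit()] result.
#' @param groups Number of bins; default 10 (deciles).
#' @return List with `chisq`, `df`, `p_value`, `groups`, `table`.
#' @export
hosmer_lemeshow <- function(model, groups = 10) {
  stopifnot(inherits(model, "logistic_model"))
  p <- model$fitted; y <- model$outcome
  n_distinct <- length(unique(p))
  if (n_distinct < groups) {
    warnf("only %d distinct fitted probabilities; reducing Hosmer-Lemeshow groups", n_distinct)
    groups <- max(3, n_distinct)
  }
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  bins <- cut(p, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(y, bins, sum)
  n_g <- tapply(y, bins, length)
  exp1 <- tapply(p, bins, sum)
  keep <- !is.na(n_g)
  obs1 <- obs1[keep]; n_g <- n_g[keep]; exp1 <- exp1[keep]
  obs0 <- n_g - obs1; exp0 <- n_g - exp1
  chisq <- sum((obs1 - exp1)^2 / pmax(exp1, 1e-10) +
               (obs0 - exp0)^2 / pmax(exp0, 1e-10))
  df <- length(n_g) - 2
  p <- if (df >= 1) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(chisq = chisq, df = df,
       p_value = p,
       groups = length(n_g),
       table = data.frame(n = as.vector(n_g), observed = as.vector(obs1),
                          expected = as.vector(exp1)))
}

#' Shapiro-Wilk normality screen
#'
#' Royston's Shapiro-Wilk W and p-value (3 <= n <= 5000); a constant sample
#' is an error.
#'
#' @param values Numeric vector.
#' @return List with `w` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(values))
  if (diff(range(values)) == 0)
    stopf("Shapiro-Wilk is undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  list(w = unname(sw$statistic), p_value = sw$p.value)
}

#' Molecular-subgroup descriptive means
#'
#' Per-stratum n, mean and SD of one APTw metric, stratified by MGMT promoter
#' methylation or IDH mutation status. Subjects with unknown status are
#' dropped (their count is reported); strata smaller than `min_n` are flagged
#' as insufficient for hypothesis testing. An empty stratum has `NA` mean,
#' never 0.
#'
#' @param cohort A [cohort_table()].
#' @param stratifier `"mgmt"` or `"idh"`.
#' @param metric One of `"mean"`, `"max"`, `"min"`, `"range"`; default
#'   `"mean"`.
#' @param min_n Minimum stratum size for testing; default 4.
#' @return Data frame with `stratum`, `n`, `mean`, `sd`,
#'   `sufficient_for_testing`; attribute `n_unknown`.
#' @export
#' @examples
#' final <- apply_exclusions(load_table1_fixture())
#' subgroup_means(final, "mgmt")
subgroup_means <- function(cohort, stratifier = c("mgmt", "idh"), metric = "mean",
                           min_n = 4) {
  stopifnot(inherits(cohort, "cohort_table"))
  stratifier <- match.arg(stratifier)
  col <- switch(stratifier, mgmt = "mgmt_status", idh = "idh_status")
  if (is.null(cohort[[col]])) stopf("cohort lacks column %s", col)
  levels_known <- switch(stratifier,
                         mgmt = c("methylated", "non-methylated"),
                         idh = c("wildtype", "mutant"))
  status <- cohort[[col]]
  n_unknown <- sum(!status %in% levels_known)
  vals <- cohort[[metric_column(metric)]]
  out <- do.call(rbind, lapply(levels_known, function(lv) {
    v <- vals[status == lv]
    data.frame(stratum = lv, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               sufficient_for_testing = length(v) >= min_n,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_unknown") <- n_unknown
  out
}
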