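#' Apply cohort exclusion rules
#'
#' Removes subjects flagged with radiological progression after histological
#' sampling, then removes whole groups smaller than the minimum size required
#' for statistical analysis (the metastasis group of the packaged cohort
#' falls to this rule at n = 2). The removed subjects and their reasons are
#' recorded in the `exclusions` attribute. Idempotent.
#'
#' @param cohort A [cohort_table()].
#' @param min_group_size Minimum group size kept for analysis; default 4.
#' @return The filtered [cohort_table()] with an `exclusions` attribute
#'   (data frame `id`, `reason`).
#' @export
#' @examples
#' final <- apply_exclusions(load_table1_fixture())
#' table(final$group)   # 16 HGG, 6 LGG
apply_exclusions <- function(cohort, min_group_size = 4) {
  stopifnot(inherits(cohort, "cohort_table"))
  prior <- attr(cohort, "exclusions")
  prog_ids <- cohort$id[cohort$progression_flag]
  excl <- data.frame(id = prog_ids,
                     reason = rep("radiological progression after histological sampling",
                                  length(prog_ids)),
                     stringsAsFactors = FALSE)
  keep <- !cohort$progression_flag
  kept <- cohort[keep, , drop = FALSE]
  sizes <- table(kept$group)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small)) {
    drop_small <- kept$group %in% small
    excl <- rbind(excl, data.frame(
      id = kept$id[drop_small],
      reason = sprintf("group %s below minimum size %d", kept$group[drop_small], min_group_size),
      stringsAsFactors = FALSE
    ))
    kept <- kept[!drop_small, , drop = FALSE]
  }
  out <- cohort_table(as.data.frame(kept), provenance = attr(cohort, "provenance"))
  attr(out, "exclusions") <- if (is.null(prior)) excl else rbind(prior, excl)
  out
}

#' Threshold classification rule
#'
#' A fixed-cutoff grade rule: predict high grade when the chosen APTw metric
#' is strictly greater than the cutoff; boundary equality predicts low grade.
#'
#' @param metric One of `"mean"`, `"max"`, `"range"`.
#' @param cutoff Cutoff in percent (> 0).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(metric = c("mean", "max", "range"), cutoff) {
  metric <- match.arg(metric)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stopf("cutoff must be a single positive percent value")
  structure(list(metric = metric, cutoff = cutoff), class = "threshold_rule")
}

#' @noRd
metric_column <- function(metric) {
  switch(metric,
         mean = "aptw_mean", max = "aptw_max", min = "aptw_min",
         range = "aptw_range",
         stopf("unknown metric '%s'", metric))
}

#' Classify one subject by a threshold rule
#'
#' @param record One row of a [cohort_table()] (or any list with the APTw
#'   fields and `group`).
#' @param rule A [threshold_rule()].
#' @return List with `predicted` (`"HGG"`/`"LGG"`), `actual`, `correct`.
#' @export
#' @seealso [classify_cohort()] for whole-cohort audits.
threshold_classify <- function(record, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  col <- metric_column(rule$metric)
  value <- record[[col]]
  if (is.null(value) || length(value) != 1L || is.na(value))
    stopf("record lacks metric '%s'", rule$metric)
  predicted <- if (value > rule$cutoff) "HGG" else "LGG"
  actual <- record[["group"]]
  list(predicted = predicted, actual = actual,
       correct = if (is.null(actual)) NA else predicted == actual)
}

#' Audit a cohort against a threshold rule
#'
#' Applies a [threshold_rule()] to every subject and summarizes the confusion
#' counts. Metastasis subjects are classified and listed in the audit (the
#' rule has no MET label, so they are never "correct"), but are excluded from
#' sensitivity and specificity, which are computed over gliomas only:
#' sensitivity = correctly called HGG / all HGG, specificity = correctly
#' called LGG / all LGG. A rate with an empty denominator is `NA`, not 0.
#'
#' @param cohort A non-empty [cohort_table()].
#' @param rule A [threshold_rule()].
#' @return A `cohort_classification`: list with `audit` (per-subject data
#'   frame), `n_correct`, `n_glioma`, `sensitivity`, `specificity`, `rule`.
#' @export
#' @examples
#' final <- apply_exclusions(load_table1_fixture())
#' classify_cohort(final, threshold_rule("max", 2.48))$n_correct   # 21
classify_cohort <- function(cohort, rule) {
  stopifnot(inherits(cohort, "cohort_table"), nrow(cohort) > 0)
  col <- metric_column(rule$metric)
  value <- cohort[[col]]
  predicted <- ifelse(value > rule$cutoff, "HGG", "LGG")
  audit <- data.frame(
    id = cohort$id, group = cohort$group, metric = rule$metric,
    value = value, cutoff = rule$cutoff, predicted = predicted,
    correct = predicted == cohort$group, stringsAsFactors = FALSE
  )
  glioma <- cohort$group %in% c("HGG", "LGG")
  n_hgg <- sum(cohort$group == "HGG")
  n_lgg <- sum(cohort$group == "LGG")
  sens <- if (n_hgg) sum(audit$correct & cohort$group == "HGG") / n_hgg else NA_real_
  spec <- if (n_lgg) sum(audit$correct & cohort$group == "LGG") / n_lgg else NA_real_
  structure(
    list(audit = audit,
         n_correct = sum(audit$correct[glioma]),
         n_glioma = sum(glioma),
         sensitivity = sens, specificity = spec, rule = rule),
    class = "cohort_classification"
  )
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("<cohort_classification> %s > %.2f%%: %d/%d gliomas correct (sens %.1f%%, spec %.1f%%)\n",
              x$rule$metric, x$rule$cutoff, x$n_correct, x$n_glioma,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Fit the combined logistic grade model
#'
#' Logistic regression of grade (HGG = 1, LGG = 0) on the APTw summary
#' statistics — by default mean, max and range (range derived as max - min).
#' Metastasis subjects are dropped before fitting. The fit is maximum
#' likelihood via [logistic_fit()].
#'
#' @param cohort A [cohort_table()] containing both LGG and HGG subjects.
#' @param predictors Subset of `c("mean", "max", "min", "range")`.
#' @return A `combined_model`: the [logistic_fit()] result plus the subject
#'   ids, fitted probabilities and predictor names.
#' @export
fit_combined_model <- function(cohort, predictors = c("mean", "max", "range")) {
  stopifnot(inherits(cohort, "cohort_table"))
  gl <- cohort[cohort$group %in% c("HGG", "LGG"), , drop = FALSE]
  if (sum(gl$group == "HGG") < 2 || sum(gl$group == "LGG") < 2)
    stopf("need at least 2 subjects per grade to fit the combined model")
  cols <- vapply(predictors, metric_column, character(1))
  design <- as.matrix(as.data.frame(gl)[, cols, drop = FALSE])
  colnames(design) <- predictors
  fit <- logistic_fit(design, as.integer(gl$group == "HGG"))
  structure(
    c(fit, list(ids = gl$id, groups = gl$group, predictors = predictors)),
    class = c("combined_model", class(fit))
  )
}

#' Predict grade from the combined model
#'
#' Predicts HGG when the fitted probability exceeds `prob_cutoff`.
#'
#' @param model A `combined_model` from [fit_combined_model()].
#' @param record One subject row (needs the model's predictor columns), or
#'   omit to predict for the fitting cohort.
#' @param prob_cutoff Probability cutoff; default 0.38.
#' @return For a single record, the predicted group; with `record = NULL`, a
#'   per-subject audit data frame (`id`, `group`, `probability`, `predicted`,
#'   `correct`).
#' @export
predict_combined <- function(model, record = NULL, prob_cutoff = 0.38) {
  stopifnot(inherits(model, "combined_model"))
  if (!is.null(record)) {
    cols <- vapply(model$predictors, metric_column, character(1))
    x <- c(1, vapply(cols, function(cc) as.numeric(record[[cc]]), numeric(1)))
    p <- stats::plogis(sum(model$coefficients * x))
    return(if (p > prob_cutoff) "HGG" else "LGG")
  }
  p <- model$fitted
  predicted <- ifelse(p > prob_cutoff, "HGG", "LGG")
  data.frame(id = model$ids, group = model$groups, probability = p,
             predicted = predicted, correct = predicted == model$groups,
             stringsAsFactors = FALSE)
}
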