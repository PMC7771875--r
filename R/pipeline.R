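#' Pipeline run configuration
#'
#' Bundles everything a reproducible run needs: the seed, acquisition and
#' asymmetry settings, the cohort source, the threshold rules to audit and
#' the probability cutoff of the combined model. Serializes losslessly to
#' JSON; unknown keys are rejected on load.
#'
#' @param seed Integer seed for all randomness in the run.
#' @param cohort `"fixture"` to analyze the packaged clinical table, or a
#'   path to a cohort CSV, or a [cohort_sim_params()] to simulate.
#' @param rules List of [threshold_rule()]s to audit; default mean > 2.0 and
#'   max > 2.48.
#' @param prob_cutoff Probability cutoff of the combined model audit;
#'   default 0.38.
#' @param protocol,asym Acquisition / asymmetry settings (defaults:
#'   [saturation_protocol()], [asym_params()]).
#' @param phantom Optional [phantom_spec()]; when present the image stages
#'   run too.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, cohort = "fixture",
                       rules = list(threshold_rule("mean", 2.0), threshold_rule("max", 2.48)),
                       prob_cutoff = 0.38,
                       protocol = saturation_protocol(), asym = asym_params(),
                       phantom = NULL, out_dir = "aptw-run") {
  structure(
    list(seed = as.integer(seed), cohort = cohort, rules = rules,
         prob_cutoff = prob_cutoff, protocol = protocol, asym = asym,
         phantom = phantom, out_dir = out_dir),
    class = "run_config"
  )
}

#' @noRd
resolve_cohort <- function(cfg) {
  if (inherits(cfg$cohort, "cohort_sim_params")) {
    params <- cfg$cohort
    params$seed <- cfg$seed
    simulate_cohort_table(params)
  } else if (identical(cfg$cohort, "fixture")) {
    load_table1_fixture()
  } else if (is.character(cfg$cohort)) {
    read_cohort_csv(cfg$cohort)
  } else stopf("config cohort must be 'fixture', a CSV path or cohort_sim_params")
}

#' Group descriptive statistics of a cohort
#'
#' Per-group average, minimum, maximum and spread of each APTw summary
#' metric — the machine-readable analogue of a clinical descriptives table.
#'
#' @param cohort A [cohort_table()].
#' @return Data frame: `metric`, `group`, `n`, `average`, `minimum`,
#'   `maximum`, `spread` (max - min of the per-subject values).
#' @export
group_descriptives <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  metrics <- c(mean = "aptw_mean", max = "aptw_max", min = "aptw_min", range = "aptw_range")
  out <- list()
  for (m in names(metrics)) for (g in unique(cohort$group)) {
    v <- cohort[[metrics[[m]]]][cohort$group == g]
    out[[length(out) + 1L]] <- data.frame(
      metric = m, group = g, n = length(v),
      average = mean(v), sd = stats::sd(v),
      minimum = min(v), maximum = max(v), spread = max(v) - min(v),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Run the full cohort analysis pipeline
#'
#' One deterministic pass over a cohort: exclusions, group descriptives,
#' Mann-Whitney comparisons of mean/max/min/range, ROC analyses with
#' Youden-midpoint cutoffs, the combined logistic model with its diagnostics
#' and classification audit, the threshold-rule audits, normality screens
#' and the molecular-subgroup descriptives. When the config carries a
#' [phantom_spec()], the image stages (phantom synthesis, APTw map, maximal
#' ROI) run as well. All artifacts are written under the config's `out_dir`
#' and listed in a manifest with content hashes.
#'
#' @param config A [run_config()].
#' @param write Write artifacts to disk (default `TRUE`); set `FALSE` to get
#'   the in-memory results only.
#' @return Invisibly, a list with `cohort`, `final`, `descriptives`,
#'   `mann_whitney`, `roc`, `combined`, `audits`, `normality`, `subgroups`,
#'   optionally `phantom`, and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- resolve_cohort(config)
  final <- apply_exclusions(cohort)
  message(sprintf("[cohort] %d subjects, %d after exclusions (%s)",
                  nrow(cohort), nrow(final),
                  paste(sprintf("%s=%d", names(table(final$group)), table(final$group)),
                        collapse = ", ")))

  metrics <- c("mean", "max", "min", "range")
  gl <- final[final$group %in% c("HGG", "LGG"), , drop = FALSE]
  mw <- lapply(metrics, function(m) {
    col <- metric_column(m)
    mann_whitney(gl[[col]][gl$group == "HGG"], gl[[col]][gl$group == "LGG"])
  })
  names(mw) <- metrics

  roc <- lapply(c("mean", "max", "range"), function(m) {
    roc_curve(gl[[metric_column(m)]], gl$group)
  })
  names(roc) <- c("mean", "max", "range")

  model <- fit_combined_model(final)
  combined <- list(
    model = model,
    roc = roc_curve(model$fitted, model$groups),
    nagelkerke = nagelkerke_r2(model),
    omnibus = omnibus_test(model),
    hosmer_lemeshow = suppressWarnings(hosmer_lemeshow(model)),
    audit = predict_combined(model, prob_cutoff = config$prob_cutoff),
    prob_cutoff = config$prob_cutoff
  )

  audits <- lapply(config$rules, function(rule) classify_cohort(final, rule))
  names(audits) <- vapply(config$rules, function(r) sprintf("%s_gt_%.2f", r$metric, r$cutoff), "")

  normality <- lapply(metrics, function(m) shapiro_wilk(gl[[metric_column(m)]]))
  names(normality) <- metrics

  subgroups <- list(mgmt = subgroup_means(final, "mgmt"),
                    idh = subgroup_means(final, "idh"))

  phantom_res <- NULL
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$seed <- config$seed
    message("[phantom] building lesion phantom and APTw map")
    ph <- build_lesion_phantom(spec, config$protocol)
    map <- compute_aptw_map(ph$offset_stack, ph$s0_volume, config$protocol,
                            config$asym, voxel_size_mm = spec$voxel_size_mm)
    message(sprintf("[phantom] QC: %d voxels, %d bad reference, %d uncorrectable",
                    map$qc$n_voxels, map$qc$n_bad_reference, map$qc$n_uncorrectable))
    placement <- find_max_roi(map, ph$lesion_mask, ph$exclusion_mask)
    phantom_res <- list(phantom = ph, map = map, placement = placement,
                        roi = roi_stats(map, placement))
  }

  results <- list(cohort = cohort, final = final,
                  descriptives = group_descriptives(final),
                  mann_whitney = mw, roc = roc, combined = combined,
                  audits = audits, normality = normality, subgroups = subgroups,
                  phantom = phantom_res, config = config)

  if (write) {
    results$manifest <- write_run_artifacts(results, config)
  }
  invisible(results)
}

#' @noRd
write_run_artifacts <- function(results, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    if (is.data.frame(obj)) utils::write.csv(obj, p, row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
    p
  }
  wr(results$descriptives, "group_descriptives.csv")
  wr(data.frame(
    metric = names(results$mann_whitney),
    u = vapply(results$mann_whitney, `[[`, numeric(1), "u_statistic"),
    p_asymptotic = vapply(results$mann_whitney, `[[`, numeric(1), "p_asymptotic"),
    p_exact = vapply(results$mann_whitney, `[[`, numeric(1), "p_exact")
  ), "mann_whitney.csv")
  roc_rows <- do.call(rbind, lapply(names(results$roc), function(m) {
    r <- results$roc[[m]]
    data.frame(metric = m, auc = r$auc, p_value = r$p_value,
               ci_lower = r$ci95[["lower"]], ci_upper = r$ci95[["upper"]],
               cutoff = r$optimal_cutoff,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  cr <- results$combined$roc
  roc_rows <- rbind(roc_rows, data.frame(
    metric = "combined", auc = cr$auc, p_value = cr$p_value,
    ci_lower = cr$ci95[["lower"]], ci_upper = cr$ci95[["upper"]],
    cutoff = results$combined$prob_cutoff,
    sensitivity = cr$sensitivity, specificity = cr$specificity))
  wr(roc_rows, "roc_analysis.csv")
  wr(results$combined$audit, "combined_model_audit.csv")
  for (nm in names(results$audits)) wr(results$audits[[nm]]$audit, sprintf("audit_%s.csv", nm))
  wr(list(
    nagelkerke_r2 = results$combined$nagelkerke,
    omnibus = results$combined$omnibus,
    hosmer_lemeshow = results$combined$hosmer_lemeshow[c("chisq", "df", "p_value", "groups")],
    coefficients = as.list(results$combined$model$coefficients),
    normality = lapply(results$normality, function(x) x[c("w", "p_value")]),
    subgroups = list(mgmt = results$subgroups$mgmt, idh = results$subgroups$idh),
    seed = config$seed
  ), "summary.json")
  if (!is.null(results$phantom)) {
    p <- file.path(config$out_dir, "aptw_map.nii.gz")
    write_aptw_nifti(results$phantom$map, p)
    paths <- c(paths, p)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Render publication-style result tables
#'
#' Plain-text replicas of the three cohort tables — group descriptives,
#' Mann-Whitney comparison and ROC analysis — with clinical display rounding
#' (descriptives 2 dp, AUC 3 dp, sensitivity/specificity 1 dp; rounding half
#' away from zero). For human comparison only; machine consumers should read
#' the CSV/JSON artifacts, which keep full precision.
#'
#' @param results The list returned by [run_pipeline()].
#' @return Character vector of lines, invisibly; printed to the console.
#' @export
render_tables <- function(results) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))

  add("== Group descriptives: APTw signal (%%) by metric and group ==")
  d <- results$descriptives
  for (m in unique(d$metric)) {
    add("APTw-%s", m)
    dm <- d[d$metric == m, ]
    for (i in seq_len(nrow(dm))) {
      add("  %-4s Average %s  Minimum %s  Maximum %s  Range %s",
          dm$group[i], fmt_num(dm$average[i]), fmt_num(dm$minimum[i]),
          fmt_num(dm$maximum[i]), fmt_num(dm$spread[i]))
    }
  }
  missing_groups <- setdiff(c("HGG", "LGG", "MET"), unique(d$group))
  for (g in missing_groups) add("  %-4s (no subjects)", g)

  add("== Mann-Whitney U: HGG vs LGG ==")
  for (m in names(results$mann_whitney)) {
    mw <- results$mann_whitney[[m]]
    add("  %-6s U = %s  p = %s", m, fmt_num(mw$u_statistic, 1), fmt_num(mw$p_asymptotic, 3))
  }

  add("== ROC: HGG vs LGG ==")
  for (m in names(results$roc)) {
    r <- results$roc[[m]]
    add("  %-6s AUC %s  (95%% CI %s-%s)  cutoff %s%%  sens %s%%  spec %s%%",
        m, fmt_num(r$auc, 3), fmt_num(r$ci95[["lower"]], 3), fmt_num(r$ci95[["upper"]], 3),
        fmt_num(r$optimal_cutoff, 2),
        fmt_num(100 * r$sensitivity, 1), fmt_num(100 * r$specificity, 1))
  }
  cr <- results$combined$roc
  add("  %-6s AUC %s  (95%% CI %s-%s)  prob cutoff %s  sens %s%%  spec %s%%",
      "comb", fmt_num(cr$auc, 3), fmt_num(cr$ci95[["lower"]], 3), fmt_num(cr$ci95[["upper"]], 3),
      fmt_num(results$combined$prob_cutoff, 2),
      fmt_num(100 * cr$sensitivity, 1), fmt_num(100 * cr$specificity, 1))
  add("  combined model: Nagelkerke R2 %s, omnibus p %s, Hosmer-Lemeshow p %s",
      fmt_num(results$combined$nagelkerke, 3),
      fmt_num(results$combined$omnibus$p_value, 3),
      fmt_num(results$combined$hosmer_lemeshow$p_value, 3))

  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
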