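#' Cohort table of per-subject APTw statistics
#'
#' A validated data frame of subject records: identifiers, demographics,
#' histology, glioma grade group (`LGG`, `HGG`, `MET`), molecular status and
#' the APTw summary statistics (mean, max, min in percent of \eqn{S_0}).
#' The within-subject range (max - min) is derived, not stored.
#'
#' @param df Data frame with at least `id`, `group`, `aptw_mean`, `aptw_max`,
#'   `aptw_min`.
#' @param provenance `"fixture"` or `"simulated"`.
#' @return The data frame with class `cohort_table` and a `provenance`
#'   attribute; an `aptw_range` column is added.
#' @export
cohort_table <- function(df, provenance = c("fixture", "simulated")) {
  provenance <- match.arg(provenance)
  needed <- c("id", "group", "aptw_mean", "aptw_max", "aptw_min")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stopf("cohort table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$id))
    stopf("subject ids must be unique")
  if (nrow(df) && !all(df$group %in% c("LGG", "HGG", "MET")))
    stopf("group must be one of LGG, HGG, MET")
  bad <- df$aptw_min > df$aptw_mean | df$aptw_mean > df$aptw_max
  if (any(bad))
    stopf("subject(s) %s violate min <= mean <= max",
          paste(df$id[bad], collapse = ", "))
  df$aptw_range <- df$aptw_max - df$aptw_min
  if (is.null(df$progression_flag)) df$progression_flag <- rep(FALSE, nrow(df))
  structure(df, class = c("cohort_table", "data.frame"), provenance = provenance)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%s): %s\n",
              nrow(x), attr(x, "provenance"),
              paste(sprintf("%s=%d", names(table(x$group)), table(x$group)), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Load the packaged 26-subject clinical cohort
#'
#' The packaged fixture: 26 presurgical brain-tumor patients with histology,
#' IDH/MGMT status, the initial (conventional-MRI) radiological
#' classification and the ROI APTw statistics (mean, max, min in percent),
#' together with the exclusion annotations used downstream (two low-grade
#' subjects with radiological progression after histological sampling are
#' flagged; the two metastases fall to the minimum-group-size rule in
#' [apply_exclusions()]).
#'
#' @return A [cohort_table()] with 26 rows, provenance `"fixture"`.
#' @export
#' @examples
#' coh <- load_table1_fixture()
#' subset(coh, id == 8, c(aptw_mean, aptw_max, aptw_min))
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "aptwquant", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df, provenance = "fixture")
}

#' Parameters for cohort simulation
#'
#' Group sizes and the group-level distribution of the APTw summary triple
#' (mean, max, min in percent). Defaults follow the clinical cohort's group
#' averages and standard deviations. The triple is drawn from a correlated
#' trivariate normal (equicorrelation `correlation`) and re-drawn until the
#' subject satisfies min <= mean <= max.
#'
#' @param n Named integer vector of group sizes; default
#'   `c(HGG = 16, LGG = 6, MET = 2)`.
#' @param group_means Named list, per group `c(mean, max, min)` centers in
#'   percent.
#' @param group_sds Named list, per group `c(mean, max, min)` SDs in percent.
#' @param correlation Correlation between the three statistics; default 0.8.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n = c(HGG = 16, LGG = 6, MET = 2),
                              group_means = list(
                                HGG = c(2.60, 3.23, 1.81),
                                LGG = c(1.49, 1.95, 1.01),
                                MET = c(2.49, 2.98, 1.76)
                              ),
                              group_sds = list(
                                HGG = c(0.97, 1.00, 0.91),
                                LGG = c(0.50, 0.39, 0.69),
                                MET = c(0.33, 0.30, 0.64)
                              ),
                              correlation = 0.8,
                              seed = 1) {
  if (any(n < 0)) stopf("group sizes must be >= 0")
  if (correlation < 0 || correlation >= 1) stopf("correlation must be in [0, 1)")
  bad <- setdiff(names(n), c("HGG", "LGG", "MET"))
  if (length(bad)) stopf("unknown groups: %s", paste(bad, collapse = ", "))
  structure(
    list(n = n, group_means = group_means, group_sds = group_sds,
         correlation = correlation, seed = as.integer(seed)),
    class = "cohort_sim_params"
  )
}

#' Simulate a subject cohort
#'
#' Draws per-subject APTw statistics from the group models in
#' [cohort_sim_params()]. Deterministic under the params' seed; the caller's
#' RNG state is preserved.
#'
#' @param params A [cohort_sim_params()].
#' @param max_tries Rejection-sampling cap per subject; exceeded means the
#'   constraint min <= mean <= max is infeasible for the given parameters.
#' @return A [cohort_table()] with provenance `"simulated"`.
#' @export
simulate_cohort_table <- function(params = cohort_sim_params(), max_tries = 1000) {
  stopifnot(inherits(params, "cohort_sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  r <- params$correlation
  sigma <- matrix(r, 3, 3); diag(sigma) <- 1
  ch <- chol(sigma)

  rows <- list()
  sid <- 0L
  for (g in names(params$n)) {
    ng <- params$n[[g]]
    if (ng == 0) next
    mu <- params$group_means[[g]]
    sd <- params$group_sds[[g]]
    for (k in seq_len(ng)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        x <- mu + sd * drop(crossprod(ch, stats::rnorm(3)))
        if (x[3] <= x[1] && x[1] <= x[2]) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("could not satisfy min <= mean <= max for group %s: infeasible parameters", g)
      sid <- sid + 1L
      rows[[sid]] <- data.frame(
        id = sid, group = g,
        aptw_mean = x[1], aptw_max = x[2], aptw_min = x[3],
        idh_status = "unknown", mgmt_status = "unknown",
        progression_flag = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), group = character(),
               aptw_mean = numeric(), aptw_max = numeric(), aptw_min = numeric(),
               idh_status = character(), mgmt_status = character(),
               progression_flag = logical(), stringsAsFactors = FALSE)
  cohort_table(df, provenance = "simulated")
}

#' Write / read cohort tables as CSV
#'
#' Canonical tabular interchange: UTF-8, header row, `.` decimal separator.
#' The derived `aptw_range` column is not written.
#'
#' @param cohort A [cohort_table()].
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df$aptw_range <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param provenance Provenance tag for the read table.
#' @export
read_cohort_csv <- function(path, provenance = "simulated") {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE), provenance = provenance)
}
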