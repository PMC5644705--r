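#' Run the full turn-taking analysis for one attempt
#'
#' Executes the complete per-attempt pipeline: optional data filters, carer
#' classification and validation, alternation proportion and k-category runs
#' test, the three nested Markov fits with likelihood-ratio comparisons,
#' per-carer and group turn-taking ratios, a Wilcoxon comparison of
#' following vs repeat rates, IVI summaries, the ordering diagnostic, the
#' IVI randomization test, and the Wald-Wolfowitz bout test on the first
#' full day's group IVIs. Stages that cannot run (e.g. a single significant
#' carer) are skipped with a recorded warning rather than an error. Fully
#' deterministic given `seed`: each randomized stage receives its own
#' sub-seed forked from the master seed, so changing the replication count
#' of one stage does not perturb another.
#'
#' @param attempt a [provisioning_attempt()].
#' @param threshold_frac carer-classification threshold (see
#'   [classify_significant()]).
#' @param min_visits,max_carers validity rules (see
#'   [validate_for_fitting()]).
#' @param n_reps randomization replicates.
#' @param seed master RNG seed.
#' @param time_unit unit for reported rates.
#' @param filter if `TRUE`, [apply_filters()] is run first (requires brood
#'   ages in the metadata).
#' @param n_perm permutations for the ordering diagnostic and reciprocity.
#' @return list of class `attempt_report`.
#' @export
run_attempt <- function(attempt, threshold_frac = 0.2, min_visits = 10,
                        max_carers = 6, n_reps = 1000, seed = NULL,
                        time_unit = "hour", filter = FALSE, n_perm = 999) {
  stopifnot(inherits(attempt, "provisioning_attempt"))
  warnings <- character()
  seeds <- fork_seeds(seed, 3L)   # ordering, randomization, reciprocity
  if (filter) attempt <- apply_filters(attempt)

  cs <- rank_helpers(classify_significant(attempt,
                                          threshold_frac = threshold_frac))
  report <- list(attempt_id = attempt$attempt_id, carer_set = cs,
                 filter_report = attempt$filter_report, seed = seed)

  if (cs$c < 2) {
    report$skipped <- "single significant carer: turn-taking analysis skipped"
    report$validity <- validate_for_fitting(cs, min_visits = min_visits,
                                            max_carers = max_carers)
    report$warnings <- c(warnings, report$skipped)
    class(report) <- "attempt_report"
    return(report)
  }

  stats <- sufficient_stats(attempt, cs)
  validity <- validate_for_fitting(cs, stats, min_visits = min_visits,
                                   max_carers = max_carers)
  report$validity <- validity
  warnings <- c(warnings, validity$warnings)
  if (!validity$valid) {
    report$skipped <-
      "validity failure (carer with too few visits): analysis skipped"
    report$warnings <- c(warnings, report$skipped)
    class(report) <- "attempt_report"
    return(report)
  }

  report$alternation <- proportion_alternated(attempt, cs)
  report$runs_test <- k_category_runs_test(attempt, carers = cs)

  full <- fit_ctmc(stats, "full", time_unit)
  per_ind <- fit_ctmc(stats, "per_individual", time_unit)
  pooled <- fit_ctmc(stats, "pooled", time_unit)
  report$fits <- list(full = full, per_individual = per_ind, pooled = pooled)
  report$model_table <- anova.ctmc_fit(pooled, per_ind, full)
  report$ratio <- turn_taking_ratio(per_ind)
  warnings <- c(warnings, report$ratio$flags)
  report$wilcoxon <- wilcoxon_lambda_mu(per_ind)
  report$reciprocity <- reciprocity_correlation(full, n_perm = n_perm,
                                                seed = seeds[[3L]])

  report$ivi <- ivi_summaries(attempt, cs)

  ## ordering diagnostic runs BEFORE the randomization, per the bias caveat
  report$ordering <- ordering_score(attempt, cs, n_perm = n_perm,
                                    seed = seeds[[1L]])
  if (is.finite(report$ordering$mean_p) &&
      (report$ordering$mean_p < 0.05 || report$ordering$mean_p > 0.95))
    warnings <- c(warnings,
                  "IVI ordering diagnostic extreme: randomization may be biased")

  report$randomization <- randomization_test(attempt, cs, n_reps = n_reps,
                                             seed = seeds[[2L]])
  for (r in report$randomization) warnings <- c(warnings, r$flags)

  first_day <- min(attempt$days$day_index)
  g <- group_ivis(attempt, cs, day = first_day)
  report$bout_test <- if (length(g) >= 4) ww_bout_test(g) else {
    warnings <- c(warnings, "too few group IVIs on first day for bout test")
    NULL
  }

  report$warnings <- warnings
  class(report) <- "attempt_report"
  report
}

#' @export
print.attempt_report <- function(x, ...) {
  cat("== Turn-taking report:", x$attempt_id, "==\n")
  cat(sprintf("significant carers: %d (excluded: %d)\n", x$carer_set$c,
              nrow(x$carer_set$excluded)))
  if (!is.null(x$skipped)) {
    cat("SKIPPED:", x$skipped, "\n")
    return(invisible(x))
  }
  cat(sprintf("alternation proportion: %.3f (%d of %d pairs)\n",
              x$alternation$proportion, x$alternation$n_alt,
              x$alternation$n_pairs))
  cat(sprintf("k-category runs test: R = %d, E[R] = %.1f, p = %.3g\n",
              x$runs_test$R_obs, x$runs_test$E_R, x$runs_test$p))
  cat("model comparison:\n")
  print(x$model_table, row.names = FALSE, digits = 4)
  cat(sprintf("group lambda/mu ratio: %.3f (Wilcoxon lambda vs mu p = %.3g)\n",
              x$ratio$group_ratio, x$wilcoxon$p.value))
  for (r in x$randomization)
    cat(sprintf("randomization [%s]: observed %.3f, p_active = %.3g, passive_flag = %s\n",
                r$statistic, r$observed, r$p_active, r$passive_flag))
  if (!is.null(x$bout_test))
    cat(sprintf("bout test (first day): R = %d, E[R] = %.1f, p = %.3g\n",
                x$bout_test$R_obs, x$bout_test$E_R, x$bout_test$p))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Run a batch of attempts and aggregate
#'
#' Applies [run_attempt()] to each attempt, continuing past hard failures
#' (which are recorded), and summarizes across attempts: group turn-taking
#' ratios by carer count, how many attempts flag passive turn-taking, and
#' how many show active turn-taking (`p_active <= alpha` on the ratio
#' statistic).
#'
#' @param attempts list of [provisioning_attempt()] objects.
#' @param ... forwarded to [run_attempt()] (a supplied `seed` is forked into
#'   one sub-seed per attempt).
#' @param alpha significance level for counting active turn-taking.
#' @param seed master seed forked across attempts.
#' @return list of class `batch_report` with `reports`, `failures` and
#'   `summary`.
#' @export
run_batch <- function(attempts, ..., alpha = 0.05, seed = NULL) {
  stopifnot(is.list(attempts))
  if (!length(attempts)) {
    warning("empty attempt manifest")
    return(structure(list(reports = list(), failures = list(),
                          summary = NULL), class = "batch_report"))
  }
  seeds <- fork_seeds(seed, length(attempts))
  reports <- list(); failures <- list()
  ids <- make.unique(vapply(seq_along(attempts), function(k)
    as.character(attempts[[k]]$attempt_id %||% k), ""))
  for (k in seq_along(attempts)) {
    res <- tryCatch(run_attempt(attempts[[k]], seed = seeds[[k]], ...),
                    error = function(e) e)
    id <- ids[k]
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else reports[[id]] <- res
  }
  done <- Filter(function(r) is.null(r$skipped), reports)
  summary <- if (length(done)) data.frame(
    attempt_id = vapply(done, `[[`, "", "attempt_id"),
    c = vapply(done, function(r) r$carer_set$c, 0L),
    alternation = vapply(done, function(r) r$alternation$proportion, 0),
    group_ratio = vapply(done, function(r) r$ratio$group_ratio, 0),
    p_active = vapply(done, function(r)
      r$randomization$group_lambda_mu_ratio$p_active %||% NA_real_, 0),
    passive_flag = vapply(done, function(r)
      isTRUE(r$randomization$group_lambda_mu_ratio$passive_flag), TRUE),
    row.names = NULL) else NULL
  structure(list(
    reports = reports, failures = failures, summary = summary,
    n_passive = if (!is.null(summary)) sum(summary$passive_flag) else 0L,
    n_active = if (!is.null(summary))
      sum(summary$p_active <= alpha, na.rm = TRUE) else 0L),
    class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("Batch of %d report(s), %d failure(s)\n",
              length(x$reports), length(x$failures)))
  if (!is.null(x$summary)) {
    print(x$summary, row.names = FALSE, digits = 3)
    cat(sprintf("passive turn-taking flagged in %d attempt(s); active (p_active <= 0.05) in %d\n",
                x$n_passive, x$n_active))
  }
  for (id in names(x$failures)) cat("failure:", id, "-", x$failures[[id]], "\n")
  invisible(x)
}

#' Serialize an attempt report to JSON
#'
#' Writes the machine-readable per-attempt report (schema shipped under
#' `inst/schema/attempt_report.schema.json`).
#'
#' @param report an `attempt_report`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "attempt_report"))
  x <- list(
    attempt_id = report$attempt_id,
    n_significant_carers = report$carer_set$c,
    carers = report$carer_set$carers,
    excluded = report$carer_set$excluded,
    skipped = report$skipped,
    warnings = as.list(report$warnings %||% character()))
  if (is.null(report$skipped)) {
    x$alternation <- report$alternation[c("proportion", "n_alt", "n_rep")]
    x$runs_test <- report$runs_test[c("R_obs", "E_R", "Var_R", "z", "p")]
    x$models <- report$model_table
    x$lambda <- as.list(report$fits$per_individual$lambda)
    x$mu <- as.list(report$fits$per_individual$mu)
    x$group_ratio <- report$ratio$group_ratio
    x$wilcoxon_p <- report$wilcoxon$p.value
    x$randomization <- lapply(report$randomization, function(r) {
      list(statistic = r$statistic, observed = r$observed,
           p_active = r$p_active, passive_flag = r$passive_flag,
           null_summary = as.list(stats::quantile(
             r$null_values, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)))
    })
    x$ivi <- list(per_carer = report$ivi$per_carer,
                  group_median_s = report$ivi$group_median_s,
                  frac_under_1h = report$ivi$frac_under_1h)
    x$ordering <- list(mean_p = report$ordering$mean_p,
                       sd_p = report$ordering$sd_p)
    if (!is.null(report$bout_test))
      x$bout_test <- report$bout_test[c("R_obs", "E_R", "p")]
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
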