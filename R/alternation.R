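## --- sequence utilities -----------------------------------------------------

## visitor sequences per observation day, in temporal order
day_sequences <- function(x, carers = NULL) {
  if (is.list(x) && !is.data.frame(x) && !inherits(x, "provisioning_attempt"))
    return(lapply(x, as.character))
  if (is.atomic(x)) return(list(as.character(x)))
  visits <- if (inherits(x, "provisioning_attempt")) x$visits else x
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  if (!is.null(carers))
    visits <- visits[visits$carer_id %in% carers, , drop = FALSE]
  visits <- visits[order(visits$day_index, visits$time), , drop = FALSE]
  split(visits$carer_id, visits$day_index)
}

n_runs <- function(x) {
  if (length(x) == 0L) return(0L)
  sum(x[-1L] != x[-length(x)]) + 1L
}

#' Proportion of alternated visits
#'
#' Over all consecutive within-day visit pairs, the fraction in which the
#' next visitor differs from the previous one (an "alternated" visit, i.e.
#' following another bird, as opposed to a repeat visit). Pairs never span a
#' day boundary.
#'
#' @param x a [provisioning_attempt()], a visit data frame, a single
#'   visitor-id vector, or a list of per-day visitor-id vectors.
#' @param carers optional significant-carer filter.
#' @return list with `proportion`, `n_alt`, `n_rep`, `n_pairs`; `proportion`
#'   is `NA` (flagged) when no day has two visits.
#' @export
proportion_alternated <- function(x, carers = NULL) {
  seqs <- day_sequences(x, carers)
  n_alt <- 0L; n_pairs <- 0L
  for (s in seqs) {
    if (length(s) < 2L) next
    d <- s[-1L] != s[-length(s)]
    n_alt <- n_alt + sum(d)
    n_pairs <- n_pairs + length(d)
  }
  list(proportion = if (n_pairs > 0) n_alt / n_pairs else NA_real_,
       n_alt = n_alt, n_rep = n_pairs - n_alt, n_pairs = n_pairs,
       flag = if (n_pairs == 0) "fewer than 2 visits in every day" else NULL)
}

## k-category runs test moments for one sequence's category counts
k_runs_moments <- function(counts) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  s2 <- sum(counts^2); s3 <- sum(counts^3)
  E <- (N * (N + 1) - s2) / N
  V <- if (N >= 2)
    (s2 * (s2 + N * (N + 1)) - 2 * N * s3 - N^3) / (N^2 * (N - 1))
  else 0
  c(E = E, V = max(V, 0))
}

#' k-category runs test for alternation
#'
#' Tests whether the number of maximal same-visitor runs in the visit
#' sequence differs from the count expected if each carer's visits were
#' placed at random — accounting for both the number of carers and the
#' inequality of their visit counts. For category counts `n_1..n_k`
#' (`N = sum n_i`), `E[R] = (N(N+1) - sum n_i^2) / N` and
#' `Var[R] = [sum n_i^2 (sum n_i^2 + N(N+1)) - 2N sum n_i^3 - N^3] /
#' (N^2 (N-1))`. More runs than expected indicate alternation.
#'
#' Multi-day sequences are handled additively: each day contributes its own
#' runs count and moments (permutations never cross day boundaries), and the
#' z statistic is formed from the summed runs, means and variances.
#'
#' @param x sequence(s) of visitor ids (vector, list of per-day vectors,
#'   visit data frame or [provisioning_attempt()]).
#' @param alternative `"more_runs"` (alternation, default), `"fewer_runs"`
#'   (clustering) or `"two_sided"`.
#' @param method `"normal_approx"` or `"monte_carlo"` (within-day
#'   permutations; the reference method).
#' @param n_mc Monte-Carlo permutations (at least 100).
#' @param seed optional RNG seed for the Monte-Carlo method.
#' @param carers optional significant-carer filter.
#' @return list of class `runs_test` with `R_obs`, `E_R`, `Var_R`, `z`, `p`,
#'   `alternative`, `method`, and `degenerate` flag.
#' @export
k_category_runs_test <- function(x,
                                 alternative = c("more_runs", "fewer_runs",
                                                 "two_sided"),
                                 method = c("normal_approx", "monte_carlo"),
                                 n_mc = 1000, seed = NULL, carers = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  seqs <- Filter(function(s) length(s) >= 2L, day_sequences(x, carers))
  if (!length(seqs)) stop("need at least one day with 2 or more visits")
  N <- sum(lengths(seqs))
  cats <- unique(unlist(seqs))
  R_obs <- sum(vapply(seqs, n_runs, 0L))
  if (length(cats) < 2L) {
    out <- list(R_obs = R_obs, E_R = R_obs, Var_R = 0, z = NA_real_, p = 1,
                alternative = alternative, method = method, N = N,
                degenerate = TRUE)
    class(out) <- "runs_test"
    return(out)
  }
  mom <- vapply(seqs, function(s) k_runs_moments(table(s)), c(E = 0, V = 0))
  E_R <- sum(mom["E", ]); Var_R <- sum(mom["V", ])
  z <- if (Var_R > 0) (R_obs - E_R) / sqrt(Var_R) else NA_real_
  if (method == "normal_approx") {
    p <- if (!is.finite(z)) 1 else switch(alternative,
      more_runs = stats::pnorm(z, lower.tail = FALSE),
      fewer_runs = stats::pnorm(z),
      two_sided = 2 * stats::pnorm(-abs(z)))
    p <- min(p, 1)
  } else {
    if (n_mc < 100) stop("n_mc must be at least 100")
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_mc)) {
        Rb <- sum(vapply(seqs, function(s) n_runs(sample(s)), 0L))
        hit <- switch(alternative,
                      more_runs = Rb >= R_obs,
                      fewer_runs = Rb <= R_obs,
                      two_sided = abs(Rb - E_R) >= abs(R_obs - E_R))
        if (hit) hits <- hits + 1L
      }
      (hits + 1) / (n_mc + 1)
    })
  }
  out <- list(R_obs = R_obs, E_R = E_R, Var_R = Var_R, z = z, p = p,
              alternative = alternative, method = method, N = N,
              n_mc = if (method == "monte_carlo") n_mc else NULL,
              degenerate = FALSE)
  class(out) <- "runs_test"
  out
}

#' @export
print.runs_test <- function(x, ...) {
  cat(sprintf("Runs test (%s, %s): R = %d, E[R] = %.3f, Var[R] = %.3f\n",
              x$alternative, x$method, x$R_obs, x$E_R, x$Var_R))
  cat(sprintf("z = %.3f, p = %.4g%s\n", x$z, x$p,
              if (isTRUE(x$degenerate)) " [degenerate: single category]" else ""))
  invisible(x)
}

#' Wald-Wolfowitz runs test for clustered group inter-visit intervals
#'
#' If a group provisions in synchronous bouts, its group IVIs (intervals
#' between successive visits by anyone) cluster: consecutive short intervals
#' within bouts, long intervals between them, hence fewer short/long runs
#' than expected. Each IVI is dichotomized at a threshold (the median by
#' default; ties count as short) and the standard two-category runs test is
#' applied: `E[R] = 2 n1 n2 / N + 1`,
#' `Var[R] = 2 n1 n2 (2 n1 n2 - N) / (N^2 (N - 1))`. The default alternative
#' is one-sided for fewer runs (clustering).
#'
#' @param ivis numeric vector of group inter-visit intervals for one day
#'   (at least 4).
#' @param threshold dichotomization threshold; defaults to `median(ivis)`.
#' @param alternative as in [k_category_runs_test()]; default
#'   `"fewer_runs"`.
#' @return list of class `runs_test`.
#' @export
ww_bout_test <- function(ivis, threshold = NULL,
                         alternative = c("fewer_runs", "more_runs",
                                         "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(ivis))
  if (length(ivis) < 4) stop("need at least 4 inter-visit intervals")
  threshold <- threshold %||% stats::median(ivis)
  short <- ivis <= threshold
  n1 <- sum(short); n2 <- sum(!short); N <- n1 + n2
  R_obs <- n_runs(short)
  if (n1 == 0L || n2 == 0L) {
    out <- list(R_obs = R_obs, E_R = 1, Var_R = 0, z = NA_real_, p = 1,
                alternative = alternative, method = "normal_approx",
                N = N, degenerate = TRUE)
    class(out) <- "runs_test"
    return(out)
  }
  E_R <- 2 * n1 * n2 / N + 1
  Var_R <- 2 * n1 * n2 * (2 * n1 * n2 - N) / (N^2 * (N - 1))
  z <- if (Var_R > 0) (R_obs - E_R) / sqrt(Var_R) else NA_real_
  p <- if (!is.finite(z)) 1 else switch(alternative,
    fewer_runs = stats::pnorm(z),
    more_runs = stats::pnorm(z, lower.tail = FALSE),
    two_sided = 2 * stats::pnorm(-abs(z)))
  out <- list(R_obs = R_obs, E_R = E_R, Var_R = Var_R, z = z, p = min(p, 1),
              alternative = alternative, method = "normal_approx", N = N,
              n_short = n1, n_long = n2, threshold = threshold,
              degenerate = FALSE)
  class(out) <- "runs_test"
  out
}

## within-day IVIs, per carer; days concatenated in temporal order
carer_ivis <- function(attempt, carers = NULL) {
  visits <- attempt$visits
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  carers <- carers %||% sort(unique(visits$carer_id))
  out <- stats::setNames(vector("list", length(carers)), carers)
  for (id in carers) {
    v <- visits[visits$carer_id == id, , drop = FALSE]
    iv <- unlist(lapply(split(v$time, v$day_index), function(t)
      if (length(t) >= 2) diff(sort(t)) else numeric(0)), use.names = FALSE)
    out[[id]] <- iv
  }
  out
}

group_ivis <- function(attempt, carers = NULL, day = NULL) {
  visits <- attempt$visits
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  if (!is.null(carers))
    visits <- visits[visits$carer_id %in% carers, , drop = FALSE]
  if (!is.null(day)) visits <- visits[visits$day_index %in% day, , drop = FALSE]
  unlist(lapply(split(visits$time, visits$day_index), function(t)
    if (length(t) >= 2) diff(sort(t)) else numeric(0)), use.names = FALSE)
}

#' Inter-visit interval summaries
#'
#' Per-carer within-day IVI counts, medians, means and the fraction shorter
#' than one hour, plus the median group IVI (interval between successive
#' visits by anyone). IVIs never span a day boundary.
#'
#' @param attempt a [provisioning_attempt()].
#' @param carers optional significant-carer filter.
#' @return list with `per_carer` (data frame), `group_median_s`,
#'   `group_n_ivi`, `frac_under_1h` (all carers pooled).
#' @export
ivi_summaries <- function(attempt, carers = NULL) {
  ivl <- carer_ivis(attempt, carers)
  per <- data.frame(
    carer_id = names(ivl),
    n_ivi = vapply(ivl, length, 0L),
    median_s = vapply(ivl, function(v) if (length(v)) stats::median(v) else NA_real_, 0),
    mean_s = vapply(ivl, function(v) if (length(v)) mean(v) else NA_real_, 0),
    frac_under_1h = vapply(ivl, function(v)
      if (length(v)) mean(v < 3600) else NA_real_, 0),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  g <- group_ivis(attempt, carers)
  all_iv <- unlist(ivl, use.names = FALSE)
  list(per_carer = per,
       group_median_s = if (length(g)) stats::median(g) else NA_real_,
       group_n_ivi = length(g),
       frac_under_1h = if (length(all_iv)) mean(all_iv < 3600) else NA_real_,
       flagged_carers = per$carer_id[per$n_ivi == 0])
}

#' Ordering diagnostic for the randomization test
#'
#' The IVI randomization test assumes each carer's intervals are
#' exchangeable within day; a systematic trend in interval length over the
#' observation period would bias it. For each carer, the intervals (days
#' concatenated in temporal order) are rank-correlated with their temporal
#' index, and a two-sided permutation p score is computed with the add-one
#' `(r + 1) / (n + 1)` estimator. Under no ordering the p scores are
#' approximately uniform, so their mean should sit near 0.5.
#'
#' @param attempt a [provisioning_attempt()].
#' @param carers optional significant-carer filter.
#' @param n_perm permutations per carer.
#' @param seed optional RNG seed.
#' @param min_ivis carers with fewer intervals are skipped (flagged).
#' @return list of class `ordering_result` with `per_carer` (carer, n_ivi,
#'   rho, p_score, flag), `mean_p`, `sd_p`.
#' @export
ordering_score <- function(attempt, carers = NULL, n_perm = 999, seed = NULL,
                           min_ivis = 5) {
  ivl <- carer_ivis(attempt, carers)
  res <- with_seed(seed, lapply(ivl, function(iv) {
    if (length(iv) < min_ivis)
      return(list(n = length(iv), rho = NA_real_, p = NA_real_,
                  flag = "too few IVIs"))
    if (stats::sd(iv) == 0)
      return(list(n = length(iv), rho = NA_real_, p = 1,
                  flag = "constant IVIs: correlation undefined"))
    idx <- seq_along(iv)
    rho <- stats::cor(iv, idx, method = "spearman")
    hits <- 0L
    for (b in seq_len(n_perm)) {
      r <- stats::cor(sample(iv), idx, method = "spearman")
      if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
    }
    list(n = length(iv), rho = rho, p = (hits + 1) / (n_perm + 1), flag = NA)
  }))
  per <- data.frame(
    carer_id = names(res),
    n_ivi = vapply(res, `[[`, 0L, "n"),
    rho = vapply(res, `[[`, 0, "rho"),
    p_score = vapply(res, `[[`, 0, "p"),
    flag = vapply(res, function(r) as.character(r$flag %||% NA), ""),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  ps <- per$p_score[!is.na(per$p_score) & is.na(per$flag)]
  out <- list(per_carer = per,
              mean_p = if (length(ps)) mean(ps) else NA_real_,
              sd_p = if (length(ps) > 1) stats::sd(ps) else NA_real_)
  class(out) <- "ordering_result"
  out
}

#' @export
print.ordering_result <- function(x, ...) {
  cat(sprintf("IVI ordering diagnostic: mean p score %.3f (SD %.3f) over %d carer(s)\n",
              x$mean_p, x$sd_p, nrow(x$per_carer)))
  invisible(x)
}
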