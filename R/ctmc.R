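#' Sufficient statistics for the visit Markov model
#'
#' The continuous-time Markov model of nest visits has state "identity of
#' the last carer to visit". With exactly observed event times its
#' likelihood depends on the data only through the transition counts
#' `n[i, j]` — visits by carer j immediately following a visit by carer i
#' within the same observation day — and the exposures `T[i]`, the total
#' time spent with i as last visitor over fully observed inter-visit
#' intervals. The first visit of each day opens the state but contributes no
#' transition, and the interval after a day's last visit contributes nothing
#' (no censoring term).
#'
#' @param x a [provisioning_attempt()] or a data frame with `day_index`,
#'   `carer_id`, `time` (seconds).
#' @param carers character vector of significant carer ids, or a
#'   [classify_significant()] result. Visits by other carers are dropped
#'   (with a message). Defaults to all carers present.
#' @return Object of class `visit_suffstats`: `carers`, `n` (c x c integer
#'   matrix, rows = previous visitor, cols = next visitor), `T` (named
#'   numeric, seconds), `n_days`, `n_visits` (visits by significant carers
#'   on retained days), `time_unit = "second"`.
#' @export
sufficient_stats <- function(x, carers = NULL) {
  visits <- if (inherits(x, "provisioning_attempt")) x$visits else x
  stopifnot(is.data.frame(visits),
            all(c("day_index", "carer_id", "time") %in% names(visits)))
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  carers <- carers %||% sort(unique(visits$carer_id))
  drop <- !(visits$carer_id %in% carers)
  if (any(drop)) {
    message(sum(drop), " visit(s) by non-significant carers dropped")
    visits <- visits[!drop, , drop = FALSE]
  }
  visits <- visits[order(visits$day_index, visits$time), , drop = FALSE]
  C <- length(carers)
  n <- matrix(0L, C, C, dimnames = list(carers, carers))
  Texp <- stats::setNames(numeric(C), carers)
  n_visits <- 0L
  days <- unique(visits$day_index)
  for (d in days) {
    v <- visits[visits$day_index == d, , drop = FALSE]
    n_visits <- n_visits + nrow(v)
    if (nrow(v) < 2L) next
    idx <- match(v$carer_id, carers)
    prev <- idx[-nrow(v)]; nxt <- idx[-1L]
    dt <- diff(v$time)
    n <- n + matrix(tabulate((nxt - 1L) * C + prev, nbins = C * C), C, C)
    for (i in unique(prev)) Texp[i] <- Texp[i] + sum(dt[prev == i])
  }
  structure(list(carers = carers, n = n, T = Texp,
                 n_days = length(days), n_visits = n_visits,
                 time_unit = "second"),
            class = "visit_suffstats")
}

#' @export
print.visit_suffstats <- function(x, ...) {
  cat(sprintf("Visit sufficient statistics: %d carers, %d visits, %d day(s)\n",
              length(x$carers), x$n_visits, x$n_days))
  cat("transition counts n[prev, next]:\n"); print(x$n)
  cat("exposures T (", x$time_unit, "):\n", sep = ""); print(x$T)
  invisible(x)
}

time_unit_seconds <- function(unit) {
  switch(match.arg(unit, c("hour", "minute", "second")),
         hour = 3600, minute = 60, second = 1)
}

#' Log-likelihood of a visit-rate matrix
#'
#' For exactly observed transitions the log-likelihood is
#' `sum_ij n[i,j] log q[i,j] - sum_i T[i] * sum_j q[i,j]`, with the
#' convention `0 * log 0 = 0`. A zero rate against a positive count yields
#' `-Inf` (a support violation, never attained at the maximum). `q` and
#' `stats$T` must be in consistent units (rates per unit time, exposures in
#' that unit).
#'
#' @param q c x c nonnegative rate matrix; `q[i, j]` is the rate at which
#'   carer j visits while i is the last visitor (diagonal = repeat rates).
#' @param stats a [sufficient_stats()] result (or compatible list with `n`
#'   and `T`).
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
ctmc_loglik <- function(q, stats) {
  n <- stats$n; Texp <- stats$T
  stopifnot(is.matrix(q), all(dim(q) == dim(n)), all(q >= 0))
  pos <- n > 0
  if (any(pos & q == 0)) return(-Inf)
  sum(n[pos] * log(q[pos])) - sum(Texp * rowSums(q))
}

new_ctmc_fit <- function(model, rates, stats, time_unit, extra = list()) {
  ll <- ctmc_loglik(rates, stats)
  n_params <- switch(model,
                     full = as.integer(length(stats$carers)^2),
                     per_individual = 2L * length(stats$carers),
                     pooled = 2L)
  structure(c(list(model = model, rates = rates, logLik = ll,
                   n_params = n_params, carers = stats$carers,
                   stats = stats, time_unit = time_unit), extra),
            class = "ctmc_fit")
}

scale_stats <- function(stats, time_unit) {
  from <- time_unit_seconds(stats$time_unit %||% "second")
  to <- time_unit_seconds(time_unit)
  stats$T <- stats$T * from / to
  stats$time_unit <- time_unit
  stats
}

#' Fit the continuous-time Markov model of nest visits
#'
#' Fits one of three nested rate structures by maximum likelihood (all
#' closed form, since transitions are exactly observed):
#' \describe{
#'   \item{`full`}{every rate free: `q[i, j] = n[i, j] / T[i]`, giving c^2
#'     parameters — how likely each bird is to follow each other bird.}
#'   \item{`per_individual`}{each carer i has a repeat rate `mu_i` (visiting
#'     after itself) and a single following rate `lambda_i` (visiting after
#'     any other carer): `mu_i = n[i, i] / T[i]`,
#'     `lambda_i = sum_{j != i} n[j, i] / sum_{j != i} T[j]`; 2c parameters.}
#'   \item{`pooled`}{all carers share one following rate `lambda0 =
#'     sum_{i != j} n[i, j] / ((c - 1) sum_i T[i])` and one repeat rate
#'     `mu0 = sum_i n[i, i] / sum_i T[i]`; 2 parameters.}
#' }
#' Turn-taking appears as `lambda > mu`: carers visit at a higher rate when
#' another bird was the last to visit than when they were themselves.
#'
#' @param x a [sufficient_stats()] result, a [provisioning_attempt()], or a
#'   visit data frame (the latter two are reduced via [sufficient_stats()]).
#' @param model rate structure to fit.
#' @param time_unit unit for reported rates and the log-likelihood
#'   (`"hour"` default; rates are events per unit).
#' @param carers forwarded to [sufficient_stats()] when `x` is not already a
#'   statistics object.
#' @return Object of class `ctmc_fit` with elements `rates` (c x c expanded
#'   matrix), `lambda`/`mu` (per-individual model), `lambda0`/`mu0` (pooled),
#'   `logLik`, `n_params`, `model`, `stats`.
#' @seealso [lrt()], [turn_taking_ratio()], [anova.ctmc_fit()]
#' @export
fit_ctmc <- function(x, model = c("full", "per_individual", "pooled"),
                     time_unit = c("hour", "minute", "second"),
                     carers = NULL) {
  model <- match.arg(model)
  time_unit <- match.arg(time_unit)
  stats <- if (inherits(x, "visit_suffstats")) x else
    sufficient_stats(x, carers)
  stats <- scale_stats(stats, time_unit)
  n <- stats$n; Texp <- stats$T; C <- length(stats$carers)
  if (model != "full" && C < 2)
    stop("constrained models need at least 2 carers")
  if (model == "full") {
    q <- n / ifelse(Texp > 0, Texp, 1)       # rows with T = 0 have n = 0
    q[Texp == 0, ] <- 0
    return(new_ctmc_fit("full", q, stats, time_unit))
  }
  if (model == "per_individual") {
    mu <- ifelse(Texp > 0, diag(n) / Texp, 0)
    lambda <- numeric(C)
    for (i in seq_len(C)) {
      To <- sum(Texp[-i])
      lambda[i] <- if (To > 0) sum(n[-i, i]) / To else 0
    }
    names(mu) <- names(lambda) <- stats$carers
    q <- matrix(rep(lambda, each = C), C, C,
                dimnames = list(stats$carers, stats$carers))
    diag(q) <- mu
    return(new_ctmc_fit("per_individual", q, stats, time_unit,
                        list(lambda = lambda, mu = mu)))
  }
  Ttot <- sum(Texp)
  lambda0 <- if (Ttot > 0) (sum(n) - sum(diag(n))) / ((C - 1) * Ttot) else 0
  mu0 <- if (Ttot > 0) sum(diag(n)) / Ttot else 0
  q <- matrix(lambda0, C, C, dimnames = list(stats$carers, stats$carers))
  diag(q) <- mu0
  new_ctmc_fit("pooled", q, stats, time_unit,
               list(lambda0 = lambda0, mu0 = mu0))
}

#' @export
print.ctmc_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Visit CTMC fit (%s model): %d carers, %d parameters\n",
              x$model, length(x$carers), x$n_params))
  cat(sprintf("logLik = %.4f (rates per %s)\n", x$logLik, x$time_unit))
  if (x$model == "per_individual") {
    print(round(rbind(lambda = x$lambda, mu = x$mu), digits))
  } else if (x$model == "pooled") {
    cat(sprintf("lambda0 = %.*f, mu0 = %.*f\n", digits, x$lambda0,
                digits, x$mu0))
  } else {
    print(round(x$rates, digits))
  }
  invisible(x)
}

#' @export
coef.ctmc_fit <- function(object, ...) {
  switch(object$model,
         full = {
           q <- object$rates
           stats::setNames(as.vector(q), outer(rownames(q), colnames(q),
                                               function(a, b) paste0(a, "->", b)))
         },
         per_individual = c(stats::setNames(object$lambda,
                                            paste0("lambda.", object$carers)),
                            stats::setNames(object$mu,
                                            paste0("mu.", object$carers))),
         pooled = c(lambda0 = object$lambda0, mu0 = object$mu0))
}

#' @export
logLik.ctmc_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' @export
summary.ctmc_fit <- function(object, ...) {
  out <- list(fit = object,
              ratio = if (object$model == "per_individual")
                turn_taking_ratio(object) else NULL)
  class(out) <- "summary.ctmc_fit"
  out
}

#' @export
print.summary.ctmc_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ratio)) {
    cat("per-carer lambda/mu:\n"); print(round(x$ratio$per_carer, 3))
    cat(sprintf("group ratio mean(lambda)/mean(mu) = %.3f\n",
                x$ratio$group_ratio))
  }
  invisible(x)
}

model_order <- c(pooled = 1L, per_individual = 2L, full = 3L)

#' Likelihood-ratio test between nested visit-rate models
#'
#' `2 * (logLik(general) - logLik(constrained))` referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in free
#' parameters. Both fits must come from the same sufficient statistics and
#' the constrained model must be nested in the general one (pooled in
#' per-individual in full). A statistic within -1e-8 of zero is clamped to
#' zero. When either fit has zero rates against positive exposure on the
#' boundary the chi-squared reference degrades; the result is flagged.
#'
#' @param general,constrained `ctmc_fit` objects on the same data.
#' @return list of class `lrt_result` with `stat`, `df`, `p`,
#'   `boundary_flag`.
#' @export
lrt <- function(general, constrained) {
  stopifnot(inherits(general, "ctmc_fit"), inherits(constrained, "ctmc_fit"))
  if (model_order[general$model] <= model_order[constrained$model])
    stop("constrained model must be nested in general model")
  if (!identical(general$stats$n, constrained$stats$n) ||
      !isTRUE(all.equal(unname(general$stats$T * time_unit_seconds(general$time_unit)),
                        unname(constrained$stats$T * time_unit_seconds(constrained$time_unit)))))
    stop("fits are not based on the same sufficient statistics")
  stat <- 2 * (general$logLik - constrained$logLik)
  if (stat < 0 && stat > -1e-8) stat <- 0
  if (stat < 0) stop("negative LRT statistic: models not nested or misfit")
  df <- general$n_params - constrained$n_params
  boundary <- any(general$rates == 0 & general$stats$T > 0) ||
    any(constrained$rates == 0 & constrained$stats$T > 0)
  structure(list(stat = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 general = general$model, constrained = constrained$model,
                 boundary_flag = boundary),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi-sq = %.4f, df = %d, p = %.4g%s\n",
              x$general, x$constrained, x$stat, x$df, x$p,
              if (x$boundary_flag) " [boundary rates: asymptotics approximate]" else ""))
  invisible(x)
}

#' Compare nested visit-rate fits
#'
#' `anova()` on two or more `ctmc_fit` objects (same data) orders them by
#' complexity and reports sequential likelihood-ratio tests.
#'
#' @param object,... `ctmc_fit` objects.
#' @return data frame with one row per model and LRT columns against the
#'   previous (simpler) model.
#' @export
anova.ctmc_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  stopifnot(all(vapply(fits, inherits, TRUE, "ctmc_fit")))
  fits <- fits[order(vapply(fits, function(f) model_order[f$model], 1L))]
  out <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    n_params = vapply(fits, `[[`, 1L, "n_params"),
                    logLik = vapply(fits, `[[`, 1, "logLik"),
                    stat = NA_real_, df = NA_integer_, p = NA_real_)
  if (length(fits) > 1) for (k in 2:length(fits)) {
    tt <- lrt(fits[[k]], fits[[k - 1]])
    out$stat[k] <- tt$stat; out$df[k] <- tt$df; out$p[k] <- tt$p
  }
  out
}

#' Turn-taking ratios from a per-individual fit
#'
#' Per-carer `lambda_i / mu_i` (infinite when `mu_i = 0` with
#' `lambda_i > 0`; flagged) and the group ratio
#' `mean_i(lambda_i) / mean_i(mu_i)`. A ratio above 1 indicates
#' turn-taking: a carer's visit rate is higher following another bird than
#' following itself.
#'
#' @param fit a `ctmc_fit` with `model = "per_individual"`.
#' @return list with `per_carer`, `group_ratio`, `flags`.
#' @export
turn_taking_ratio <- function(fit) {
  stopifnot(inherits(fit, "ctmc_fit"))
  if (fit$model != "per_individual")
    stop("turn_taking_ratio needs a per_individual fit")
  per <- ifelse(fit$mu > 0, fit$lambda / fit$mu,
                ifelse(fit$lambda > 0, Inf, NaN))
  names(per) <- fit$carers
  mmu <- mean(fit$mu)
  group <- if (mmu > 0) mean(fit$lambda) / mmu else NA_real_
  flags <- character()
  if (any(!is.finite(per)))
    flags <- c(flags, "some per-carer ratios undefined or infinite (mu = 0)")
  if (mmu == 0) flags <- c(flags, "group ratio undefined (mean mu = 0)")
  list(per_carer = per, group_ratio = group, flags = flags)
}

#' Wilcoxon signed-rank comparison of following vs repeat rates
#'
#' Paired comparison of per-carer `lambda_i` against `mu_i` across the
#' carers of one or more fits. The exact distribution is used for 25 or
#' fewer pairs (without ties), the normal approximation above.
#'
#' @param fit a per-individual `ctmc_fit`, or a list of them (carers
#'   pooled across fits).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
wilcoxon_lambda_mu <- function(fit) {
  fits <- if (inherits(fit, "ctmc_fit")) list(fit) else fit
  stopifnot(all(vapply(fits, function(f)
    inherits(f, "ctmc_fit") && f$model == "per_individual", TRUE)))
  lambda <- unlist(lapply(fits, `[[`, "lambda"))
  mu <- unlist(lapply(fits, `[[`, "mu"))
  suppressWarnings(
    stats::wilcox.test(lambda, mu, paired = TRUE,
                       exact = length(lambda) <= 25))
}

#' Reciprocity of pairwise following rates
#'
#' Rank correlation between `q[i, j]` and `q[j, i]` over unordered carer
#' pairs: do birds preferentially follow the birds that follow them? The
#' p-value is by seeded permutation of pair labels. Undefined (flagged) for
#' fewer than 3 carers, where only one pair exists.
#'
#' @param x a full-model `ctmc_fit` or a rate matrix.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return list with `rho`, `p`, `n_pairs`, `flag`.
#' @export
reciprocity_correlation <- function(x, n_perm = 999, seed = NULL) {
  q <- if (inherits(x, "ctmc_fit")) x$rates else x
  stopifnot(is.matrix(q), nrow(q) == ncol(q))
  C <- nrow(q)
  if (C < 3)
    return(list(rho = NA_real_, p = NA_real_, n_pairs = if (C == 2) 1L else 0L,
                flag = "undefined for fewer than 3 carers"))
  ut <- which(upper.tri(q), arr.ind = TRUE)
  xv <- q[ut]; yv <- q[ut[, 2:1, drop = FALSE]]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_pairs = nrow(ut),
                flag = "constant rates: correlation undefined"))
  rho <- stats::cor(xv, yv, method = "spearman")
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      r <- stats::cor(xv, sample(yv), method = "spearman")
      if (abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
    }
    list(rho = rho, p = (exceed + 1) / (n_perm + 1), n_pairs = nrow(ut),
         flag = NULL)
  })
}

#' Dummy-state model structure for a general multi-state fitter
#'
#' The who-follows-whom process has "silent" self-transitions (repeat
#' visits) that general multi-state software cannot represent directly. The
#' standard workaround doubles the state space: each carer i gets a base
#' state A_i ("i was last visitor") and a dummy state B_i entered on a
#' repeat visit, with an automatic reset transition B_i -> A_i fixed at an
#' arbitrary very high rate. For c carers this gives 2c states and
#' c(c + 1) transitions: c^2 estimated visit rates (from each base state, to
#' the other carers' base states or to own dummy) plus c fixed resets. This
#' export exists for cross-validation against such fitters; the package's
#' own likelihood never needs it.
#'
#' @param c number of carers.
#' @param carers optional carer ids (defaults to `C1..Cc`).
#' @return list with `n_states`, `states` (data frame), `transitions`
#'   (data frame with `from`, `to`, `type` = `"visit"` or `"reset"`),
#'   `n_visit_transitions`, `n_transitions`.
#' @export
export_msm_structure <- function(c, carers = NULL) {
  stopifnot(is_count(c), c >= 1)
  carers <- carers %||% paste0("C", seq_len(c))
  stopifnot(length(carers) == c)
  states <- data.frame(
    state = c(paste0(carers, ".A"), paste0(carers, ".B")),
    carer = rep(carers, 2L),
    kind = rep(c("base", "dummy"), each = c),
    stringsAsFactors = FALSE)
  tr <- list()
  for (i in seq_len(c)) for (j in seq_len(c)) {
    to <- if (i == j) paste0(carers[j], ".B") else paste0(carers[j], ".A")
    tr[[length(tr) + 1L]] <- data.frame(
      from = paste0(carers[i], ".A"), to = to, type = "visit",
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(c))
    tr[[length(tr) + 1L]] <- data.frame(
      from = paste0(carers[i], ".B"), to = paste0(carers[i], ".A"),
      type = "reset", stringsAsFactors = FALSE)
  transitions <- do.call(rbind, tr)
  list(n_states = 2L * c, states = states, transitions = transitions,
       n_visit_transitions = sum(transitions$type == "visit"),
       n_transitions = nrow(transitions))
}
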