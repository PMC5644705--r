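#' Shuffle one carer-day's inter-visit intervals
#'
#' Core move of the dissociation test: the carer's within-day IVIs are
#' re-ordered uniformly at random and the visit times rebuilt from the
#' observed first visit (the anchor) by cumulative summation. Visit count,
#' IVI multiset, and first and last visit times are all preserved exactly.
#' Uses the current RNG stream; seed at the caller.
#'
#' @param times numeric vector of one carer's visit times within one day.
#' @return Shuffled visit times, sorted ascending.
#' @export
shuffle_day <- function(times) {
  if (length(times) < 3L) return(sort(times))
  t <- sort(times)
  iv <- diff(t)
  c(t[1L], t[1L] + cumsum(sample(iv)))
}

#' Build one dissociated pseudo-dataset
#'
#' Applies [shuffle_day()] independently to every carer-day, merges the
#' artificial visit times per day, and sorts them, breaking exact time ties
#' uniformly at random. The result is a structurally valid
#' [provisioning_attempt()] analyzable by every downstream operation, in
#' which any dependence between the visit times of different carers has been
#' destroyed while each carer's within-day interval structure (including
#' refractory signatures) is preserved.
#'
#' @param attempt a [provisioning_attempt()].
#' @param carers optional significant-carer filter.
#' @return A pseudo `provisioning_attempt`.
#' @export
build_pseudo_attempt <- function(attempt, carers = NULL) {
  stopifnot(inherits(attempt, "provisioning_attempt"))
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  visits <- attempt$visits
  if (!is.null(carers))
    visits <- visits[visits$carer_id %in% carers, , drop = FALSE]
  days <- split(visits, visits$day_index)
  out <- lapply(days, function(v) {
    pieces <- lapply(split(v$time, v$carer_id), shuffle_day)
    carer <- rep(names(pieces), lengths(pieces))
    time <- unlist(pieces, use.names = FALSE)
    o <- order(time, stats::runif(length(time)))  # random tie-break
    data.frame(day_index = v$day_index[1L], carer_id = carer[o],
               time = time[o], stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, out)
  rownames(v) <- NULL
  provisioning_attempt(v, attempt$days, attempt$attempt_id,
                       attempt$metadata)
}

## fast internal representation of an attempt for repeated shuffling:
## per day, the per-carer sorted time vectors plus carer index
rand_prepare <- function(attempt, carers) {
  visits <- attempt$visits
  visits <- visits[visits$carer_id %in% carers, , drop = FALSE]
  lapply(split(visits, visits$day_index), function(v) {
    idx <- match(v$carer_id, carers)
    lapply(split(v$time, idx), sort)  # names are carer indices
  })
}

## one shuffled day -> ordered carer-index sequence and times
rand_shuffle_merge <- function(day) {
  pieces <- lapply(day, shuffle_day)
  idx <- rep(as.integer(names(pieces)), lengths(pieces))
  time <- unlist(pieces, use.names = FALSE)
  o <- order(time, stats::runif(length(time)))
  list(idx = idx[o], time = time[o])
}

## statistics on a merged-day list, via carer indices 1..C
stat_alternation <- function(days) {
  alt <- 0L; pairs <- 0L
  for (d in days) {
    n <- length(d$idx)
    if (n < 2L) next
    alt <- alt + sum(d$idx[-1L] != d$idx[-n])
    pairs <- pairs + n - 1L
  }
  if (pairs > 0) alt / pairs else NA_real_
}

stat_suffstats <- function(days, C) {
  n <- numeric(C * C)
  Texp <- numeric(C)
  for (d in days) {
    m <- length(d$idx)
    if (m < 2L) next
    prev <- d$idx[-m]; nxt <- d$idx[-1L]
    dt <- diff(d$time)
    n <- n + tabulate((nxt - 1L) * C + prev, nbins = C * C)
    for (i in unique(prev)) Texp[i] <- Texp[i] + sum(dt[prev == i])
  }
  list(n = matrix(n, C, C), T = Texp)
}

stat_group_ratio <- function(days, C) {
  s <- stat_suffstats(days, C)
  mu <- ifelse(s$T > 0, diag(s$n) / s$T, 0)
  lambda <- vapply(seq_len(C), function(i) {
    To <- sum(s$T[-i])
    if (To > 0) sum(s$n[-i, i]) / To else 0
  }, 0)
  list(ratio = if (mean(mu) > 0) mean(lambda) / mean(mu) else NA_real_,
       pooled = {
         Tt <- sum(s$T)
         l0 <- if (Tt > 0) (sum(s$n) - sum(diag(s$n))) / ((C - 1) * Tt) else 0
         m0 <- if (Tt > 0) sum(diag(s$n)) / Tt else 0
         if (m0 > 0) l0 / m0 else NA_real_
       })
}

#' Dissociation (randomization) test for active turn-taking
#'
#' Separates active turn-taking — carers responding to each other — from
#' passive turn-taking generated by group size, unequal visit rates and the
#' shape of individual IVI distributions (e.g. refractory periods). Each
#' replication shuffles every carer-day's IVIs ([shuffle_day()]), rebuilds an
#' artificial provisioning day, and recomputes the requested turn-taking
#' statistics; the observed value is then compared to this passive-only null
#' distribution. `p_active = (#\{null >= observed\} + 1) / (n_reps + 1)`
#' (one-sided: active turn-taking pushes both statistics up). The
#' `passive_flag` is set when even the null distribution's minimum exceeds
#' the no-turn-taking reference (ratio 1; for the alternation proportion,
#' the multinomial expectation `1 - sum p_i^2` from the carers' visit
#' shares), indicating passive turn-taking beyond group-size chance.
#'
#' For the `group_lambda_mu_ratio` statistic each replicate is refit with
#' the per-individual model (closed form). If the ratio is undefined (mean
#' repeat rate zero) in more than 5% of replicates, the result is flagged
#' and the pooled-model ratio `lambda0 / mu0` is substituted and labelled.
#'
#' @param attempt a filtered [provisioning_attempt()].
#' @param carers significant carers ([classify_significant()] result or id
#'   vector); defaults to all carers present.
#' @param n_reps number of dissociation replicates (1000 by default).
#' @param statistics any of `"proportion_alternated"`,
#'   `"group_lambda_mu_ratio"`.
#' @param seed optional RNG seed; identical seeds give identical null
#'   distributions.
#' @return list of `randomization_result` objects (one per statistic), each
#'   with `statistic`, `observed`, `null_values`, `p_active`,
#'   `passive_flag`, `reference`, `n_reps`, `seed`, `flags`.
#' @export
randomization_test <- function(attempt, carers = NULL, n_reps = 1000,
                               statistics = c("proportion_alternated",
                                              "group_lambda_mu_ratio"),
                               seed = NULL) {
  stopifnot(inherits(attempt, "provisioning_attempt"))
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (inherits(carers, "carer_set")) carers <- carers$carers$carer_id
  carers <- carers %||% sort(unique(attempt$visits$carer_id))
  C <- length(carers)
  if (C < 2) stop("randomization test needs at least 2 significant carers")
  prep <- rand_prepare(attempt, carers)
  obs_days <- lapply(prep, function(day) {
    idx <- rep(as.integer(names(day)), lengths(day))
    time <- unlist(day, use.names = FALSE)
    o <- order(time)
    list(idx = idx[o], time = time[o])
  })

  want_alt <- "proportion_alternated" %in% statistics
  want_ratio <- "group_lambda_mu_ratio" %in% statistics
  obs_alt <- if (want_alt) stat_alternation(obs_days)
  obs_ratio <- if (want_ratio) stat_group_ratio(obs_days, C)

  null_alt <- if (want_alt) numeric(n_reps)
  null_ratio <- if (want_ratio) numeric(n_reps)
  null_pooled <- if (want_ratio) numeric(n_reps)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      days <- lapply(prep, rand_shuffle_merge)
      if (want_alt) null_alt[b] <- stat_alternation(days)
      if (want_ratio) {
        r <- stat_group_ratio(days, C)
        null_ratio[b] <- r$ratio
        null_pooled[b] <- r$pooled
      }
    }
  })

  results <- list()
  if (want_alt) {
    counts <- vapply(seq_len(C), function(i)
      sum(vapply(obs_days, function(d) sum(d$idx == i), 0L)), 0L)
    p_share <- counts / sum(counts)
    reference <- 1 - sum(p_share^2)   # multinomial no-structure expectation
    results$proportion_alternated <- structure(list(
      statistic = "proportion_alternated", observed = obs_alt,
      null_values = null_alt,
      p_active = (sum(null_alt >= obs_alt, na.rm = TRUE) + 1) / (n_reps + 1),
      passive_flag = isTRUE(min(null_alt, na.rm = TRUE) > reference),
      reference = reference, n_reps = n_reps, seed = seed, flags = NULL),
      class = "randomization_result")
  }
  if (want_ratio) {
    flags <- NULL
    obs <- obs_ratio$ratio
    nulls <- null_ratio
    na_frac <- mean(!is.finite(nulls))
    if (!is.finite(obs) || na_frac > 0.05) {
      flags <- sprintf(
        "per-individual ratio undefined in %.1f%% of replicates; pooled lambda0/mu0 substituted",
        100 * na_frac)
      obs <- obs_ratio$pooled
      nulls <- null_pooled
    }
    results$group_lambda_mu_ratio <- structure(list(
      statistic = "group_lambda_mu_ratio", observed = obs,
      null_values = nulls,
      p_active = (sum(nulls >= obs, na.rm = TRUE) + 1) / (n_reps + 1),
      passive_flag = isTRUE(min(nulls, na.rm = TRUE) > 1),
      reference = 1, n_reps = n_reps, seed = seed, flags = flags),
      class = "randomization_result")
  }
  results
}

#' @export
print.randomization_result <- function(x, ...) {
  q <- stats::quantile(x$null_values, c(0, 0.5, 1), na.rm = TRUE)
  cat(sprintf("Randomization test: %s\n", x$statistic))
  cat(sprintf("  observed %.4f vs null [min %.4f, median %.4f, max %.4f] (%d reps)\n",
              x$observed, q[1], q[2], q[3], x$n_reps))
  cat(sprintf("  p_active = %.4g; passive turn-taking %s (reference %.4f)\n",
              x$p_active,
              if (x$passive_flag) "present (null range excludes reference)"
              else "not flagged", x$reference))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
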