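#' Configuration for the provisioning simulator
#'
#' Three generative modes emulate the statistical structure of cooperative
#' provisioning data:
#' \describe{
#'   \item{`markov`}{the fitted model run generatively: given last visitor
#'     i, carer j visits next after an exponential race with rate
#'     `Q[i, j]`. Ground truth for parameter-recovery and calibration
#'     studies.}
#'   \item{`mechanistic`}{each carer is an independent renewal-like stream
#'     with hazard `base_rates[i]`, silenced during a refractory window
#'     after its own visit (travel + foraging time), and optionally
#'     multiplied by `repeat_suppression` while the carer is the current
#'     last visitor. `repeat_suppression = 1` gives passive turn-taking
#'     only; values below 1 add an active response (repeat rate below
#'     following rate).}
#'   \item{`bouts`}{synchronous group provisioning on top of background
#'     individual provisioning: each carer visits independently at rate
#'     `base_rates[i]` throughout the day, and in addition bout start times
#'     are Poisson (`bout_rate`) with every carer joining a bout with
#'     probability `bout_prob`, queueing at the nest with small i.i.d.
#'     spacings (`bout_jitter`). The background stream is essential for the
#'     mode to exhibit detectable bout clustering: without it every
#'     inter-bout interval is a single gap, so long group IVIs can never
#'     form runs and a fewer-runs signal is impossible in principle.}
#' }
#'
#' @param mode `"markov"`, `"mechanistic"` or `"bouts"`.
#' @param c number of carers (derived from `Q`/`base_rates` if omitted).
#' @param Q c x c rate matrix, events per hour (markov mode).
#' @param base_rates per-carer hazards, events per hour (mechanistic/bouts).
#' @param refractory `list(type = "none")`, `list(type = "fixed", d = sec)`,
#'   or `list(type = "gamma", shape =, scale =)` (scale in seconds).
#' @param repeat_suppression multiplier in `[0, 1]` on a carer's hazard
#'   while it is the last visitor; 1 = no active response.
#' @param day_length observation-day length, seconds (default 12 h).
#' @param n_days number of observation days (default 3).
#' @param bout_rate bouts per hour (bouts mode).
#' @param bout_prob probability each carer visits in a bout.
#' @param bout_jitter mean spacing between successive within-bout visits,
#'   seconds.
#' @param seed optional RNG seed.
#' @param carer_ids optional carer labels (default `C1..Cc`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(mode = c("markov", "mechanistic", "bouts"),
                       c = NULL, Q = NULL, base_rates = NULL,
                       refractory = list(type = "none"),
                       repeat_suppression = 1,
                       day_length = 12 * 3600, n_days = 3,
                       bout_rate = NULL, bout_prob = 0.8, bout_jitter = 30,
                       seed = NULL, carer_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "markov") {
    stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), all(Q >= 0),
              all(is.finite(Q)))
    c <- c %||% nrow(Q)
    stopifnot(c == nrow(Q))
  } else {
    stopifnot(!is.null(base_rates), all(base_rates >= 0))
    c <- c %||% length(base_rates)
    stopifnot(c == length(base_rates))
  }
  stopifnot(is_count(c), c >= 1,
            repeat_suppression >= 0, repeat_suppression <= 1,
            day_length > 0, is_count(n_days), n_days >= 1)
  refractory$type <- match.arg(refractory$type %||% "none",
                               c("none", "fixed", "gamma"))
  if (refractory$type == "fixed") stopifnot(refractory$d >= 0)
  if (refractory$type == "gamma")
    stopifnot(refractory$shape > 0, refractory$scale > 0)
  carer_ids <- carer_ids %||% paste0("C", seq_len(c))
  stopifnot(length(carer_ids) == c)
  structure(list(mode = mode, c = c, Q = Q, base_rates = base_rates,
                 refractory = refractory,
                 repeat_suppression = repeat_suppression,
                 day_length = day_length, n_days = n_days,
                 bout_rate = bout_rate, bout_prob = bout_prob,
                 bout_jitter = bout_jitter, seed = seed,
                 carer_ids = carer_ids),
            class = "sim_config")
}

draw_refractory <- function(refractory, n = 1) {
  switch(refractory$type,
         none = rep(0, n),
         fixed = rep(refractory$d, n),
         gamma = stats::rgamma(n, shape = refractory$shape,
                               scale = refractory$scale))
}

sim_day_markov <- function(Qs, day_start, day_end, carer_ids) {
  C <- nrow(Qs)
  row_tot <- rowSums(Qs)
  cumP <- t(apply(Qs, 1L, function(r)
    if (sum(r) > 0) cumsum(r) / sum(r) else rep(1, C)))
  init_rate <- colMeans(Qs)                    # row-averaged arrival rates
  if (sum(init_rate) == 0)
    return(data.frame(carer_id = character(), time = numeric()))
  t <- day_start + stats::rexp(1, sum(init_rate))
  if (t >= day_end)
    return(data.frame(carer_id = character(), time = numeric()))
  state <- sample.int(C, 1L, prob = init_rate)
  ids <- integer(256); times <- numeric(256)
  k <- 1L; ids[1L] <- state; times[1L] <- t
  repeat {
    tot <- row_tot[state]
    if (tot == 0) break
    t <- t + stats::rexp(1, tot)
    if (t >= day_end) break
    state <- findInterval(stats::runif(1), cumP[state, ]) + 1L
    k <- k + 1L
    if (k > length(ids)) {
      length(ids) <- 2L * length(ids); length(times) <- 2L * length(times)
    }
    ids[k] <- state; times[k] <- t
  }
  data.frame(carer_id = carer_ids[ids[seq_len(k)]],
             time = times[seq_len(k)], stringsAsFactors = FALSE)
}

sim_day_mechanistic <- function(base_s, refractory, beta, day_start, day_end,
                                carer_ids) {
  C <- length(base_s)
  t <- day_start
  last <- 0L
  block <- rep(day_start, C)   # carer i silent while t < block[i]
  ids <- integer(256); times <- numeric(256); k <- 0L
  repeat {
    h <- ifelse(t < block, 0, base_s * ifelse(seq_len(C) == last, beta, 1))
    H <- sum(h)
    future <- block[block > t]
    tc <- min(c(future, day_end))    # next hazard change point
    if (H == 0) {
      if (tc >= day_end) break
      t <- tc
      next
    }
    dt <- stats::rexp(1, H)
    if (t + dt >= tc) {
      if (tc >= day_end) break
      t <- tc
      next
    }
    t <- t + dt
    j <- sample.int(C, 1L, prob = h)
    k <- k + 1L
    if (k > length(ids)) {
      length(ids) <- 2L * length(ids); length(times) <- 2L * length(times)
    }
    ids[k] <- j; times[k] <- t
    last <- j
    block[j] <- t + draw_refractory(refractory)
  }
  data.frame(carer_id = carer_ids[ids[seq_len(k)]],
             time = times[seq_len(k)], stringsAsFactors = FALSE)
}

sim_day_bouts <- function(rate_s, prob, jitter, base_s, day_start, day_end,
                          carer_ids) {
  C <- length(carer_ids)
  len <- day_end - day_start
  ids <- character(0); times <- numeric(0)
  # background individual provisioning between bouts: without it, every
  # inter-bout interval is one single gap, and clustering of long group
  # IVIs (hence a fewer-runs signal) could never arise
  for (i in seq_len(C)) {
    nb <- stats::rpois(1, base_s[i] * len)
    if (nb > 0) {
      ids <- c(ids, rep(carer_ids[i], nb))
      times <- c(times, stats::runif(nb, day_start, day_end))
    }
  }
  n_bouts <- stats::rpois(1, rate_s * len)
  if (n_bouts == 0 && length(ids) == 0)
    return(data.frame(carer_id = character(), time = numeric()))
  starts <- if (n_bouts > 0) sort(stats::runif(n_bouts, day_start, day_end))
            else numeric(0)
  for (s in starts) {
    who <- which(stats::runif(C) < prob)
    if (!length(who)) next
    # participants queue at the nest: sequential arrivals with small
    # i.i.d. spacings, in random order
    who <- who[sample.int(length(who))]
    tt <- s + cumsum(stats::rexp(length(who), 1 / jitter))
    keep <- tt < day_end
    ids <- c(ids, carer_ids[who[keep]])
    times <- c(times, tt[keep])
  }
  o <- order(times)
  data.frame(carer_id = ids[o], time = times[o], stringsAsFactors = FALSE)
}

#' Simulate a provisioning attempt
#'
#' Generates a multi-day [provisioning_attempt()] under the configured mode
#' (see [sim_config()]). Fully deterministic given `config$seed`. Days are
#' laid out on consecutive calendar offsets (day d occupies
#' `[(d-1) * 86400, (d-1) * 86400 + day_length)` seconds) and metadata brood
#' ages are set above the standard filtering threshold so that simulated
#' attempts pass [apply_filters()] unchanged.
#'
#' @param config a [sim_config()].
#' @param attempt_id label for the simulated attempt.
#' @return A `provisioning_attempt`. Empty attempts (all rates zero) carry
#'   attribute `"empty"` = TRUE.
#' @export
simulate_provisioning <- function(config, attempt_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    days <- data.frame(day_index = seq_len(config$n_days),
                       day_start = (seq_len(config$n_days) - 1) * 86400,
                       day_end = (seq_len(config$n_days) - 1) * 86400 +
                         config$day_length)
    out <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      v <- switch(config$mode,
        markov = sim_day_markov(config$Q / 3600, days$day_start[d],
                                days$day_end[d], config$carer_ids),
        mechanistic = sim_day_mechanistic(
          config$base_rates / 3600, config$refractory,
          config$repeat_suppression, days$day_start[d], days$day_end[d],
          config$carer_ids),
        bouts = sim_day_bouts(
          (config$bout_rate %||% stop("bout_rate required")) / 3600,
          config$bout_prob, config$bout_jitter, config$base_rates / 3600,
          days$day_start[d], days$day_end[d], config$carer_ids))
      if (nrow(v)) v$day_index <- days$day_index[d]
      out[[d]] <- v
    }
    out <- out[vapply(out, nrow, 0L) > 0]
    v <- if (length(out)) do.call(rbind, out) else
      data.frame(day_index = integer(), carer_id = character(),
                 time = numeric())
    md <- list(
      brood_age = stats::setNames(10 + seq_len(config$n_days),
                                  days$day_index),
      carer_class = stats::setNames(rep("unknown", config$c),
                                    config$carer_ids))
    att <- provisioning_attempt(v[, c("day_index", "carer_id", "time")],
                                days, attempt_id, md)
    if (nrow(v) == 0) attr(att, "empty") <- TRUE
    att
  })
}
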