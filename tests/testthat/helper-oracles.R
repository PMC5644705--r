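## Independent oracles used by the tests. These never call the code paths
## they check.

## Exhaustive enumeration of the runs-count distribution over all distinct
## arrangements of a multiset with the given category counts. Under the
## permutation null every distinct arrangement is equally likely (each
## corresponds to the same number, prod(n_i!), of underlying permutations).
enum_runs <- function(counts) {
  counts <- as.integer(counts[counts > 0])
  N <- sum(counts)
  out <- integer(0)
  rec <- function(cnt, last, runs, left) {
    if (left == 0L) {
      out[[length(out) + 1L]] <<- runs
      return(invisible())
    }
    for (k in seq_along(cnt)) {
      if (cnt[k] == 0L) next
      cnt[k] <- cnt[k] - 1L
      rec(cnt, k, runs + as.integer(k != last), left - 1L)
      cnt[k] <- cnt[k] + 1L
    }
  }
  rec(counts, 0L, 0L, N)
  out
}

## All partitions of n into at least `min_parts` positive parts
## (category label identities do not affect the runs distribution).
partitions_of <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k))
      out[[length(out) + 1L]] <- c(k, rest)
  }
  out
}

## Numerical maximum-likelihood fit of a visit-rate model by quasi-Newton
## optimization of the log-likelihood over log rates, with analytic
## gradient. Independent route against the closed-form estimators.
numeric_mle <- function(stats, model = c("full", "per_individual", "pooled")) {
  model <- match.arg(model)
  C <- length(stats$carers)
  n <- stats$n
  Tm <- matrix(stats$T, C, C)  # row i = exposure of state i
  map <- matrix(0L, C, C)
  if (model == "full") {
    map[] <- seq_len(C * C)
  } else if (model == "per_individual") {
    for (i in seq_len(C)) for (j in seq_len(C))
      map[i, j] <- if (i == j) C + j else j     # lambda_j / mu_j
  } else {
    map[] <- 2L; diag(map) <- 1L                # mu0 = 1, lambda0 = 2
  }
  P <- max(map)
  cnt <- vapply(seq_len(P), function(p) sum(n[map == p]), 0)
  expo <- vapply(seq_len(P), function(p) sum(Tm[map == p]), 0)
  est <- which(cnt > 0 & expo > 0)
  negll <- function(theta) {
    rates <- numeric(P); rates[est] <- exp(theta)
    -ctmc_loglik(matrix(rates[map], C, C), stats)
  }
  grad <- function(theta) {
    rates <- numeric(P); rates[est] <- exp(theta)
    q <- matrix(rates[map], C, C)
    gq <- ifelse(q > 0, n / ifelse(q > 0, q, 1), 0) - Tm  # d ll / d q
    gp <- vapply(est, function(p) sum(gq[map == p]), 0)
    -gp * exp(theta)
  }
  init <- log(cnt[est] / expo[est]) + 0.5       # deliberately off-optimum
  opt <- stats::optim(init, negll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  rates <- numeric(P); rates[est] <- exp(opt$par)
  list(rates = matrix(rates[map], C, C,
                      dimnames = dimnames(n)),
       logLik = -opt$value, convergence = opt$convergence,
       estimable = matrix(map %in% est, C, C))
}

## A small simulated attempt for reuse in tests.
toy_markov_attempt <- function(C = 2, rate = 20, n_days = 1,
                               day_length = 6 * 3600, seed = 1) {
  Q <- matrix(rate, C, C)
  simulate_provisioning(sim_config("markov", Q = Q, n_days = n_days,
                                   day_length = day_length, seed = seed))
}

## The worked two-carer example: visits A@0, B@10, B@25, A@40 minutes.
toy_ab_visits <- function() {
  data.frame(day_index = 1, carer_id = c("A", "B", "B", "A"),
             time = c(0, 10, 25, 40) * 60)
}
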