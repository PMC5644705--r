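test_that("sufficient statistics match hand enumeration on the worked example", {
  st <- sufficient_stats(toy_ab_visits())
  expect_equal(st$n, matrix(c(0L, 1L, 1L, 1L), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(unname(st$T), c(10, 30) * 60)     # seconds
  expect_equal(st$n_visits - st$n_days, sum(st$n))
})

test_that("sufficient statistics are additive over days and ignore sub-2-visit days", {
  v <- toy_ab_visits()
  v2 <- rbind(v, transform(v, day_index = 2, time = time + 86400))
  st1 <- sufficient_stats(v)
  st2 <- sufficient_stats(v2)
  expect_equal(st2$n, st1$n * 2L)
  expect_equal(st2$T, st1$T * 2)

  singles <- data.frame(day_index = c(1, 2), carer_id = c("A", "B"),
                        time = c(0, 86400))
  st <- sufficient_stats(singles)
  expect_true(all(st$n == 0))
  expect_true(all(st$T == 0))
})

test_that("closed-form MLEs and log-likelihood match the hand-worked values", {
  st <- sufficient_stats(toy_ab_visits())
  full <- fit_ctmc(st, "full", time_unit = "minute")
  expect_equal(full$rates["A", "B"], 0.1)
  expect_equal(full$rates["B", "B"], 1 / 30)
  expect_equal(full$rates["B", "A"], 1 / 30)
  expect_equal(full$rates["A", "A"], 0)
  # ln 0.1 - 10*0.1 + 2*(ln(1/30) - 15*(2/30))
  expect_equal(full$logLik, log(0.1) - 1 + 2 * (log(1 / 30) - 1),
               tolerance = 1e-10)
  expect_equal(round(full$logLik, 4), -12.1050)

  pi <- fit_ctmc(st, "per_individual", time_unit = "minute")
  expect_equal(unname(pi$mu), c(0, 1 / 30))
  expect_equal(unname(pi$lambda), c(1 / 30, 0.1))

  po <- fit_ctmc(st, "pooled", time_unit = "minute")
  expect_equal(po$lambda0, 2 / 40)
  expect_equal(po$mu0, 1 / 40)

  tr <- turn_taking_ratio(pi)
  expect_equal(tr$group_ratio, 4)
  expect_true(any(grepl("infinite", tr$flags)))  # mu_A = 0
})

test_that("the log-likelihood honours its support conventions", {
  st <- list(n = matrix(0L, 2, 2), T = c(0, 0))
  expect_equal(ctmc_loglik(matrix(2, 2, 2), st), 0)   # empty data

  st2 <- list(n = matrix(c(1L, 0L, 0L, 0L), 2, 2), T = c(1, 0))
  q <- matrix(0, 2, 2)
  expect_equal(ctmc_loglik(q, st2), -Inf)             # count with zero rate
})

test_that("a rate matrix constructed as n = k * T is recovered exactly", {
  Texp <- c(A = 7200, B = 10800)
  k <- 3 / 3600   # per second
  n <- matrix(round(k * rep(Texp, 2)), 2, 2,
              dimnames = list(names(Texp), names(Texp)))
  st <- structure(list(carers = names(Texp), n = n, T = Texp,
                       n_days = 1L, n_visits = sum(n) + 1L,
                       time_unit = "second"), class = "visit_suffstats")
  f <- fit_ctmc(st, "full", "second")
  expect_equal(f$rates, n / rep(Texp, 2), tolerance = 1e-12)
})

test_that("log-likelihood ordering of nested models holds on simulated data", {
  for (seed in 1:8) {
    C <- sample(2:5, 1)
    Q <- matrix(stats::runif(C * C, 2, 20), C, C)
    att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 1,
                                            day_length = 4 * 3600,
                                            seed = seed))
    st <- sufficient_stats(att)
    ll <- vapply(c("full", "per_individual", "pooled"),
                 function(m) fit_ctmc(st, m)$logLik, 0)
    expect_true(ll["full"] >= ll["per_individual"] - 1e-8)
    expect_true(ll["per_individual"] >= ll["pooled"] - 1e-8)
  }
})

test_that("numerical maximization agrees with the closed forms", {
  set.seed(99)
  for (rep in 1:6) {
    C <- sample(c(2L, 3L, 4L), 1)
    Q <- matrix(stats::runif(C * C, 5, 25), C, C)
    att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 1,
                                            day_length = 8 * 3600,
                                            seed = 100 + rep))
    st <- sufficient_stats(att)
    for (model in c("full", "per_individual", "pooled")) {
      cf <- fit_ctmc(st, model, "second")
      num <- numeric_mle(st, model)
      keep <- num$estimable & cf$rates > 0
      expect_lt(max(abs(num$rates[keep] - cf$rates[keep]) / cf$rates[keep]),
                1e-6)
    }
  }
})

test_that("likelihood-ratio tests report the expected degrees of freedom", {
  Q <- matrix(8, 4, 4)
  att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 1,
                                          day_length = 8 * 3600, seed = 5))
  st <- sufficient_stats(att)
  full <- fit_ctmc(st, "full")
  pi <- fit_ctmc(st, "per_individual")
  po <- fit_ctmc(st, "pooled")
  t1 <- lrt(full, pi)
  expect_equal(t1$df, 16L - 8L)
  t2 <- lrt(pi, po)
  expect_equal(t2$df, 8L - 2L)
  expect_gte(t1$stat, 0)
  expect_error(lrt(po, full), "nested")
})

test_that("rescaling time rescales rates and leaves LRT statistics invariant", {
  st <- sufficient_stats(toy_ab_visits())
  f_h <- fit_ctmc(st, "full", "hour")
  f_m <- fit_ctmc(st, "full", "minute")
  expect_equal(f_h$rates, f_m$rates * 60, tolerance = 1e-12)

  lrt_h <- lrt(fit_ctmc(st, "per_individual", "hour"),
               fit_ctmc(st, "pooled", "hour"))
  lrt_m <- lrt(fit_ctmc(st, "per_individual", "minute"),
               fit_ctmc(st, "pooled", "minute"))
  expect_equal(lrt_h$stat, lrt_m$stat, tolerance = 1e-9)
  # deterministic Jacobian shift: per-minute rates are 60-fold smaller
  expect_equal(f_m$logLik - f_h$logLik, -sum(st$n) * log(60),
               tolerance = 1e-9)
})

test_that("reciprocity correlation behaves at its edges", {
  q <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)   # exactly symmetric
  r <- reciprocity_correlation(q, n_perm = 199, seed = 1)
  expect_equal(r$rho, 1)

  r2 <- reciprocity_correlation(matrix(1:4 / 10, 2, 2))
  expect_true(is.na(r2$rho))
  expect_match(r2$flag, "fewer than 3")
})

test_that("dummy-state export has 2c states and c(c+1) transitions", {
  for (C in 2:6) {
    s <- export_msm_structure(C)
    expect_equal(s$n_states, 2L * C)
    expect_equal(s$n_visit_transitions, C^2)
    expect_equal(s$n_transitions, C * (C + 1))
    expect_equal(sum(s$transitions$type == "reset"), C)
  }
})

test_that("lambda exceeds mu by Wilcoxon test when simulated with repeat suppression", {
  Q <- matrix(20, 4, 4)
  diag(Q) <- 5
  att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 2,
                                          day_length = 8 * 3600, seed = 21))
  fit <- fit_ctmc(sufficient_stats(att), "per_individual")
  expect_true(all(fit$lambda > fit$mu))
  w <- wilcoxon_lambda_mu(fit)
  expect_lt(w$p.value, 0.15)   # n = 4 pairs: exact floor is 1/8
})
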