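test_that("simulation is deterministic under a seed and varies across seeds", {
  cfg <- sim_config("markov", Q = matrix(10, 3, 3), n_days = 2, seed = 5)
  a <- simulate_provisioning(cfg)
  b <- simulate_provisioning(cfg)
  expect_identical(a$visits, b$visits)
  cfg2 <- sim_config("markov", Q = matrix(10, 3, 3), n_days = 2, seed = 6)
  expect_false(identical(a$visits, simulate_provisioning(cfg2)$visits))
})

test_that("event times are increasing within carer and inside day windows", {
  for (mode_cfg in list(
    sim_config("markov", Q = matrix(15, 2, 2), n_days = 2, seed = 3),
    sim_config("mechanistic", base_rates = c(20, 15),
               refractory = list(type = "gamma", shape = 3, scale = 60),
               n_days = 2, seed = 3),
    sim_config("bouts", base_rates = c(10, 10), bout_rate = 6,
               bout_prob = 0.9, bout_jitter = 20, n_days = 2, seed = 3))) {
    att <- simulate_provisioning(mode_cfg)
    m <- match(att$visits$day_index, att$days$day_index)
    expect_true(all(att$visits$time >= att$days$day_start[m]))
    expect_true(all(att$visits$time < att$days$day_end[m]))
    for (v in split(att$visits, list(att$visits$carer_id,
                                     att$visits$day_index)))
      if (nrow(v) > 1) expect_true(all(diff(v$time) > 0))
  }
})

test_that("markov-mode transition frequencies converge to the generating rates", {
  Q <- matrix(c(10, 20, 16, 6), 2, 2, byrow = TRUE)
  att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 8,
                                          day_length = 12 * 3600, seed = 44))
  st <- sufficient_stats(att)
  expect_gt(st$n_visits, 2000)
  qhat <- st$n / (st$T / 3600)
  # each cell within 3 Monte-Carlo SDs (Poisson: SD ~ q / sqrt(count))
  for (i in 1:2) for (j in 1:2) {
    se <- Q[i, j] / sqrt(st$n[i, j])
    expect_lt(abs(qhat[i, j] - Q[i, j]), 3.5 * se)
  }
})

test_that("equal-rate carers give symmetric repeat proportions near 1/c", {
  for (C in c(2, 4)) {
    att <- simulate_provisioning(sim_config(
      "markov", Q = matrix(12 * 4 / C, C, C), n_days = 3,
      day_length = 12 * 3600, seed = 50 + C))
    p <- proportion_alternated(att)
    repeat_prop <- 1 - p$proportion
    se <- sqrt((1 / C) * (1 - 1 / C) / p$n_pairs)
    expect_lt(abs(repeat_prop - 1 / C), 3.5 * se)
  }
})

test_that("full suppression of repeats forces perfect alternation", {
  att <- simulate_provisioning(sim_config(
    "mechanistic", base_rates = c(20, 20, 20), repeat_suppression = 0,
    n_days = 1, seed = 8))
  expect_equal(proportion_alternated(att)$proportion, 1)
})

test_that("fixed refractory periods floor the individual IVIs", {
  att <- simulate_provisioning(sim_config(
    "mechanistic", base_rates = c(30, 30),
    refractory = list(type = "fixed", d = 300), n_days = 1, seed = 13))
  for (v in split(att$visits$time, att$visits$carer_id))
    expect_true(all(diff(sort(v)) >= 300))
})

test_that("mechanistic mode without refractory or response reduces to markov", {
  # carer j visits at constant hazard base_j regardless of state, which is
  # the markov model with q[i, j] = base_j for every i
  base <- c(18, 12)
  att_m <- simulate_provisioning(sim_config(
    "mechanistic", base_rates = base, n_days = 4, day_length = 12 * 3600,
    seed = 61))
  att_q <- simulate_provisioning(sim_config(
    "markov", Q = rbind(base, base), n_days = 4, day_length = 12 * 3600,
    seed = 62))
  p_m <- proportion_alternated(att_m)
  p_q <- proportion_alternated(att_q)
  se <- sqrt(0.25 / p_m$n_pairs + 0.25 / p_q$n_pairs)
  expect_lt(abs(p_m$proportion - p_q$proportion), 4 * se)
  # fitted per-carer rates agree across the two routes
  f_m <- fit_ctmc(sufficient_stats(att_m), "per_individual")
  f_q <- fit_ctmc(sufficient_stats(att_q), "per_individual")
  expect_lt(max(abs(f_m$lambda - f_q$lambda) / f_q$lambda), 0.2)
})

test_that("bout mode produces clustered group IVIs; degenerate configs are flagged", {
  set.seed(71)
  small_p <- 0
  n_days <- 30
  for (k in seq_len(n_days)) {
    att <- simulate_provisioning(sim_config(
      "bouts", base_rates = c(10, 10, 10), bout_rate = 4, bout_prob = 0.95,
      bout_jitter = 10, n_days = 1, day_length = 6 * 3600, seed = 700 + k))
    g <- unlist(lapply(split(att$visits$time, att$visits$day_index),
                       function(t) diff(sort(t))))
    if (length(g) >= 10 && ww_bout_test(g)$p <= 0.05) small_p <- small_p + 1
  }
  expect_gt(small_p / n_days, 0.5)   # strong clustering detected mostly

  empty <- simulate_provisioning(sim_config(
    "bouts", base_rates = c(0, 0), bout_rate = 0, n_days = 1, seed = 1))
  expect_true(isTRUE(attr(empty, "empty")))
  expect_equal(nrow(empty$visits), 0L)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config("markov", Q = matrix(-1, 2, 2)))
  expect_error(sim_config("mechanistic", base_rates = c(10, 10),
                          repeat_suppression = 1.5))
  expect_error(sim_config("mechanistic", base_rates = c(10, 10),
                          refractory = list(type = "fixed", d = -5)))
})
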