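test_that("alternation proportions match hand counts", {
  expect_equal(proportion_alternated(c("A", "B", "B", "A"))$proportion, 2 / 3)
  expect_equal(proportion_alternated(c("A", "B", "A", "B"))$proportion, 1)
  expect_equal(proportion_alternated(c("A", "A", "A"))$proportion, 0)
  # pairs never cross a day boundary
  two_days <- list(c("A", "A"), c("B", "B"))
  expect_equal(proportion_alternated(two_days)$proportion, 0)
  undef <- proportion_alternated(list("A", "B"))
  expect_true(is.na(undef$proportion))
  expect_match(undef$flag, "fewer than 2")
})

test_that("alternation proportion agrees with the transition-count identity", {
  att <- toy_markov_attempt(C = 3, rate = 12, n_days = 2, seed = 3)
  st <- sufficient_stats(att)
  p1 <- proportion_alternated(att)$proportion
  expect_equal(p1, 1 - sum(diag(st$n)) / sum(st$n))
})

test_that("k-category runs moments match exhaustive enumeration (spot checks)", {
  # {A:2, B:2}: 6 equally likely arrangements with runs (2,4,3,3,4,2)
  r <- enum_runs(c(2, 2))
  expect_equal(sort(r), c(2, 2, 3, 3, 4, 4))
  tst <- k_category_runs_test(c("A", "A", "B", "B"))
  expect_equal(tst$E_R, 3)
  expect_equal(tst$E_R, mean(r))
  expect_equal(tst$Var_R, mean(r^2) - mean(r)^2, tolerance = 1e-12)

  for (counts in list(c(3, 2), c(2, 2, 2), c(4, 3), c(1, 2, 3))) {
    r <- enum_runs(counts)
    seqv <- rep(LETTERS[seq_along(counts)], counts)
    tst <- k_category_runs_test(seqv)
    expect_equal(tst$E_R, mean(r), tolerance = 1e-12)
    expect_equal(tst$Var_R, stats::var(r) * (length(r) - 1) / length(r),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo runs p-values match enumeration and handle degeneracy", {
  # AABB observed: R = 2; all 6 arrangements have R >= 2, so p(more) ~ 1
  tst <- k_category_runs_test(c("A", "A", "B", "B"), method = "monte_carlo",
                              n_mc = 2000, seed = 8)
  expect_equal(tst$R_obs, 2L)
  expect_gt(tst$p, 0.9)
  # fewer-runs direction: exact p = 2/6
  tst2 <- k_category_runs_test(c("A", "A", "B", "B"),
                               alternative = "fewer_runs",
                               method = "monte_carlo", n_mc = 3000, seed = 8)
  expect_equal(tst2$p, 1 / 3, tolerance = 0.04)

  deg <- k_category_runs_test(c("A", "A", "A"))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  expect_error(k_category_runs_test(c("A", "B"), method = "monte_carlo",
                                    n_mc = 50), "n_mc")
})

test_that("normal and Monte-Carlo runs p-values agree on long sequences", {
  set.seed(14)
  for (k in 1:4) {
    seqv <- sample(c("A", "B", "C"), 120, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    pn <- k_category_runs_test(seqv, method = "normal_approx")$p
    pm <- k_category_runs_test(seqv, method = "monte_carlo", n_mc = 2000,
                               seed = k)$p
    expect_lt(abs(pn - pm), 0.05)
  }
})

test_that("Wald-Wolfowitz bout test follows the two-category formulas", {
  # S,S,L,L: n1 = n2 = 2, E[R] = 2*2*2/4 + 1 = 3, R = 2
  tst <- ww_bout_test(c(1, 2, 10, 11), threshold = 5)
  expect_equal(tst$E_R, 3)
  expect_equal(tst$R_obs, 2L)
  expect_equal(tst$Var_R, 2 * 2 * 2 * (2 * 2 * 2 - 4) / (16 * 3))

  # perfectly interleaved short/long: many runs, fewer-runs p large
  tst2 <- ww_bout_test(c(1, 10, 2, 11, 3, 12), threshold = 5)
  expect_equal(tst2$R_obs, 6L)
  expect_gt(tst2$p, 0.5)

  deg <- ww_bout_test(rep(7, 6))     # all equal: everything "short"
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  expect_error(ww_bout_test(c(1, 2, 3)), "at least 4")
})

test_that("bout test false-positive rate is near alpha for memoryless group IVIs", {
  set.seed(31)
  n_days <- 300
  rej <- 0L
  for (k in seq_len(n_days)) {
    ivis <- stats::rexp(30, 1 / 120)
    if (ww_bout_test(ivis)$p <= 0.05) rej <- rej + 1L
  }
  rate <- rej / n_days
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_days))
})

test_that("IVI summaries use within-day intervals and the 1-hour fraction", {
  att <- provisioning_attempt(
    data.frame(day_index = c(1, 1, 1, 2, 2),
               carer_id = c("A", "A", "A", "A", "B"),
               time = c(0, 600, 1800, 86400, 86500)),
    data.frame(day_index = 1:2, day_start = c(0, 86400),
               day_end = c(43200, 129600)))
  s <- ivi_summaries(att)
  a <- s$per_carer[s$per_carer$carer_id == "A", ]
  expect_equal(a$n_ivi, 2L)                 # 600 s and 1200 s; no cross-day IVI
  expect_equal(a$median_s, 900)
  expect_equal(a$frac_under_1h, 1)
  b <- s$per_carer[s$per_carer$carer_id == "B", ]
  expect_equal(b$n_ivi, 0L)
  expect_true("B" %in% s$flagged_carers)
  # group IVIs: day 1 diffs 600, 1200; day 2 diff 100
  expect_equal(s$group_median_s, 600)
})

test_that("ordering diagnostic flags trends and passes exchangeable IVIs", {
  mk_att <- function(ivis) {
    t <- cumsum(c(100, ivis))
    provisioning_attempt(
      data.frame(day_index = 1, carer_id = "A", time = t),
      data.frame(day_index = 1, day_start = 0, day_end = max(t) + 1))
  }
  inc <- ordering_score(mk_att(1:10 * 10), n_perm = 999, seed = 2)
  expect_lte(inc$per_carer$p_score, 0.01)

  const <- ordering_score(mk_att(rep(60, 8)), n_perm = 199, seed = 2)
  expect_equal(const$per_carer$p_score, 1)
  expect_match(const$per_carer$flag, "constant")

  few <- ordering_score(mk_att(c(10, 20)), n_perm = 199, seed = 2)
  expect_match(few$per_carer$flag, "too few")

  # i.i.d. intervals: p scores roughly uniform, mean near 0.5
  set.seed(77)
  ps <- replicate(40, {
    ordering_score(mk_att(stats::rexp(20, 1 / 300)), n_perm = 199)$mean_p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})
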