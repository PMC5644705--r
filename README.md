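# turntaking

Tools to quantify **turn-taking** in cooperative offspring provisioning from
timestamped nest-visit records.

## The science

In many cooperatively breeding birds a brood is provisioned by several
carers — the breeding pair plus non-breeding helpers. A long-standing
question is whether carers *coordinate*: does a carer preferentially visit
after somebody else has visited, rather than simply returning at its own
pace? Observed visit sequences often alternate far more than chance would
suggest, but elevated alternation on its own is ambiguous. It arises
*passively* from group size, unequal visit rates, and refractory periods
(travel and foraging time impose a minimum gap between one carer's
successive visits), and only sometimes *actively*, from carers genuinely
responding to one another.

This package implements the full analysis chain for separating those
explanations:

1. **Ingest** — collapse raw PIT-tag (RFID) reads into discrete visits
   using a 2-minute chained gap window; parse timestamps; segment
   observation days; filter by brood age and disturbance windows
   (`read_visit_table()`, `collapse_reads()`, `apply_filters()`).
2. **Carer classification** — retain "significant" carers by the iterative
   rule that excludes any carer whose visit count is at most 20% of the
   mean of the others' (`classify_significant()`, `validate_for_fitting()`).
3. **Markov modelling** — treat the identity of the last visitor as the
   state of a continuous-time Markov chain observed at exact transition
   times, and fit three nested rate structures by closed-form maximum
   likelihood: `full` (every who-follows-whom rate free), `per_individual`
   (each carer has one following rate λᵢ and one repeat rate μᵢ), and
   `pooled` (a single λ₀ and μ₀ for everyone). Likelihood-ratio tests
   compare them, and the ratio λ/μ > 1 quantifies turn-taking
   (`fit_ctmc()`, `lrt()`, `turn_taking_ratio()`).
4. **Sequence statistics** — the proportion of alternated visit pairs, a
   k-category runs test for alternation, and a Wald–Wolfowitz runs test on
   group inter-visit intervals for bout-like clustering
   (`proportion_alternated()`, `k_category_runs_test()`, `ww_bout_test()`).
5. **Randomization (dissociation) test** — shuffle each carer's
   inter-visit intervals within each day, preserving its visit count, IVI
   multiset and first/last visit times, and rebuild the group sequence.
   This null keeps every *individual* pattern (including refractory
   periods) while destroying *responses between carers*; an observed
   statistic in the right tail of the null indicates **active**
   turn-taking, while a null distribution entirely above the memoryless
   reference flags **passive** turn-taking (`randomization_test()`).
6. **Simulator** — generative models (fitted-Markov, mechanistic with
   refractory periods and repeat-suppression, and synchronous bouts over a
   background stream) for power and calibration studies
   (`sim_config()`, `simulate_provisioning()`).
7. **Pipeline** — one call per breeding attempt, batch aggregation, and
   JSON reports (`run_attempt()`, `run_batch()`, `report_json()`).

## Worked example: the two-carer toy

Visits A at 0, B at 10, B at 25, A at 40 minutes. The sufficient statistics
are the transition counts and the time spent with each carer as "last
visitor":

```r
library(turntaking)
v <- data.frame(day_index = 1, carer_id = c("A", "B", "B", "A"),
                time = c(0, 10, 25, 40) * 60)   # seconds
st <- sufficient_stats(v)
st$n
#>   A B
#> A 0 1
#> B 1 1
st$T
#>    A    B
#>  600 1800
```

A spends 10 minutes as last visitor, B 30 minutes. The full-model MLEs are
`q̂ij = n_ij / T_i`:

```r
fit_ctmc(st, "full", time_unit = "minute")
#> Visit CTMC fit (full model): 2 carers, 4 parameters
#> logLik = -12.1050 (rates per minute)
#>        A      B
#> A 0.0000 0.1000
#> B 0.0333 0.0333
```

By hand: `log(0.1) - 1 + 2*(log(1/30) - 1) = -12.1050`. The pooled model
gives `λ̂₀ = 2/40 = 0.05` and `μ̂₀ = 1/40 = 0.025` per minute, and the
per-individual group ratio `mean(λ̂)/mean(μ̂) = 4`.

## A full attempt analysis

```r
Q <- matrix(c(5, 16, 12,
              14, 4, 15,
              13, 12, 6), 3, 3, byrow = TRUE)   # events per hour
att <- simulate_provisioning(sim_config("markov", Q = Q, n_days = 2,
                                        day_length = 8 * 3600, seed = 42))
run_attempt(att, n_reps = 1000, seed = 9)
#> == Turn-taking report: sim ==
#> significant carers: 3 (excluded: 0)
#> alternation proportion: 0.853 (412 of 483 pairs)
#> k-category runs test: R = 414, E[R] = 323.3, p = 6.93e-19
#> model comparison:
#>           model n_params logLik  stat df      p
#>          pooled        2  682.5    NA NA     NA
#>  per_individual        6  685.6 6.235  4 0.1822
#>            full        9  688.4 5.607  3 0.1324
#> group lambda/mu ratio: 2.923 (Wilcoxon lambda vs mu p = 0.25)
#> randomization [proportion_alternated]: observed 0.853, p_active = 0.000999, passive_flag = TRUE
#> randomization [group_lambda_mu_ratio]: observed 2.923, p_active = 0.000999, passive_flag = TRUE
#> bout test (first day): R = 135, E[R] = 128.5, p = 0.793
```

The generating rates really do make carers respond to one another
(following rates 12–16/h versus repeat rates 4–6/h), and the randomization
test detects it: the observed alternation (0.853) exceeds all 1000 shuffled
nulls (`p_active = 1/1001`). The `passive_flag` notes that even the
shuffled nulls alternate above the memoryless reference — group size alone
produces substantial alternation, which is exactly why the randomization
null (and not 0.5 or `(c-1)/c`) is the right yardstick for "active"
turn-taking.

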