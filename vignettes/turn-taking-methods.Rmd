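---
title: "Turn-taking in cooperative provisioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-taking in cooperative provisioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turntaking)
```

## 1. The scientific question

When several carers provision one brood, their visit sequence often
alternates strikingly: a carer tends to visit after *someone else* rather
than repeat. Alternation alone does not demonstrate coordination. Three
passive mechanisms inflate it:

* **group size** — with $c$ equally active, mutually indifferent carers the
  expected proportion of alternated consecutive pairs is $(c-1)/c$ (0.5 for
  a pair, 0.8 for five);
* **rate inequality** — unequal rates reduce it below that, but in a fully
  predictable way;
* **refractory periods** — travel and foraging impose a minimum gap between
  one carer's successive visits, so immediately repeating is physically
  disfavoured even without any social response.

The package therefore answers two separate questions: *how strong is
turn-taking* (the Markov model and sequence statistics), and *is any of it
active*, i.e. attributable to carers responding to one another (the IVI
randomization test)?

## 2. Data model

A **breeding attempt** holds visits `(day_index, carer_id, time)` with
times in absolute seconds, observation days as half-open windows
`[day_start, day_end)`, and optional metadata (brood ages, carer classes).
Upstream of that:

* raw PIT-tag reads are collapsed into visits with a **2-minute chained gap
  window** (`collapse_reads()`): a read starts a new visit only if more
  than 120 s separate it from the previous read *by the same carer*; the
  visit is stamped with its first read. Chaining (rather than a fixed
  window from the first read) matches how a bird lingering at the nest
  produces a read train.
* filtering (`apply_filters()`) removes days with brood age ≤ 10 days
  (provisioning style changes with nestling age), fledge days, and
  user-specified disturbance windows. All removals are recorded in a
  `filter_report`.

**Significant carers** are selected by the iterative rule: repeatedly
exclude the lowest-count carer whose visit count is at most
`threshold_frac` (default 0.2) times the mean count of all *other* retained
carers, one per round (`classify_significant()`). Model fitting
additionally requires every retained carer to have strictly more than 10
visits (`validate_for_fitting()`).

## 3. The continuous-time Markov model

The state is the identity of the last visitor. Each visit by carer $j$
while the state is $i$ is a transition $i \to j$ (a repeat when $j = i$),
observed at its exact time. With transition counts $n_{ij}$ and exposure
times $T_i$ (total time spent in state $i$, accumulated within days only),
the log-likelihood of rate matrix $Q = (q_{ij})$ is

$$\ell(Q) = \sum_{i,j} n_{ij}\log q_{ij} - \sum_i T_i \sum_j q_{ij},$$

with the conventions $0\log 0 = 0$ and $\ell = -\infty$ if some $n_{ij}>0$
has $q_{ij}=0$. Three nested structures are fitted in closed form:

| model | parameters | MLE |
|---|---|---|
| `full` | $c^2$ | $\hat q_{ij} = n_{ij}/T_i$ |
| `per_individual` | $2c$: $\lambda_j$ (following), $\mu_j$ (repeat) | $\hat\mu_j = n_{jj}/T_j$, $\hat\lambda_j = \sum_{i\ne j} n_{ij} \big/ \sum_{i\ne j} T_i$ |
| `pooled` | 2: $\lambda_0, \mu_0$ | $\hat\lambda_0 = \sum_{i\ne j} n_{ij} / \big((c-1)\sum_i T_i\big)$, $\hat\mu_0 = \sum_i n_{ii} / \sum_i T_i$ |

Because transitions are exactly observed, these are genuine MLEs (each rate
is a Poisson-count-over-exposure estimator on its pooled cells); the
acceptance suite verifies them against an independent quasi-Newton
optimization of $\ell$ to $10^{-6}$ relative. Nested models are compared by
likelihood-ratio tests with $\chi^2$ degrees of freedom equal to the
parameter-count difference (`lrt()`, `anova()` on fits). Rates sitting at
the zero boundary are flagged, since the $\chi^2$ reference is then
approximate.

Turn-taking is quantified by $\lambda/\mu$: per carer, and at group level
as $\operatorname{mean}(\hat\lambda_i)/\operatorname{mean}(\hat\mu_i)$,
with a Wilcoxon signed-rank test of $\lambda_i$ versus $\mu_i$ across
carers. `export_msm_structure()` emits the equivalent multi-state layout
with one dummy state per carer (so that repeats become observable
transitions), $2c$ states and $c(c+1)$ transitions, for cross-checking in
general-purpose multi-state software.

**Censoring.** The likelihood omits the censored final sojourn of each day
(time from the last visit to `day_end` contributes exposure only up to the
last transition; we accumulate $T_i$ between visits, not to day end).
Adding the censored term $-T^{\mathrm{cens}}_i \sum_j q_{ij}$ would be a
one-line change; it is excluded so that the sufficient statistics match the
hand-worked toy example exactly and because with hundreds of visits per day
the effect is negligible.

## 4. Sequence statistics

* `proportion_alternated()`: fraction of consecutive within-day visit pairs
  with different visitors.
* `k_category_runs_test()`: for category counts $n_1..n_k$, $N = \sum n_i$,
  $S_r=\sum n_i^r$,
  $E[R] = (N(N+1)-S_2)/N$ and
  $\mathrm{Var}[R] = (S_2(S_2+N(N+1))-2NS_3-N^3)/(N^2(N-1))$.
  Multi-day records are handled additively (runs never cross a day
  boundary) and a Monte-Carlo permutation method is available as the
  reference. The moments and the whole null distribution are tested against
  exhaustive enumeration of all arrangements for $N \le 8$.
* `ww_bout_test()`: group IVIs are dichotomized at the median (ties short)
  and the two-category Wald–Wolfowitz runs test applied, one-sided for
  *fewer* runs (clustered short intervals = provisioning bouts).

## 5. The randomization (dissociation) test

`randomization_test()` builds the passive-only null: within each carer-day,
the first visit time is kept and the remaining visits are rebuilt from a
random permutation of that carer-day's IVIs; carers are then merged, with
exact time ties broken uniformly at random. Each pseudo-day preserves, per
carer: visit count, IVI multiset, and first and last visit times — hence
individual rates, refractory signatures (the minimum IVI is invariant) and
day structure — while destroying any dependence *between* carers.

With observed statistic $s$ and null draws $s^{(1)}..s^{(B)}$,

$$p_{\text{active}} = \frac{\#\{s^{(b)} \ge s\} + 1}{B + 1},$$

the standard add-one permutation estimator (never exactly zero, ties count
against rejection). Two statistics are computed by default: the alternation
proportion and the group $\lambda/\mu$ ratio. The **passive flag** is set
when even the *smallest* null value exceeds the memoryless reference (1 for
the ratio; $1-\sum_i p_i^2$ with $p_i$ the carers' visit shares for
alternation): alternation is then elevated for structural reasons
regardless of any response.

Two caveats are built in. First, if a statistic is undefined in more than
5% of replicates (e.g. a carer never repeats in a shuffle, making the
ratio infinite), pooled-substitute values are used and the result is
flagged. Second, shuffling assumes IVIs are exchangeable within a
carer-day; `ordering_score()` checks this beforehand via the permutation
distribution of the Spearman correlation between IVI and temporal position,
and the pipeline warns when the diagnostic is extreme (a strong diurnal
trend would bias the null).

For independent renewal-type carers the test is exact by exchangeability;
the calibration tests confirm a uniform $p_{\text{active}}$ distribution
for memoryless carers and a rejection rate at the nominal level under
refractory-only simulation (passive structure but no response). A slight
conservatism is expected and observed when the alternation statistic is
extremely discrete (ties between null and observed values count toward
$p$).

## 6. The simulator

`simulate_provisioning()` draws multi-day attempts under three modes:

* **markov** — the fitted model run generatively: competing exponential
  clocks with rates $Q[i,\cdot]$ given last visitor $i$; the first visitor
  of a day is drawn proportionally to column means of $Q$. This is the
  ground truth for parameter-recovery and LRT-calibration studies.
* **mechanistic** — each carer is an event stream with base hazard
  $b_i$, silenced during a refractory window after its own visit (none,
  fixed $d$, or gamma-distributed), and multiplied by
  `repeat_suppression` $\beta \in [0,1]$ while the carer is the last
  visitor. $\beta = 1$ generates *passive-only* turn-taking (refractory
  structure, no response); $\beta < 1$ adds an *active* response of
  tunable strength. Simulation is event-driven with piecewise-constant
  hazards: the next candidate event is drawn at the current total hazard
  and re-drawn at each hazard change point (refractory expiries), which is
  exact for piecewise-exponential processes.
* **bouts** — synchronous group provisioning: bout start times are Poisson,
  each carer joins a bout with probability `bout_prob`, and participants
  queue with small i.i.d. exponential spacings, *superimposed on a
  background Poisson stream per carer at its base rate*. The background is
  not cosmetic: in a pure-bout stream every inter-bout interval is a
  single gap, so long group IVIs can never be adjacent and a fewer-runs
  clustering signal is impossible in principle (for bouts of fixed size
  $k$ the short/long pattern is $(k-1)$ shorts then one long, giving
  *more* runs than chance for every $k$). Sparse individual visits between
  bouts are what allow long intervals to form runs, and they are also the
  realistic regime: bout-like coordination, if present, happens on top of
  ordinary provisioning rather than instead of it.

All modes are deterministic given `config$seed`, using a seed-forking
scheme (`fork_seeds()`) that gives every randomized pipeline stage its own
substream, so changing the replicate count of one stage never perturbs
another.

## 7. Numerical choices

* Internal times are in seconds; fitted rates are reported per hour, minute
  or second. Rescaling time multiplies rates by the scale and shifts the
  log-likelihood by $-(\sum n_{ij})\log s$ (the Jacobian), leaving LRT
  statistics invariant; this equivariance is tested.
* Closed-form estimators are used everywhere (no optimization at runtime);
  the numerical optimizer exists only as an independent oracle in the test
  suite.
* LRT statistics in $[-10^{-8}, 0)$ are clamped to zero (floating-point
  noise on the closed forms); genuinely negative values raise an error
  since they indicate a nesting violation.
* Monte-Carlo p-values use the add-one estimator throughout, so reported
  significance is never an artifact of too few replicates.
* Exact time ties (possible in shuffled pseudo-data) are broken uniformly
  at random, not by carer order, to avoid a deterministic bias in the
  null.

## 8. Scope and limitations

* Rates are assumed constant within a day (no diurnal modulation); the
  ordering diagnostic partially guards the randomization test against
  violations, but the Markov fits would average over any trend.
* The model conditions on visit identity sequences and timing; it does not
  model load size, prey type, or brood demand.
* The per-day censored final sojourn is omitted from the likelihood (see
  §3).
* The Wilcoxon comparison of $\lambda_i$ vs $\mu_i$ treats carers within an
  attempt as independent pairs, which ignores their interaction — it is a
  descriptive companion to the LRT, not a substitute.
* The bout test dichotomizes at the median by default; thresholds far into
  a tail lose power, and a single day with fewer than four group IVIs is
  not testable.

## 9. Worked example

```r
v <- data.frame(day_index = 1, carer_id = c("A", "B", "B", "A"),
                time = c(0, 10, 25, 40) * 60)
st <- sufficient_stats(v)
fit_ctmc(st, "full", time_unit = "minute")
#> Visit CTMC fit (full model): 2 carers, 4 parameters
#> logLik = -12.1050 (rates per minute)
#>        A      B
#> A 0.0000 0.1000
#> B 0.0333 0.0333
```

Counts $n_{AB} = n_{BB} = n_{BA} = 1$ with exposures $T_A = 10$,
$T_B = 30$ minutes give $\hat q_{AB} = 1/10$, $\hat q_{BB} = \hat q_{BA} =
1/30$, and
$\ell = \log 0.1 - 1 + 2(\log\tfrac1{30} - 1) = -12.1050$.
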