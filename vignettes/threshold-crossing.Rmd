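---
title: "Threshold-crossing designs: models, rules, and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-crossing designs: models, rules, and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshtrial)
library(dplyr)
```

## The design problem

A threshold-crossing trial replaces the concurrent control arm of a
randomized trial with an efficacy threshold `t` derived from historical
control data (past trial control arms, registries, real-world cohorts). All
prospective patients receive the experimental treatment; efficacy is claimed
when the single-arm result crosses `t` by a one-sided test. The appeal is
economic and ethical — in the best case the trial needs a quarter of the
patients of a parallel-group design — but the control estimate is now a
*sample* quantity from another era, and both its sampling error and any
systematic drift of the control condition propagate into the error rates of
the prospective trial. This package exists to quantify exactly that
trade-off.

Everything is built on one probability model: a normally distributed
endpoint with known standard deviation `sigma`, historical control mean
`mu_C`, and experimental mean `mu_N`. The planning quantities live in
`design_params()`:

* `delta` — the standardized effect `(mu_N - mu_C)/sigma` the program is
  powered to detect (dimensionless; default 0.2, a small effect by Cohen's
  convention and the reference value used throughout),
* `sigma` — the planning standard deviation (endpoint units; default 1, so
  endpoint units and standardized units coincide),
* `alpha` — the one-sided significance level (default 0.025),
* `power` — the target power (default 0.8).

All tests are known-variance z-tests using the planning `sigma`. With
hundreds of patients per arm the Student-t correction is far below every
other source of error in this problem (the historical sampling error alone
is an order of magnitude larger), and the known-variance form admits the
exact closed-form oracle below, which is what makes the Monte Carlo engine
verifiable.

## Sample sizes and threshold rules

The two closed-form sizes are the standard normal-theory ones:

* parallel-group, per group: `ceiling(2 (z_{1-alpha} + z_{power})^2 / delta^2)`
  — 393 at the defaults (`parallel_group_size()`);
* single-arm against a fixed threshold at standardized distance
  `delta_eff`: `ceiling((z_{1-alpha} + z_{power})^2 / delta_eff^2)` — 197
  when the threshold sits at the true control mean (`single_arm_size()`).

Sizes always round by `ceiling()`; the "about 400 / about 200 / about 800"
style of reporting is a separate presentation helper, `round_hundred()`,
and never feeds back into the planning math.

`threshold_rule()` encodes the three ways `t` is placed above the
historical estimate:

| rule | threshold | rationale |
|---|---|---|
| `naive_mean` | observed historical mean | no allowance for sampling error |
| `ci_upper` | mean + `z_{(1+gamma)/2} sigma / sqrt(n_h)` | covers the estimate's sampling error |
| `ci_upper_plus` | the above + `c * delta * sigma` | additionally guards against drift |

`gamma` defaults to 0.95 and `c` to one of 0.1/0.2/0.3 in the canonical
grids (`default_threshold_rules()`). The CI half-width deliberately uses the
planning `sigma`, not the cohort's observed standard deviation: the
threshold is part of the pre-agreed analysis plan and should be a
deterministic function of the historical summaries under the planning
model. `compute_threshold(use_observed_sd = TRUE)` exposes the
observed-sd variant for sensitivity analyses.

A CI-based threshold eats into the assumed effect: the planning size
`planned_trial_size()` uses the *known* half-width,
`delta_eff = delta - z_{(1+gamma)/2}/sqrt(n_h) - c * delta`, so the size is
a deterministic function of `(rule, n_h)`, non-increasing in `n_h`, and not
re-derived from each simulated historical draw. We extend the half-width
adjustment to the inflated rules by also subtracting `c * delta`, which is
the same "account for the higher threshold" logic applied to the extra
margin. When `delta_eff <= 0` the rule has consumed the whole assumed
effect and the design is infeasible; this raises a typed condition
(`threshtrial_infeasible_error`) rather than returning an infinite size, so
scenario grids can record the cell as infeasible and move on. At the
defaults this happens for `ci_upper` whenever `n_h <= 96`.

```{r sizes}
p <- design_params()
c(two_arm_per_group = parallel_group_size(p),
  single_arm_best_case = single_arm_size(p$delta),
  single_arm_ci_1000 = planned_trial_size("ci", 1000, p))
```

## The exact oracle

Marginally over the historical sampling distribution, the one-sample test
statistic is normal, so the probability that the design rejects has a
closed form. With threshold offset `o` in sigma units (0, the CI
half-width, or half-width plus `c * delta`), true standardized effect
`true_delta` over the concurrent control, and control-mean drift `drift`
(endpoint units) between the historical and concurrent eras:

\[
P(\text{reject}) \;=\; 1 - \Phi\!\left(
  \frac{o\sigma + z_{1-\alpha}\sigma/\sqrt{n} - \Delta_{true}\sigma - \text{drift}}
       {\sigma\sqrt{1/n + 1/n_h}}\right).
\]

`rejection_probability()` implements this. `true_delta = 0` gives the
type-I error, `true_delta = delta` the power. Three consequences worth
knowing:

* the naive rule is anti-conservative: at `n_h = 100`, `n = 197` its
  type-I error is 0.128, five times nominal, shrinking to `alpha` only as
  `n_h` grows;
* the CI rule controls the level without drift, provably so when the CI
  level matches the test level (the offset-plus-critical-value numerator
  always exceeds `z` times the denominator);
* drift shifts the numerator one-for-one, so any rule is eventually
  inflated; the `c * delta` margin buys protection against drift up to
  roughly that size, which is why the inflated rules control the level in
  drift scenarios the plain CI rule fails.

## The Monte Carlo engine

`estimate_oc()` estimates one scenario cell by seeded simulation: draw the
historical mean, apply the rule, draw the trial of the planned size at
`mu_hist + drift + true_delta * sigma`, test, tally. Two engineering
choices matter:

* **Sufficient-statistic simulation.** The z-test depends on the data only
  through the sample means, so the engine draws each replicate's means
  directly from their exact sampling distributions
  `N(mu, sigma^2/n)` rather than averaging `n` patient-level draws. This is
  distributionally identical, not an approximation, and makes a
  100,000-replicate cell essentially free. The patient-level generators
  `simulate_historical_cohort()` and `simulate_trial()` are the user-facing
  fixtures for I/O and pooling work and do draw individual outcomes.
* **Descriptor-hashed sub-streams.** Each cell seeds its own RNG stream via
  `cell_seed(root, descriptors...)` — a base-31 string hash of the scenario
  descriptors modulo `2^31 - 1`, added to the root seed. A cell's result
  therefore never depends on which other cells run, and grids reproduce
  byte-identically from `(config, seed)`.

Every cell carries its binomial standard error and the oracle value; the
test suite holds the engine to within four standard errors of the oracle
across rules, historical sizes, effects, and drifts. `oc_grid()` crosses
rules with an `n_h` axis, drift and effect values — the full
operating-characteristic surface of the design family — and appends
two-arm reference rows (`two_arm_oc()`), which are flat in `n_h` by
construction since a concurrent control owes nothing to history. Default
replication is 100,000 for null cells (Monte Carlo standard error about
0.0005 near a 2.5% rate) and 10,000 for power cells, where a 0.4% error is
ample. Because the problem is location invariant (an identical sub-stream
shifted by `mu_hist` produces identical rejections — asserted in the
tests), the historical mean defaults to 0 without loss of generality.

```{r grid}
oc <- oc_grid(p, n_h = c(100, 250, 500, 1000),
              n_reps_null = 20000, n_reps_power = 5000, seed = 1)
oc |>
  filter(true_delta == 0, feasible) |>
  select(rule, c, n_h, planned_n, rejection_rate, exact) |>
  head(8)
```

`plot_oc(oc)` draws the familiar rejection-rate-versus-`n_h` curves (solid:
Monte Carlo, dashed: oracle); `plot_oc(oc, metric = "planned_n")` shows the
sample-size cost of caution.

## Pooling several historical sources

With more than one historical cohort, between-source variability has to be
acknowledged. `pool_controls()` implements inverse-variance pooling with
cohort variance `sd_i^2 / n_i` (observed `sd` when available, planning
`sigma` otherwise): fixed-effect, and random-effects with the
DerSimonian–Laird moment estimator of the between-source variance `tau2`.
DL is the field's default moment method, needs no iteration, and has a
two-line closed form a regulator can recompute by hand; the method slot is
the single place to swap in an alternative (REML, Paule–Mandel) should one
be preferred. The pooled precision is re-expressed as an effective patient
count `sigma^2 / se^2`, and `pooled_to_cohort()` hands the threshold rules
a synthetic cohort with `n_h = floor(effective_n)` — flooring is the
conservative direction, widening the CI-based thresholds. A random-effects
pool always has `se` at least as large as the fixed-effect pool, so it
always yields the more cautious threshold.

```{r pool}
cohorts <- tibble::tibble(
  source_id = c("trial_A", "registry_B"),
  n = c(100, 100), mean = c(0.0, 0.4), sd = c(1, 1)
)
glance(pool_controls(cohorts, "random"))
```

## The multistage decision flow

`classify_outcome()` maps a completed stage-1 trial to one of three zones:
**effective** when the one-sided lower `(1 - alpha)` confidence bound
clears the efficacy threshold (exactly equivalent to the z-test rejecting;
the point-estimate variant is available via `criterion = "point"`),
**ineffective** when the point estimate falls below the futility threshold,
**promising** otherwise. The bound-based efficacy rule is the stricter and
the test-consistent reading of "the (confidence bounds of the) result
exceeds the threshold", so it is the default; for futility, a point
estimate below the bar is the natural sponsor's stopping rule and no bound
is involved.

`simulate_program()` runs the whole adaptive pathway: a promising stage-1
result rolls over into either a conventional RCT with concurrent controls
(sized by `parallel_group_size()` at the stage-2 alpha) or a second
single-arm trial that reuses the stage-1 threshold with fresh patients
only (no pooling of stage-1 data — re-using data against the same
threshold would bias the second test, and the conservative reading is to
require fresh confirmation). The futility bar defaults to the replicate's
observed historical mean — the natural "worse than control" benchmark —
and is fully overridable: `"none"`, a fixed value, or `"efficacy_bound"`
(which empties the promising zone and collapses the flow to a single-stage
design, a useful degenerate check). No multiplicity adjustment is applied
across stages by default — the stages answer the same question with
independent data, and the overall false-positive rate is bounded by the
sum of the stage-wise levels (asserted in the tests); choosing a smaller
`stage2_alpha` implements an explicit split.

The program summary reports the stage-1 zone probabilities (an exact
partition), the overall probability of a positive conclusion, and the
expected total patients, counting both arms of a stage-2 RCT.

## The pipeline and its reproducibility contract

`run_pipeline()` executes the pre-agreed plan from a YAML/JSON config —
pool, derive thresholds and sizes per rule, estimate the OC grid, simulate
the flow — and writes `threshold_report.json`, `oc_grid.csv`,
`program_oc.csv`, and `run_log.json` (config hash, seed, version; no
timestamps, so identical config and seed give byte-identical artifacts).
Cohort CSVs come in a summary schema (`source_id,n,mean,sd`) or a
patient-level schema (`source_id,patient_id,outcome`); mixed schemas,
non-numeric fields, and stated-`n` mismatches are typed parse errors naming
the offending line. Missing outcome values are rejected rather than
imputed: missing-data handling belongs in the estimand discussion, not in a
CSV reader. A thin command-line wrapper (`inst/cli/threshtrial`, with
subcommands `pool`, `threshold`, `size`, `simulate`, `flow`, `all`) drives
the same functions for shell use.

## What the synthetic data do and do not show

The generators draw independent homoscedastic normal outcomes, which is
exactly the planning model: they exercise the *sampling-error* and *drift*
mechanics of threshold designs, and the package's verified claims (error
control, inflation, size trade-offs) are claims about that model. Real
historical controls additionally carry selection effects, covariate
imbalance, measurement differences between eras, and non-normal endpoints —
none of which the simulations emulate, and all of which bias a threshold
comparison in ways no threshold margin provably absorbs. Passing tests
therefore validate the arithmetic of the design, not the comparability of
any particular historical cohort; the latter is a scientific judgement the
package only parameterizes (via drift scenarios and conservative rules).

Other known limitations: continuous normal endpoints only (no binary or
survival outcomes), no covariate adjustment, no Bayesian borrowing of
historical information, and a drift model that is a pure location shift.

## Numerical conventions and problem sizes

Normal quantiles are used at full precision (`qnorm(0.975)` = 1.959964, not
1.96); ties at a critical value never reject (a probability-zero event,
fixed for determinism). The documented examples and the test suite run
grids of a few hundred thousand replicates in seconds thanks to the
sufficient-statistic engine; the headline operating characteristics
(`scripts/acceptance.R`) use 100,000 replicates per quantity, putting the
Monte Carlo standard error near 0.05% on the type-I scale and 0.13% on the
power scale.
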