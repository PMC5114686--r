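#' Simulate a historical control cohort
#'
#' Draws `n` independent normal outcomes and summarizes them as a one-row
#' cohort tibble (with the raw draws kept in a `values` list-column). Given
#' the same `seed` the cohort is reproduced exactly; `seed = NULL` uses and
#' advances the session RNG stream.
#'
#' @param n Number of patients (>= 1).
#' @param mu True control mean (endpoint units).
#' @param sigma Outcome standard deviation (> 0).
#' @param source_id Label for the simulated source.
#' @param seed Optional integer seed; when supplied the draw is made in a
#'   local RNG scope and the session stream is untouched.
#' @return A one-row cohort tibble: `source_id`, `n`, `mean`, `sd`,
#'   `values`. The `sd` of a single-patient cohort is reported as 0.
#' @examples
#' simulate_historical_cohort(100, mu = 0, seed = 42)
#' @export
simulate_historical_cohort <- function(n, mu = 0, sigma = 1,
                                       source_id = "historical",
                                       seed = NULL) {
  n <- check_count(n, "n")
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  x <- with_optional_seed(seed, rnorm(n, mu, sigma))
  tibble(
    source_id = source_id, n = n,
    mean = mean(x), sd = if (n > 1L) sd(x) else 0,
    values = list(x)
  )
}

#' Simulate a single-arm trial outcome
#'
#' Draws `n` independent normal outcomes for patients on the experimental
#' treatment and returns the trial-level summary.
#'
#' @inheritParams simulate_historical_cohort
#' @param mu True mean response under the experimental treatment.
#' @return A one-row tibble: `n`, `mean`, `sd` (0 when `n = 1`).
#' @examples
#' simulate_trial(197, mu = 0.2, seed = 7)
#' @export
simulate_trial <- function(n, mu, sigma = 1, seed = NULL) {
  n <- check_count(n, "n")
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  x <- with_optional_seed(seed, rnorm(n, mu, sigma))
  tibble(n = n, mean = mean(x), sd = if (n > 1L) sd(x) else 0)
}

#' Monte Carlo operating characteristics of one threshold-design scenario
#'
#' Estimates, by seeded simulation, the probability that the threshold
#' design rejects: per replicate a historical cohort mean is drawn at
#' `mu_hist`, the threshold rule is applied, a trial of the planned size is
#' drawn with true mean `mu_hist + drift + true_delta * sigma`, and the
#' one-sample z-test is run. The trial size is the deterministic
#' [planned_trial_size()] for `(rule, n_h)` (override with `n`), fixed
#' across replicates. The replicate-level sample means are simulated
#' directly from their exact sampling distribution
#' `N(mu, sigma^2 / n)` — the sufficient statistic for the z-test — which is
#' distributionally identical to averaging patient-level draws.
#'
#' The closed-form [rejection_probability()] for the same scenario is
#' returned alongside for validation.
#'
#' @inheritParams rejection_probability
#' @param mu_hist True historical control mean (endpoint units); the
#'   problem is location invariant, so the default 0 is general.
#' @param n Trial size override; default is the planned size.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Optional root seed. The cell draws from a sub-stream derived
#'   from the seed and the scenario descriptors (see [cell_seed()]), so a
#'   cell's result does not depend on which other cells run.
#' @return A one-row tibble: `rule`, `gamma`, `c`, `n_h`, `drift`,
#'   `true_delta`, `planned_n`, `rejection_rate`, `mc_se` (binomial standard
#'   error), `exact` (the oracle), `n_reps`, `seed`, `feasible`. For an
#'   infeasible cell (`effective_delta <= 0`) the numeric results are `NA`
#'   and `feasible` is `FALSE`.
#' @examples
#' estimate_oc(design_params(), "naive", n_h = 100, n_reps = 1e4, seed = 1)
#' @export
estimate_oc <- function(params, rule, n_h, true_delta = 0, drift = 0,
                        mu_hist = 0, n = NULL, n_reps = 1e5, seed = NULL) {
  stopifnot(inherits(params, "design_params"))
  rule <- parse_threshold_rule(rule)
  n_h <- check_count(n_h, "n_h")
  n_reps <- check_count(n_reps, "n_reps")
  base <- tibble(
    rule = .env$rule$rule, gamma = .env$rule$gamma, c = .env$rule$c,
    n_h = n_h, drift = drift, true_delta = true_delta
  )
  planned <- tryCatch(
    if (is.null(n)) planned_trial_size(rule, n_h, params) else check_count(n, "n"),
    threshtrial_infeasible_error = function(e) NA_integer_
  )
  if (is.na(planned)) {
    return(dplyr::mutate(base,
      planned_n = NA_integer_, rejection_rate = NA_real_, mc_se = NA_real_,
      exact = NA_real_, n_reps = n_reps,
      seed = seed %||% NA_integer_, feasible = FALSE
    ))
  }
  run <- function() {
    mc_single_arm(rule, n_h, planned, params, true_delta, drift, mu_hist,
                  n_reps)
  }
  p_hat <- if (is.null(seed)) {
    run()
  } else {
    withr::with_seed(
      cell_seed(seed, rule$rule, rule$gamma, rule$c, n_h, drift, true_delta,
                n_reps),
      run()
    )
  }
  exact_p <- rejection_probability(rule, n_h, planned, params, true_delta,
                                   drift)
  dplyr::mutate(base,
    planned_n = planned,
    rejection_rate = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / n_reps),
    exact = exact_p,
    n_reps = n_reps, seed = seed %||% NA_integer_, feasible = TRUE
  )
}

# Vectorized Monte Carlo core; expects the RNG state to be set by the caller.
mc_single_arm <- function(rule, n_h, n, params, true_delta, drift, mu_hist,
                          n_reps) {
  sigma <- params$sigma
  hist_means <- rnorm(n_reps, mu_hist, sigma / sqrt(n_h))
  trial_means <- rnorm(n_reps, mu_hist + drift + true_delta * sigma,
                       sigma / sqrt(n))
  thresholds <- hist_means + rule_offset(rule, n_h, params) * sigma
  z <- (trial_means - thresholds) * sqrt(n) / sigma
  mean(z > qnorm(1 - params$alpha))
}

#' Monte Carlo operating characteristics of the parallel-group design
#'
#' Simulates a two-arm trial with concurrent controls: both arm means are
#' drawn from their exact sampling distributions and compared with the
#' one-sided two-sample z-test. Because the control arm is concurrent, the
#' result does not depend on historical data or on a common drift of the
#' control condition.
#'
#' @inheritParams estimate_oc
#' @param n_per_group Per-group size; default is the closed-form
#'   [parallel_group_size()].
#' @param mu_ctrl True concurrent control mean (location invariant; default
#'   0).
#' @return A one-row tibble: `rule = "two_arm"`, `n_per_group`, `planned_n`
#'   (total over both arms), `true_delta`, `rejection_rate`, `mc_se`,
#'   `exact`, `n_reps`, `seed`.
#' @examples
#' two_arm_oc(design_params(), true_delta = 0.2, n_reps = 1e4, seed = 1)
#' @export
two_arm_oc <- function(params, true_delta = 0, n_per_group = NULL,
                       n_reps = 1e5, seed = NULL, mu_ctrl = 0) {
  stopifnot(inherits(params, "design_params"))
  n_g <- if (is.null(n_per_group)) parallel_group_size(params)
         else check_count(n_per_group, "n_per_group")
  n_reps <- check_count(n_reps, "n_reps")
  run <- function() mc_two_arm(n_g, params, true_delta, mu_ctrl, n_reps)
  p_hat <- if (is.null(seed)) {
    run()
  } else {
    withr::with_seed(cell_seed(seed, "two_arm", true_delta, n_g, n_reps),
                     run())
  }
  tibble(
    rule = "two_arm", n_per_group = n_g, planned_n = 2L * n_g,
    true_delta = true_delta,
    rejection_rate = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / n_reps),
    exact = two_arm_power(n_g, params, true_delta),
    n_reps = n_reps, seed = seed %||% NA_integer_
  )
}

mc_two_arm <- function(n_per_group, params, true_delta, mu_ctrl, n_reps) {
  sigma <- params$sigma
  m_exp <- rnorm(n_reps, mu_ctrl + true_delta * sigma,
                 sigma / sqrt(n_per_group))
  m_ctrl <- rnorm(n_reps, mu_ctrl, sigma / sqrt(n_per_group))
  z <- (m_exp - m_ctrl) / (sigma * sqrt(2 / n_per_group))
  mean(z > qnorm(1 - params$alpha))
}

#' Operating-characteristic grid over historical sample sizes and rules
#'
#' Crosses the threshold rules with a grid of historical control sizes,
#' drift values, and true effects, estimating each cell by Monte Carlo and
#' attaching the closed-form oracle. Two-arm parallel-group reference rows
#' are appended for each `(drift, true_delta)` combination; their results
#' are identical across `n_h` by construction (the control arm is
#' concurrent). Null cells (`true_delta = 0`) use `n_reps_null` replicates
#' and power cells `n_reps_power`, reflecting the tighter Monte Carlo error
#' needed near a 2.5% rejection rate.
#'
#' @inheritParams estimate_oc
#' @param rules A tibble with columns `rule`, `gamma`, `c` (one row per
#'   rule), e.g. [default_threshold_rules()].
#' @param n_h Vector of historical control sizes (the grid's x-axis).
#' @param drift Vector of drift values (endpoint units).
#' @param true_delta Vector of true standardized effects; defaults to the
#'   null and the design alternative.
#' @param n_reps_null,n_reps_power Replicates for null / power cells.
#' @param two_arm Append the parallel-group reference rows?
#' @param seed Root seed; each cell uses its own descriptor-derived
#'   sub-stream so the grid layout never changes a cell's result.
#' @return A long tibble, one row per cell, with the columns of
#'   [estimate_oc()] (two-arm rows carry `rule = "two_arm"`, `gamma` and `c`
#'   `NA`). Infeasible cells are retained with `feasible = FALSE`.
#' @examples
#' oc_grid(design_params(), n_h = c(100, 1000),
#'         n_reps_null = 2000, n_reps_power = 2000, seed = 1)
#' @export
oc_grid <- function(params, rules = default_threshold_rules(),
                    n_h = c(100, 250, 500, 1000, 2000),
                    drift = 0, true_delta = c(0, params$delta),
                    n_reps_null = 1e5, n_reps_power = 1e4,
                    two_arm = TRUE, mu_hist = 0, seed = 1) {
  stopifnot(inherits(params, "design_params"))
  if (!is.data.frame(rules) || !all(c("rule", "gamma", "c") %in% names(rules))) {
    abort("`rules` must be a tibble with columns rule, gamma, c.",
          class = "threshtrial_config_error")
  }
  cells <- tidyr::expand_grid(
    rules, n_h = as.integer(n_h), drift = drift, true_delta = true_delta
  )
  single <- purrr::pmap(cells, function(rule, gamma, c, n_h, drift,
                                        true_delta) {
    estimate_oc(
      params, threshold_rule(rule, gamma = gamma, c = c),
      n_h = n_h, true_delta = true_delta, drift = drift, mu_hist = mu_hist,
      n_reps = if (true_delta == 0) n_reps_null else n_reps_power,
      seed = seed
    )
  })
  out <- dplyr::bind_rows(single)
  if (two_arm) {
    ref_cells <- tidyr::expand_grid(drift = drift, true_delta = true_delta)
    refs <- purrr::pmap(ref_cells, function(drift, true_delta) {
      oc <- two_arm_oc(
        params, true_delta = true_delta,
        n_reps = if (true_delta == 0) n_reps_null else n_reps_power,
        seed = seed, mu_ctrl = mu_hist + drift
      )
      # same concurrent-control result replicated across the n_h axis
      tidyr::expand_grid(n_h = as.integer(n_h)) |>
        dplyr::mutate(
          rule = "two_arm", gamma = NA_real_, c = NA_real_,
          drift = drift, true_delta = true_delta,
          planned_n = oc$planned_n, rejection_rate = oc$rejection_rate,
          mc_se = oc$mc_se, exact = oc$exact, n_reps = oc$n_reps,
          seed = seed, feasible = TRUE
        )
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(refs))
  }
  dplyr::relocate(out, "rule", "gamma", "c", "n_h", "drift", "true_delta")
}

#' Deterministic per-cell seed derivation
#'
#' Derives the seed of a scenario cell's RNG sub-stream from the root seed
#' and the cell's descriptors: the descriptors are concatenated into a key
#' string and hashed with a base-31 polynomial over the character codes,
#' modulo the Mersenne prime 2^31 - 1; the root seed is added modulo the
#' same prime. Adding or removing cells from a grid therefore never
#' perturbs another cell's draws.
#'
#' @param root Integer root seed.
#' @param ... Scenario descriptors (coerced to character).
#' @return An integer seed in \[1, 2^31 - 1\].
#' @examples
#' cell_seed(1, "ci_upper", 0.95, 0, 1000, 0, 0)
#' @export
cell_seed <- function(root, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)),
               collapse = "|")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer((as.numeric(root) %% m + h) %% m + 1)
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
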