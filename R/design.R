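#' Per-group sample size for a parallel-group superiority trial
#'
#' Smallest per-group `n` so that a one-sided two-sample z-test at level
#' `alpha` attains the target power against a standardized mean difference
#' `delta`:
#' \deqn{n = \lceil 2 (z_{1-\alpha} + z_{power})^2 / \Delta^2 \rceil.}
#' At the reference scenario (`delta = 0.2`, `alpha = 0.025`, `power = 0.8`)
#' this gives 393 per group, i.e. "about 400" after rounding to the nearest
#' hundred (see [round_hundred()]), for a total of 786 ("about 800").
#'
#' @param params A [design_params()] object.
#' @return Integer per-group sample size.
#' @examples
#' parallel_group_size(design_params()) # 393
#' @seealso [single_arm_size()], [planned_trial_size()]
#' @export
parallel_group_size <- function(params) {
  stopifnot(inherits(params, "design_params"))
  z <- qnorm(1 - params$alpha) + qnorm(params$power)
  as.integer(ceiling(2 * z^2 / params$delta^2))
}

#' Sample size for a single-arm trial against a fixed threshold
#'
#' Smallest `n` so that a one-sided one-sample z-test at level `alpha`
#' attains the target power when the true mean exceeds the threshold by
#' `effective_delta` standard deviations:
#' \deqn{n = \lceil (z_{1-\alpha} + z_{power})^2 / \Delta_{eff}^2 \rceil.}
#' When the threshold sits exactly at the control mean,
#' `effective_delta = delta` and the reference scenario gives 197 ("about
#' 200"): a quarter of the parallel-group total.
#'
#' @param effective_delta Standardized distance between the assumed treatment
#'   mean and the threshold (> 0). A CI-based threshold eats into the assumed
#'   effect, reducing this below `delta`.
#' @param alpha One-sided significance level.
#' @param power Target power.
#' @return Integer sample size.
#' @examples
#' single_arm_size(0.2) # 197
#' @export
single_arm_size <- function(effective_delta, alpha = 0.025, power = 0.80) {
  check_number(alpha, "alpha", lower = 0, upper = 0.5, strict = TRUE)
  check_number(power, "power", lower = 0, upper = 1, strict = TRUE)
  if (!is.numeric(effective_delta) || length(effective_delta) != 1L ||
      !is.finite(effective_delta) || effective_delta <= 0) {
    stop_infeasible(effective_delta)
  }
  z <- qnorm(1 - alpha) + qnorm(power)
  as.integer(ceiling(z^2 / effective_delta^2))
}

#' Round a sample size to the nearest hundred
#'
#' Presentation helper for "about 400 / about 200 / about 800" style
#' reporting; never used inside the planning math itself.
#'
#' @param n Numeric vector of sample sizes.
#' @return Integer vector rounded to the nearest 100.
#' @examples
#' round_hundred(c(393, 197, 786, 413)) # 400 200 800 400
#' @export
round_hundred <- function(n) {
  as.integer(round(n / 100) * 100)
}

#' Derive the efficacy threshold from historical control data
#'
#' Applies a [threshold_rule()] to a historical control estimate:
#' * `naive_mean`: `t = mean`;
#' * `ci_upper`: `t = mean + z_{(1+gamma)/2} * sigma / sqrt(n)`;
#' * `ci_upper_plus`: the `ci_upper` value `+ c * delta * sigma`.
#'
#' By default the half-width uses the planning `sigma` from `params`
#' (a deterministic, pre-specifiable adjustment); set
#' `use_observed_sd = TRUE` to use the cohort's observed standard deviation
#' instead.
#'
#' @param hist A single historical cohort: a one-row tibble with columns
#'   `n`, `mean` (and optionally `sd`, `source_id`), or a
#'   [pool_controls()] result, which is converted via [pooled_to_cohort()].
#'   Several cohorts must be pooled first.
#' @param rule A [threshold_rule()] (or a label accepted by
#'   [parse_threshold_rule()]).
#' @param params A [design_params()] object supplying `sigma` and `delta`.
#' @param use_observed_sd Use the cohort's observed `sd` for the CI
#'   half-width instead of the planning `sigma`. Default `FALSE`.
#'
#' @return An object of class `efficacy_threshold` with elements `t` (the
#'   threshold, endpoint units), `rule`, and `provenance` (historical mean,
#'   `n`, sd used, source label).
#' @examples
#' hist <- tibble::tibble(source_id = "registry", n = 1000, mean = 0, sd = 1)
#' compute_threshold(hist, "ci", design_params())
#' @export
compute_threshold <- function(hist, rule, params, use_observed_sd = FALSE) {
  stopifnot(inherits(params, "design_params"))
  rule <- parse_threshold_rule(rule)
  if (inherits(hist, "pooled_controls")) {
    hist <- pooled_to_cohort(hist)
  }
  hist <- validate_cohorts(hist)
  if (nrow(hist) != 1L) {
    abort("`hist` must be a single cohort; pool several cohorts with `pool_controls()` first.",
          class = "threshtrial_config_error")
  }
  if (is.na(hist$mean)) {
    abort("Historical cohort has no mean; cannot derive a threshold.",
          class = "threshtrial_config_error")
  }
  sd_used <- params$sigma
  if (use_observed_sd) {
    if (is.na(hist$sd) || hist$sd <= 0) {
      abort("`use_observed_sd = TRUE` requires a positive observed sd.",
            class = "threshtrial_config_error")
    }
    sd_used <- hist$sd
  }
  t <- hist$mean
  if (rule$rule %in% c("ci_upper", "ci_upper_plus")) {
    t <- t + qnorm((1 + rule$gamma) / 2) * sd_used / sqrt(hist$n)
  }
  if (rule$rule == "ci_upper_plus") {
    t <- t + rule$c * params$delta * params$sigma
  }
  structure(
    list(
      t = t,
      rule = rule,
      provenance = list(
        mean = hist$mean, n_h = hist$n, sd_used = sd_used,
        source_id = hist$source_id
      )
    ),
    class = "efficacy_threshold"
  )
}

#' @export
print.efficacy_threshold <- function(x, ...) {
  cat("<efficacy_threshold>\n")
  cat(sprintf("  t = %.5f  [rule: %s]\n", x$t, rule_label(x$rule)))
  cat(sprintf("  from %s: mean = %.5f, n = %d\n",
              x$provenance$source_id, x$provenance$mean,
              as.integer(x$provenance$n_h)))
  invisible(x)
}

#' Planned single-arm trial size under a threshold rule
#'
#' Deterministic planning size that accounts for how far the threshold rule
#' pushes `t` above the control mean. The standardized effect left over for
#' the one-sample test is
#' \deqn{\Delta_{eff} = \Delta - [\mathrm{CI\ rules}]\, z_{(1+\gamma)/2}/\sqrt{n_h} - c\,\Delta,}
#' using the known CI half-width (not a random draw), and the size is
#' `single_arm_size(effective_delta, alpha, power)`. The size is
#' non-increasing in `n_h` and converges to the naive single-arm size as
#' `n_h` grows. With 1000 historical controls the 95% CI rule gives 413
#' ("about 400", half the parallel-group total).
#'
#' @inheritParams compute_threshold
#' @param n_h Number of historical control patients.
#' @return Integer trial size, or an error of class
#'   `threshtrial_infeasible_error` when the rule consumes the whole assumed
#'   effect (`effective_delta <= 0`).
#' @examples
#' planned_trial_size("ci", 1000, design_params()) # 413
#' @export
planned_trial_size <- function(rule, n_h, params) {
  stopifnot(inherits(params, "design_params"))
  rule <- parse_threshold_rule(rule)
  n_h <- check_count(n_h, "n_h")
  eff <- effective_delta(rule, n_h, params)
  if (eff <= 0) {
    stop_infeasible(eff, rule = rule, n_h = n_h)
  }
  single_arm_size(eff, alpha = params$alpha, power = params$power)
}

# Standardized effect remaining after the threshold rule's offset.
effective_delta <- function(rule, n_h, params) {
  params$delta - rule_offset(rule, n_h, params)
}

# Offset of the threshold above the historical mean, in sigma units.
rule_offset <- function(rule, n_h, params) {
  switch(rule$rule,
    naive_mean = rep(0, length(n_h)),
    ci_upper = qnorm((1 + rule$gamma) / 2) / sqrt(n_h),
    ci_upper_plus = qnorm((1 + rule$gamma) / 2) / sqrt(n_h) +
      rule$c * params$delta
  )
}

#' One-sample z-test of a single-arm trial against a threshold
#'
#' Tests `H0: mu_N <= t` against `H1: mu_N > t` with the known-variance
#' statistic `z = (mean - t) * sqrt(n) / sigma`, rejecting when
#' `z > z_{1-alpha}` (a tie at the critical value does not reject).
#'
#' @param mean Observed trial mean (endpoint units).
#' @param n Trial sample size.
#' @param threshold An [compute_threshold()] result or a bare numeric
#'   threshold value.
#' @param params A [design_params()] object (supplies `sigma` and `alpha`).
#' @return A one-row tibble: `estimate`, `n`, `threshold`, `statistic`,
#'   `crit`, `reject`, `alpha`.
#' @examples
#' one_sample_z_test(0.25, 197, 0.06, design_params())
#' @export
one_sample_z_test <- function(mean, n, threshold, params) {
  stopifnot(inherits(params, "design_params"))
  n <- check_count(n, "n")
  t <- if (inherits(threshold, "efficacy_threshold")) threshold$t else threshold
  check_number(t, "threshold")
  z <- (mean - t) * sqrt(n) / params$sigma
  crit <- qnorm(1 - params$alpha)
  tibble(
    estimate = mean, n = n, threshold = t,
    statistic = z, crit = crit, reject = z > crit, alpha = params$alpha
  )
}

#' Two-sample z-test for a parallel-group superiority trial
#'
#' Tests `H0: mu_N <= mu_C` against `H1: mu_N > mu_C` with
#' `z = (mean_exp - mean_ctrl) / (sigma * sqrt(1/n_exp + 1/n_ctrl))`,
#' rejecting when `z > z_{1-alpha}`.
#'
#' @param mean_exp,n_exp Experimental arm mean and size.
#' @param mean_ctrl,n_ctrl Concurrent control arm mean and size.
#' @inheritParams one_sample_z_test
#' @return A one-row tibble: `estimate` (the mean difference), `n_exp`,
#'   `n_ctrl`, `statistic`, `crit`, `reject`, `alpha`.
#' @examples
#' two_sample_z_test(0.2, 393, 0, 393, design_params())
#' @export
two_sample_z_test <- function(mean_exp, n_exp, mean_ctrl, n_ctrl, params) {
  stopifnot(inherits(params, "design_params"))
  n_exp <- check_count(n_exp, "n_exp")
  n_ctrl <- check_count(n_ctrl, "n_ctrl")
  z <- (mean_exp - mean_ctrl) / (params$sigma * sqrt(1 / n_exp + 1 / n_ctrl))
  crit <- qnorm(1 - params$alpha)
  tibble(
    estimate = mean_exp - mean_ctrl, n_exp = n_exp, n_ctrl = n_ctrl,
    statistic = z, crit = crit, reject = z > crit, alpha = params$alpha
  )
}

#' Exact marginal rejection probability of a threshold-crossing design
#'
#' Closed-form probability, marginal over the sampling distribution of the
#' historical control mean, that the one-sample z-test rejects. With the
#' threshold offset `o` (in sigma units; 0 for the naive rule,
#' `z_{(1+gamma)/2}/sqrt(n_h)` for the CI rule, plus `c * delta` for the
#' inflated rule), the concurrent control mean drifted by `drift` and a true
#' standardized effect `true_delta` over the concurrent control:
#' \deqn{P(\mathrm{reject}) = 1 - \Phi\!\left(
#'   \frac{o\sigma + z_{1-\alpha}\sigma/\sqrt{n} - \Delta_{true}\sigma - \mathrm{drift}}
#'        {\sigma\sqrt{1/n + 1/n_h}}\right).}
#' `true_delta = 0` gives the (possibly drift-inflated) type-I error;
#' `true_delta = delta` gives the power. This is the oracle the Monte Carlo
#' engine is validated against.
#'
#' Vectorized over `n_h`, `n`, `true_delta`, and `drift`.
#'
#' @inheritParams planned_trial_size
#' @param n Single-arm trial size.
#' @param true_delta True standardized effect of the new treatment over the
#'   concurrent control (0 under the null).
#' @param drift Shift of the concurrent control mean relative to the
#'   historical control mean, in endpoint units.
#' @return Numeric vector of rejection probabilities.
#' @examples
#' p <- design_params()
#' rejection_probability("naive", n_h = 100, n = 197, p) # inflated: 0.128
#' rejection_probability("ci", n_h = 100, n = 197, p)    # conservative
#' @export
rejection_probability <- function(rule, n_h, n, params, true_delta = 0,
                                  drift = 0) {
  stopifnot(inherits(params, "design_params"))
  rule <- parse_threshold_rule(rule)
  sigma <- params$sigma
  off <- rule_offset(rule, n_h, params)
  num <- off * sigma + qnorm(1 - params$alpha) * sigma / sqrt(n) -
    true_delta * sigma - drift
  1 - pnorm(num / (sigma * sqrt(1 / n + 1 / n_h)))
}

#' Exact power of the two-sample z-test
#'
#' `1 - pnorm(z_{1-alpha} - true_delta * sqrt(n/2))` for equal per-group
#' size `n_per_group`; independent of historical data and of any common
#' drift affecting both concurrent arms.
#'
#' @param n_per_group Per-group sample size.
#' @inheritParams rejection_probability
#' @return Numeric rejection probability.
#' @examples
#' two_arm_power(393, design_params(), true_delta = 0.2) # > 0.8
#' @export
two_arm_power <- function(n_per_group, params, true_delta = 0) {
  stopifnot(inherits(params, "design_params"))
  1 - pnorm(qnorm(1 - params$alpha) - true_delta * sqrt(n_per_group / 2))
}

#' @export
tidy.efficacy_threshold <- function(x, ...) {
  tibble(
    t = x$t,
    rule = x$rule$rule,
    gamma = x$rule$gamma,
    c = x$rule$c,
    hist_mean = x$provenance$mean,
    n_h = as.integer(x$provenance$n_h),
    sd_used = x$provenance$sd_used,
    source_id = x$provenance$source_id
  )
}

stop_infeasible <- function(effective_delta, rule = NULL, n_h = NULL) {
  msg <- "Infeasible design: the effective standardized effect is not positive."
  if (!is.null(rule)) {
    msg <- paste0(
      msg, sprintf(
        " The %s threshold with n_h = %d consumes the whole assumed effect (effective delta = %.4f).",
        rule_label(rule), as.integer(n_h), effective_delta
      )
    )
  }
  abort(msg, class = "threshtrial_infeasible_error",
        effective_delta = effective_delta)
}
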