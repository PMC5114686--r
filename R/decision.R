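#' Efficacy and futility thresholds for the multistage decision flow
#'
#' A completed single-arm trial is classified against two benchmarks: an
#' efficacy threshold `efficacy_t` (crossing it establishes efficacy) and a
#' lower futility threshold `futility_f` (falling below it terminates
#' development); results in between are "promising" and trigger a second
#' stage.
#'
#' @param efficacy_t Efficacy threshold (endpoint units), e.g. the `t` of a
#'   [compute_threshold()] result.
#' @param futility_f Futility threshold (endpoint units); must not exceed
#'   `efficacy_t`. Default `-Inf` (no futility stop).
#' @return An object of class `decision_thresholds`.
#' @examples
#' decision_thresholds(efficacy_t = 0.062, futility_f = 0)
#' @export
decision_thresholds <- function(efficacy_t, futility_f = -Inf) {
  check_number(efficacy_t, "efficacy_t")
  if (!is.numeric(futility_f) || length(futility_f) != 1L ||
      is.na(futility_f)) {
    abort("`futility_f` must be a single number (possibly -Inf).",
          class = "threshtrial_config_error")
  }
  if (futility_f > efficacy_t) {
    abort("`futility_f` must not exceed `efficacy_t`.",
          class = "threshtrial_config_error")
  }
  structure(list(efficacy_t = efficacy_t, futility_f = futility_f),
            class = "decision_thresholds")
}

#' Classify a completed single-arm trial
#'
#' Classifies the trial as `"effective"`, `"promising"`, or `"ineffective"`:
#' * effective — the one-sided lower `(1 - alpha)` confidence bound,
#'   `mean - z_{1-alpha} * sigma / sqrt(n)`, exceeds the efficacy threshold
#'   (equivalent to rejection by [one_sample_z_test()]); with
#'   `criterion = "point"` the point estimate is compared instead;
#' * ineffective — the point estimate falls below the futility threshold;
#' * promising — everything in between.
#'
#' @param trial A one-row tibble (or list) with `n` and `mean`, e.g. from
#'   [simulate_trial()].
#' @param thresholds A [decision_thresholds()] object.
#' @param params A [design_params()] object (supplies `sigma` and `alpha`).
#' @param criterion `"bound"` (default, test-equivalent lower confidence
#'   bound) or `"point"` (point-estimate crossing).
#' @return A single string: `"effective"`, `"promising"`, or
#'   `"ineffective"`.
#' @examples
#' dt <- decision_thresholds(0.06, 0)
#' classify_outcome(list(n = 400, mean = 0.30), dt, design_params())
#' @export
classify_outcome <- function(trial, thresholds, params,
                             criterion = c("bound", "point")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(params, "design_params"),
            inherits(thresholds, "decision_thresholds"))
  n <- check_count(trial$n, "trial$n")
  est <- trial$mean
  crossing_stat <- if (criterion == "bound") {
    est - qnorm(1 - params$alpha) * params$sigma / sqrt(n)
  } else {
    est
  }
  if (crossing_stat > thresholds$efficacy_t) {
    "effective"
  } else if (est < thresholds$futility_f) {
    "ineffective"
  } else {
    "promising"
  }
}

#' Simulate the multistage threshold-crossing program
#'
#' Monte Carlo simulation of the full adaptive pathway: a stage-1 single-arm
#' trial against a historically derived threshold is classified as
#' effective, promising, or ineffective; a promising result rolls over into
#' a stage-2 study — a conventional randomized controlled trial with
#' concurrent controls, a second single-arm trial reusing the stage-1
#' threshold with fresh patients, or nothing (`"none"`, promising is then
#' terminal).
#'
#' Per replicate a historical cohort mean is drawn at `mu_hist`, the
#' threshold rule sets the efficacy threshold, a stage-1 trial of the
#' planned size is drawn with true mean `mu_hist + drift +
#' true_delta * sigma`, and the outcome is classified (lower-confidence
#' bound rule). The futility threshold defaults to the replicate's observed
#' historical mean. No multiplicity adjustment is applied across stages
#' unless a smaller `stage2_alpha` is chosen; under the defaults the overall
#' false-positive probability is bounded by the sum of the stage-wise
#' levels.
#'
#' @inheritParams estimate_oc
#' @param stage2 `"rct"`, `"single_arm"`, or `"none"`.
#' @param stage2_alpha One-sided level of the stage-2 test; defaults to
#'   `params$alpha`.
#' @param futility Futility rule: `"historical_mean"` (default; the
#'   replicate's observed historical mean), `"none"` (never stop for
#'   futility), `"efficacy_bound"` (set at the stage-1 critical mean, which
#'   empties the promising zone and reduces the flow to a single-stage
#'   design), or a fixed numeric value in endpoint units.
#' @param n Stage-1 trial size override; default is the planned size for
#'   `(rule, n_h)`.
#' @return A one-row tibble: stage-1 outcome probabilities `p_effective`,
#'   `p_promising`, `p_ineffective` (summing to 1), the overall probability
#'   `p_positive` of a final positive conclusion (stage-1 efficacy or
#'   stage-2 success), `expected_n` (expected total patients over both
#'   stages, counting both arms of a stage-2 RCT), the stage sizes, and the
#'   simulation metadata.
#' @examples
#' simulate_program(design_params(), "ci", n_h = 1000, true_delta = 0.2,
#'                  n_reps = 2000, seed = 1)
#' @export
simulate_program <- function(params, rule, n_h, true_delta = 0, drift = 0,
                             mu_hist = 0,
                             stage2 = c("rct", "single_arm", "none"),
                             stage2_alpha = NULL,
                             futility = "historical_mean",
                             n = NULL, n_reps = 1e4, seed = NULL) {
  stopifnot(inherits(params, "design_params"))
  stage2 <- match.arg(stage2)
  rule <- parse_threshold_rule(rule)
  n_h <- check_count(n_h, "n_h")
  n_reps <- check_count(n_reps, "n_reps")
  stage2_alpha <- stage2_alpha %||% params$alpha
  check_number(stage2_alpha, "stage2_alpha", lower = 0, upper = 0.5,
               strict = TRUE)
  n1 <- if (is.null(n)) {
    planned_trial_size(rule, n_h, params)
  } else {
    check_count(n, "n")
  }

  run <- function() {
    sigma <- params$sigma
    zcrit1 <- qnorm(1 - params$alpha)
    hist_means <- rnorm(n_reps, mu_hist, sigma / sqrt(n_h))
    t_eff <- hist_means + rule_offset(rule, n_h, params) * sigma
    mu_true <- mu_hist + drift + true_delta * sigma
    trial_means <- rnorm(n_reps, mu_true, sigma / sqrt(n1))
    f <- if (identical(futility, "historical_mean")) {
      hist_means
    } else if (identical(futility, "none")) {
      rep(-Inf, n_reps)
    } else if (identical(futility, "efficacy_bound")) {
      t_eff + zcrit1 * sigma / sqrt(n1)
    } else if (is.numeric(futility) && length(futility) == 1L) {
      rep(futility, n_reps)
    } else {
      abort("`futility` must be \"historical_mean\", \"none\", \"efficacy_bound\", or a number.",
            class = "threshtrial_config_error")
    }
    effective <- trial_means - zcrit1 * sigma / sqrt(n1) > t_eff
    ineffective <- !effective & trial_means < f
    promising <- !(effective | ineffective)

    positive <- effective
    total_n <- rep(as.numeric(n1), n_reps)
    n2 <- NA_integer_
    k <- sum(promising)
    if (stage2 == "rct") {
      p2 <- design_params(params$delta, params$sigma, stage2_alpha,
                          params$power)
      n2 <- parallel_group_size(p2)
      if (k > 0L) {
        m_exp <- rnorm(k, mu_true, sigma / sqrt(n2))
        m_ctl <- rnorm(k, mu_hist + drift, sigma / sqrt(n2))
        z2 <- (m_exp - m_ctl) / (sigma * sqrt(2 / n2))
        positive[promising] <- z2 > qnorm(1 - stage2_alpha)
        total_n[promising] <- total_n[promising] + 2 * n2
      }
    } else if (stage2 == "single_arm") {
      n2 <- n1
      if (k > 0L) {
        m2 <- rnorm(k, mu_true, sigma / sqrt(n2))
        z2 <- (m2 - t_eff[promising]) * sqrt(n2) / sigma
        positive[promising] <- z2 > qnorm(1 - stage2_alpha)
        total_n[promising] <- total_n[promising] + n2
      }
    }
    tibble(
      rule = .env$rule$rule, gamma = .env$rule$gamma, c = .env$rule$c,
      n_h = n_h,
      drift = drift, true_delta = true_delta,
      stage2 = stage2, stage2_alpha = stage2_alpha,
      stage1_n = n1, stage2_n = n2,
      p_effective = mean(effective),
      p_promising = mean(promising),
      p_ineffective = mean(ineffective),
      p_positive = mean(positive),
      expected_n = mean(total_n),
      n_reps = n_reps, seed = seed %||% NA_integer_
    )
  }

  if (is.null(seed)) {
    run()
  } else {
    withr::with_seed(
      cell_seed(seed, "program", rule$rule, rule$gamma, rule$c, n_h, drift,
                true_delta, stage2, stage2_alpha, n_reps),
      run()
    )
  }
}
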