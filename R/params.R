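#' Planning assumptions for a threshold-crossing design
#'
#' Bundles the four quantities every design calculation in the package needs:
#' the standardized effect size the trial is powered to detect, the outcome
#' standard deviation, the one-sided significance level, and the target power.
#' The defaults reproduce the reference scenario used throughout the package
#' documentation: a normally distributed endpoint with `sigma = 1`, a
#' standardized effect `delta = 0.2`, one-sided `alpha = 0.025`, and 80% power.
#'
#' @param delta Standardized effect size \eqn{\Delta = (\mu_N - \mu_C)/\sigma}
#'   (dimensionless, > 0).
#' @param sigma Outcome standard deviation in endpoint units (> 0). All tests
#'   are known-variance z-tests that use this planning value.
#' @param alpha One-sided significance level, in (0, 0.5).
#' @param power Target power, in (0, 1).
#'
#' @return An object of class `design_params`: a named list with the four
#'   validated components.
#' @examples
#' design_params()
#' design_params(delta = 0.3, power = 0.9)
#' @export
design_params <- function(delta = 0.2, sigma = 1, alpha = 0.025, power = 0.80) {
  check_number(delta, "delta", lower = 0, strict = TRUE)
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 0.5, strict = TRUE)
  check_number(power, "power", lower = 0, upper = 1, strict = TRUE)
  structure(
    list(delta = delta, sigma = sigma, alpha = alpha, power = power),
    class = "design_params"
  )
}

#' @export
print.design_params <- function(x, ...) {
  cat("<design_params>\n")
  cat(sprintf("  standardized effect delta: %g\n", x$delta))
  cat(sprintf("  outcome sd sigma:          %g\n", x$sigma))
  cat(sprintf("  one-sided alpha:           %g\n", x$alpha))
  cat(sprintf("  target power:              %g\n", x$power))
  invisible(x)
}

#' Threshold derivation rule
#'
#' Describes how the efficacy threshold `t` is derived from historical control
#' data. Three rules are supported:
#' * `"naive_mean"` — `t` is the observed historical mean itself;
#' * `"ci_upper"` — `t` is the upper boundary of a two-sided `gamma`-level
#'   confidence interval for the control mean;
#' * `"ci_upper_plus"` — the `ci_upper` value further inflated by a fraction
#'   `c` of the assumed standardized effect (i.e. `+ c * delta * sigma`).
#'
#' `c = 0` makes `ci_upper_plus` identical to `ci_upper`.
#'
#' @param rule One of `"naive_mean"`, `"ci_upper"`, `"ci_upper_plus"`.
#' @param gamma Two-sided confidence level for the CI-based rules (default
#'   0.95).
#' @param c Inflation fraction of the standardized effect for
#'   `"ci_upper_plus"` (>= 0); typical values are 0.1, 0.2, 0.3.
#'
#' @return An object of class `threshold_rule`.
#' @examples
#' threshold_rule("ci_upper")
#' threshold_rule("ci_upper_plus", c = 0.2)
#' parse_threshold_rule("ci+0.3")
#' @export
threshold_rule <- function(rule = c("naive_mean", "ci_upper", "ci_upper_plus"),
                           gamma = 0.95, c = 0) {
  rule <- match.arg(rule)
  check_number(gamma, "gamma", lower = 0, upper = 1, strict = TRUE)
  check_number(c, "c", lower = 0)
  if (rule != "ci_upper_plus" && c != 0) {
    abort("`c` is only meaningful for rule \"ci_upper_plus\".",
          class = "threshtrial_config_error")
  }
  structure(list(rule = rule, gamma = gamma, c = c), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("<threshold_rule>", rule_label(x), "\n")
  invisible(x)
}

#' @describeIn threshold_rule Parse a compact rule label such as `"naive"`,
#'   `"ci"`, or `"ci+0.2"` (as used on the command line) into a
#'   `threshold_rule`; passes existing `threshold_rule` objects through.
#' @param x A `threshold_rule` or a character label.
#' @export
parse_threshold_rule <- function(x, gamma = 0.95) {
  if (inherits(x, "threshold_rule")) {
    return(x)
  }
  if (!is.character(x) || length(x) != 1L) {
    abort("A threshold rule must be a `threshold_rule` object or a single string.",
          class = "threshtrial_config_error")
  }
  if (x %in% c("naive", "naive_mean")) {
    return(threshold_rule("naive_mean", gamma = gamma))
  }
  if (x %in% c("ci", "ci_upper")) {
    return(threshold_rule("ci_upper", gamma = gamma))
  }
  if (grepl("^ci\\+", x)) {
    c <- suppressWarnings(as.numeric(sub("^ci\\+", "", x)))
    if (is.na(c)) {
      abort(sprintf("Cannot parse inflation fraction in rule label %s.", dQuote(x)),
            class = "threshtrial_config_error")
    }
    return(threshold_rule("ci_upper_plus", gamma = gamma, c = c))
  }
  if (x == "ci_upper_plus") {
    return(threshold_rule("ci_upper_plus", gamma = gamma, c = 0.1))
  }
  abort(sprintf(
    "Unknown threshold rule %s. Use \"naive\", \"ci\", or \"ci+<c>\" (e.g. \"ci+0.2\").",
    dQuote(x)
  ), class = "threshtrial_config_error")
}

#' The canonical set of threshold rules for operating-characteristic grids
#'
#' The naive observed-mean rule, the 95% CI upper-bound rule, and the CI rule
#' inflated by 0.1, 0.2 and 0.3 of the standardized effect.
#'
#' @param gamma Two-sided confidence level for the CI-based rows.
#' @return A tibble with columns `rule`, `gamma`, `c`, one row per rule.
#' @examples
#' default_threshold_rules()
#' @export
default_threshold_rules <- function(gamma = 0.95) {
  tibble(
    rule = c("naive_mean", "ci_upper", rep("ci_upper_plus", 3L)),
    gamma = gamma,
    c = c(0, 0, 0.1, 0.2, 0.3)
  )
}

rule_label <- function(rule) {
  switch(rule$rule,
    naive_mean = "naive mean",
    ci_upper = sprintf("CI upper (%g%%)", 100 * rule$gamma),
    ci_upper_plus = sprintf("CI upper (%g%%) + %g*delta", 100 * rule$gamma, rule$c)
  )
}

# --- internal validation helpers ------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    bounds <- sprintf(
      if (strict) "strictly between %g and %g" else "in [%g, %g]",
      lower, upper
    )
    abort(sprintf("`%s` must be a single finite number %s.", name, bounds),
          class = "threshtrial_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && abs(x - round(x)) < 1e-8
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %g.", name, min),
          class = "threshtrial_config_error")
  }
  invisible(as.integer(round(x)))
}
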