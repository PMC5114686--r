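#' Validate a tibble of historical control cohorts
#'
#' Canonical cohort form: one row per historical source with columns
#' `source_id`, `n`, `mean`, and optionally `sd` (filled with `NA` when
#' absent) and a `values` list-column of patient-level outcomes. When
#' `values` is present its length, mean and sd must agree with the stored
#' summaries.
#'
#' @param x A data frame of cohort summaries.
#' @return A validated tibble with columns `source_id`, `n`, `mean`, `sd`
#'   (and `values` if supplied).
#' @examples
#' as_historical_cohorts(data.frame(source_id = "a", n = 100, mean = 0.3))
#' @export
as_historical_cohorts <- function(x) {
  validate_cohorts(x)
}

validate_cohorts <- function(x) {
  if (!is.data.frame(x)) {
    abort("Cohorts must be supplied as a data frame.",
          class = "threshtrial_config_error")
  }
  x <- as_tibble(x)
  needed <- c("n", "mean")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Cohort table lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "threshtrial_config_error")
  }
  if (!"source_id" %in% names(x)) {
    x$source_id <- paste0("cohort_", seq_len(nrow(x)))
  }
  if (!"sd" %in% names(x)) {
    x$sd <- NA_real_
  }
  if (nrow(x) == 0L) {
    abort("At least one historical cohort is required.",
          class = "threshtrial_config_error")
  }
  if (any(!is.finite(x$n) | x$n < 1 | abs(x$n - round(x$n)) > 1e-8)) {
    abort("Cohort sizes `n` must be integers >= 1.",
          class = "threshtrial_config_error")
  }
  x$n <- as.integer(round(x$n))
  if (any(!is.na(x$sd) & x$sd < 0)) {
    abort("Cohort `sd` must be >= 0.", class = "threshtrial_config_error")
  }
  if ("values" %in% names(x)) {
    for (i in seq_len(nrow(x))) {
      v <- x$values[[i]]
      if (is.null(v)) next
      if (length(v) != x$n[i]) {
        abort(sprintf("Cohort %s: %d patient-level values but n = %d.",
                      dQuote(x$source_id[i]), length(v), x$n[i]),
              class = "threshtrial_parse_error")
      }
      if (abs(mean(v) - x$mean[i]) > 1e-6 ||
          (!is.na(x$sd[i]) && length(v) > 1L && abs(sd(v) - x$sd[i]) > 1e-6)) {
        abort(sprintf("Cohort %s: stored summaries disagree with patient-level values.",
                      dQuote(x$source_id[i])),
              class = "threshtrial_parse_error")
      }
    }
  }
  dplyr::relocate(x, "source_id", "n", "mean", "sd")
}

#' Pool historical control cohorts into one estimate of the control mean
#'
#' Inverse-variance pooling of several historical control cohorts, giving a
#' single meta-analytic estimate of the historical control mean that the
#' threshold rules can consume.
#'
#' Each cohort's sampling variance is `sd_i^2 / n_i`, using the observed
#' `sd` when present and the planning `sigma` otherwise. The fixed-effect
#' pool weights by the inverse of that variance. The random-effects pool
#' adds a between-source variance `tau2` estimated by DerSimonian-Laird:
#' \deqn{Q = \sum w_i (\bar y_i - \hat\mu_{FE})^2,\quad
#'  \tau^2 = \max\!\left(0, \frac{Q - (k-1)}{\sum w_i - \sum w_i^2/\sum w_i}\right),}
#' then re-weights by `1 / (sd_i^2/n_i + tau2)`. With a single cohort the
#' random-effects pool falls back to the fixed-effect result.
#'
#' The `effective_n` component, `sigma^2 / se^2`, expresses the pooled
#' precision on the patient-count scale and is what [pooled_to_cohort()]
#' hands to the threshold rules.
#'
#' @param cohorts A cohort tibble (see [as_historical_cohorts()]).
#' @param method `"fixed"` or `"random"`.
#' @param sigma Planning standard deviation used for cohorts without an
#'   observed `sd` and for the `effective_n` scale.
#' @return An object of class `pooled_controls`: `estimate`, `se`, `tau2`,
#'   `Q`, `method`, `k`, `effective_n`, `sigma`, plus the per-cohort table
#'   with weights (see [tidy.pooled_controls()]).
#' @examples
#' cohorts <- tibble::tibble(
#'   source_id = c("trial_A", "registry_B"),
#'   n = c(100, 100), mean = c(0.0, 0.4), sd = c(1, 1)
#' )
#' pool_controls(cohorts, "fixed")
#' pool_controls(cohorts, "random") # DL: tau2 = 0.07, se = 0.2
#' @export
pool_controls <- function(cohorts, method = c("fixed", "random"), sigma = 1) {
  method <- match.arg(method)
  check_number(sigma, "sigma", lower = 0, strict = TRUE)
  cohorts <- validate_cohorts(cohorts)
  sd_i <- ifelse(!is.na(cohorts$sd) & cohorts$sd > 0, cohorts$sd, sigma)
  vi <- sd_i^2 / cohorts$n
  w <- 1 / vi
  k <- nrow(cohorts)
  fe_est <- sum(w * cohorts$mean) / sum(w)
  Q <- sum(w * (cohorts$mean - fe_est)^2)
  if (method == "fixed" || k == 1L) {
    tau2 <- 0
    w_star <- w
  } else {
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (vi + tau2)
  }
  estimate <- sum(w_star * cohorts$mean) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  structure(
    list(
      estimate = estimate, se = se, tau2 = tau2, Q = Q,
      method = method, k = k,
      effective_n = sigma^2 / se^2, sigma = sigma,
      cohorts = dplyr::mutate(cohorts, vi = vi, weight = w_star / sum(w_star))
    ),
    class = "pooled_controls"
  )
}

#' @export
print.pooled_controls <- function(x, ...) {
  cat(sprintf("<pooled_controls> %s-effect pool of %d cohort(s)\n",
              x$method, x$k))
  cat(sprintf("  estimate = %.5f  (se = %.5f)\n", x$estimate, x$se))
  if (x$method == "random") {
    cat(sprintf("  tau2 = %.5f  (Q = %.4f)\n", x$tau2, x$Q))
  }
  cat(sprintf("  effective n = %.1f\n", x$effective_n))
  invisible(x)
}

#' Convert a pooled estimate into a synthetic single-cohort summary
#'
#' Adapter so the threshold rules, which expect one cohort's `mean` and `n`,
#' can consume a meta-analytic pool: the synthetic cohort carries the pooled
#' mean and `n = floor(effective_n)` (at least 1; flooring is conservative,
#' widening the CI-based thresholds).
#'
#' @param pool A [pool_controls()] result.
#' @return A one-row cohort tibble tagged `pooled(fixed)` or
#'   `pooled(random)`.
#' @examples
#' cohorts <- tibble::tibble(n = 100, mean = 0.3, sd = 1)
#' pooled_to_cohort(pool_controls(cohorts))
#' @export
pooled_to_cohort <- function(pool) {
  stopifnot(inherits(pool, "pooled_controls"))
  tibble(
    source_id = sprintf("pooled(%s)", pool$method),
    n = max(1L, as.integer(floor(pool$effective_n + 1e-9))),
    mean = pool$estimate,
    sd = NA_real_
  )
}

#' @describeIn pool_controls Per-cohort table with sampling variances and
#'   normalized pooling weights.
#' @param x A `pooled_controls` object.
#' @param ... Unused.
#' @export
tidy.pooled_controls <- function(x, ...) {
  x$cohorts
}

#' @describeIn pool_controls One-row summary: `estimate`, `se`, `tau2`, `Q`,
#'   `method`, `k`, `effective_n`.
#' @export
glance.pooled_controls <- function(x, ...) {
  tibble(
    estimate = x$estimate, se = x$se, tau2 = x$tau2, Q = x$Q,
    method = x$method, k = x$k, effective_n = x$effective_n
  )
}
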