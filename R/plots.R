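#' Plot operating-characteristic curves against historical sample size
#'
#' Line plot of a Monte Carlo metric (or the planned trial size) versus the
#' historical control size, one curve per threshold rule, with the two-arm
#' reference shown as a flat line. Facets over `drift` and `true_delta`
#' when the grid varies them.
#'
#' @param oc An [oc_grid()] result.
#' @param metric Column to plot: `"rejection_rate"` (default),
#'   `"planned_n"`, or `"exact"`.
#' @param show_exact Overlay the closed-form oracle as a dashed line when
#'   plotting `rejection_rate`.
#' @return A ggplot object.
#' @examples
#' oc <- oc_grid(design_params(), n_h = c(100, 400, 1000),
#'               n_reps_null = 1000, n_reps_power = 1000, seed = 1)
#' plot_oc(oc)
#' plot_oc(oc, metric = "planned_n")
#' @export
plot_oc <- function(oc, metric = c("rejection_rate", "planned_n", "exact"),
                    show_exact = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(oc), metric %in% names(oc))
  oc <- dplyr::mutate(oc, design = dplyr::case_when(
    .data$rule == "two_arm" ~ "parallel group",
    .data$rule == "naive_mean" ~ "naive mean",
    .data$rule == "ci_upper" ~ "CI upper",
    TRUE ~ sprintf("CI upper + %g delta", .data$c)
  ))
  p <- ggplot2::ggplot(
    dplyr::filter(oc, .data$feasible),
    ggplot2::aes(x = .data$n_h, y = .data[[metric]],
                 colour = .data$design, group = .data$design)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "historical control sample size",
      y = switch(metric,
        rejection_rate = "Monte Carlo rejection probability",
        planned_n = "planned trial size (total patients)",
        exact = "exact rejection probability"
      ),
      colour = "design"
    ) +
    ggplot2::theme_minimal()
  if (metric == "rejection_rate" && show_exact) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$exact), linetype = "dashed", alpha = 0.6
    )
  }
  facets <- c(
    if (length(unique(oc$drift)) > 1L) "drift",
    if (length(unique(oc$true_delta)) > 1L) "true_delta"
  )
  if (length(facets) > 0L) {
    p <- p + ggplot2::facet_grid(
      rows = if (length(facets) == 2L) ggplot2::vars(.data$drift) else NULL,
      cols = ggplot2::vars(.data[[facets[length(facets)]]]),
      labeller = ggplot2::label_both
    )
  }
  p
}

#' Forest-style plot of a pooled historical control estimate
#'
#' Per-cohort means with gamma-level confidence whiskers and the pooled
#' estimate as a highlighted bottom row.
#'
#' @param object A [pool_controls()] result.
#' @param gamma Two-sided confidence level for the whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cohorts <- tibble::tibble(
#'   source_id = c("A", "B", "C"), n = c(120, 80, 200),
#'   mean = c(0.05, 0.22, 0.11), sd = c(1, 1, 1)
#' )
#' autoplot(pool_controls(cohorts, "random"))
#' @export
autoplot.pooled_controls <- function(object, gamma = 0.95, ...) {
  z <- qnorm((1 + gamma) / 2)
  rows <- tidy(object) |>
    dplyr::mutate(se = sqrt(.data$vi), kind = "cohort")
  pooled <- tibble(
    source_id = sprintf("pooled (%s)", object$method),
    mean = object$estimate, se = object$se, weight = 1, kind = "pooled"
  )
  dat <- dplyr::bind_rows(rows[, c("source_id", "mean", "se", "weight", "kind")],
                          pooled) |>
    dplyr::mutate(source_id = factor(.data$source_id,
                                     levels = rev(unique(.data$source_id))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean, y = .data$source_id,
                                    colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - z * .data$se,
                   xmax = .data$mean + z * .data$se),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight)) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "control mean (endpoint units)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
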