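test_that("simulated cohorts and trials are reproducible and self-consistent", {
  a <- simulate_historical_cohort(250, mu = 0.1, sigma = 1, seed = 42)
  b <- simulate_historical_cohort(250, mu = 0.1, sigma = 1, seed = 42)
  expect_identical(a, b)
  expect_identical(a$n, 250L)
  expect_equal(a$mean, mean(a$values[[1]]))
  expect_equal(a$sd, sd(a$values[[1]]))

  t1 <- simulate_trial(100, mu = 0.2, seed = 7)
  t2 <- simulate_trial(100, mu = 0.2, seed = 7)
  expect_identical(t1, t2)
  expect_identical(simulate_trial(1, mu = 0, seed = 3)$sd, 0)

  # near-degenerate noise collapses onto the true mean
  tiny <- simulate_historical_cohort(50, mu = 0.3, sigma = 1e-12, seed = 5)
  expect_equal(tiny$mean, 0.3, tolerance = 1e-10)
  expect_equal(tiny$sd, 0, tolerance = 1e-10)
})

test_that("large simulated samples concentrate at the true mean", {
  big <- simulate_historical_cohort(1e6, mu = 0, sigma = 1, seed = 11)
  expect_lt(abs(big$mean), 0.005)
  trial <- simulate_trial(1e6, mu = 0.2, sigma = 1, seed = 12)
  expect_lt(abs(trial$mean - 0.2), 0.005)
})

test_that("Monte Carlo cells agree with the closed-form oracle", {
  cells <- tidyr::expand_grid(
    rules = list(
      threshold_rule("naive_mean"),
      threshold_rule("ci_upper"),
      threshold_rule("ci_upper_plus", c = 0.2)
    ),
    n_h = c(200L, 1000L),
    true_delta = c(0, 0.2),
    drift = c(0, 0.1)
  )
  for (i in seq_len(nrow(cells))) {
    oc <- estimate_oc(
      ref_params, cells$rules[[i]], n_h = cells$n_h[i],
      true_delta = cells$true_delta[i], drift = cells$drift[i],
      n_reps = 2e4, seed = 2024
    )
    expect_true(oc$feasible)
    expect_lte(abs(oc$rejection_rate - oc$exact),
               4 * max(oc$mc_se, 5e-4))
  }
})

test_that("cells reproduce exactly and are independent of the grid layout", {
  a <- estimate_oc(ref_params, "ci", n_h = 500, n_reps = 5000, seed = 9)
  b <- estimate_oc(ref_params, "ci", n_h = 500, n_reps = 5000, seed = 9)
  expect_identical(a, b)
  # the same cell inside a larger grid gives the same number
  g <- oc_grid(ref_params,
               rules = tibble::tibble(rule = "ci_upper", gamma = 0.95, c = 0),
               n_h = c(250L, 500L), true_delta = 0,
               n_reps_null = 5000, two_arm = FALSE, seed = 9)
  expect_equal(
    dplyr::filter(g, n_h == 500)$rejection_rate,
    a$rejection_rate
  )
  expect_false(identical(
    estimate_oc(ref_params, "ci", n_h = 500, n_reps = 5000, seed = 10)$rejection_rate,
    a$rejection_rate
  ))
})

test_that("the problem is location invariant", {
  # an identical sub-stream shifted by mu_hist gives identical rejections
  a <- estimate_oc(ref_params, "naive", n_h = 100, mu_hist = 0,
                   n_reps = 5000, seed = 31)
  b <- estimate_oc(ref_params, "naive", n_h = 100, mu_hist = 5,
                   n_reps = 5000, seed = 31)
  expect_equal(a$rejection_rate, b$rejection_rate)
})

test_that("the grid keeps two-arm references flat and flags infeasible cells", {
  g <- oc_grid(
    ref_params,
    n_h = c(50L, 100L, 1000L), true_delta = c(0, 0.2),
    n_reps_null = 5000, n_reps_power = 5000, seed = 3
  )
  two <- dplyr::filter(g, rule == "two_arm")
  per_cell <- dplyr::summarise(
    dplyr::group_by(two, true_delta),
    distinct = dplyr::n_distinct(rejection_rate), .groups = "drop"
  )
  expect_true(all(per_cell$distinct == 1L))

  # CI-based rules cannot be planned with too few historical controls
  infeas <- dplyr::filter(g, rule != "naive_mean", rule != "two_arm",
                          n_h == 50L)
  expect_true(all(!infeas$feasible))
  expect_true(all(is.na(infeas$planned_n)))
  feas <- dplyr::filter(g, rule == "naive_mean" | rule == "two_arm")
  expect_true(all(feas$feasible))

  # planned single-arm size falls as historical data accrue
  ci_rows <- dplyr::filter(g, rule == "ci_upper", true_delta == 0, feasible)
  ci_rows <- dplyr::arrange(ci_rows, n_h)
  expect_true(all(diff(ci_rows$planned_n) <= 0))

  # the whole grid reproduces byte-identically
  g2 <- oc_grid(
    ref_params,
    n_h = c(50L, 100L, 1000L), true_delta = c(0, 0.2),
    n_reps_null = 5000, n_reps_power = 5000, seed = 3
  )
  expect_identical(g, g2)
})

test_that("drift inflates the naive design's type-I error but not the RCT's", {
  no_drift <- estimate_oc(ref_params, "naive", n_h = 1000, drift = 0,
                          n_reps = 2e4, seed = 17)
  drifted <- estimate_oc(ref_params, "naive", n_h = 1000, drift = 0.1,
                         n_reps = 2e4, seed = 17)
  expect_gt(drifted$exact, no_drift$exact)
  expect_gt(drifted$rejection_rate,
            ref_params$alpha + 4 * drifted$mc_se)
  # concurrent controls drift with the experimental arm: level unchanged
  rct <- two_arm_oc(ref_params, true_delta = 0, mu_ctrl = 0.1,
                    n_reps = 2e4, seed = 17)
  expect_lte(abs(rct$rejection_rate - ref_params$alpha), 4 * rct$mc_se)
})
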