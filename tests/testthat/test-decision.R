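test_that("trial outcomes classify into the three decision zones", {
  dt <- decision_thresholds(efficacy_t = 0.06, futility_f = 0)
  # lower confidence bound clears the threshold: effective
  expect_identical(
    classify_outcome(list(n = 400L, mean = 0.30), dt, ref_params),
    "effective"
  )
  # point estimate below futility: ineffective
  expect_identical(
    classify_outcome(list(n = 400L, mean = -0.05), dt, ref_params),
    "ineffective"
  )
  # in between (mean at t, wide CI): promising
  expect_identical(
    classify_outcome(list(n = 20L, mean = 0.06), dt, ref_params),
    "promising"
  )
  # bound rule is equivalent to the one-sample z-test
  for (m in c(0.0, 0.1, 0.2, 0.3)) {
    trial <- list(n = 197L, mean = m)
    expect_identical(
      classify_outcome(trial, dt, ref_params) == "effective",
      one_sample_z_test(m, 197, dt$efficacy_t, ref_params)$reject
    )
  }
  # point-estimate variant only needs the mean to cross
  expect_identical(
    classify_outcome(list(n = 20L, mean = 0.07), dt, ref_params,
                     criterion = "point"),
    "effective"
  )
  expect_error(decision_thresholds(0.1, 0.2),
               class = "threshtrial_config_error")
})

test_that("stage-1 outcome probabilities always sum to one", {
  for (td in c(0, 0.1, 0.2)) {
    pr <- simulate_program(ref_params, "ci", n_h = 400, true_delta = td,
                           n_reps = 4000, seed = 5)
    expect_equal(pr$p_effective + pr$p_promising + pr$p_ineffective, 1)
    expect_gte(pr$p_positive, pr$p_effective)
  }
})

test_that("degenerate thresholds make every trial promising and terminal", {
  pr <- simulate_program(
    ref_params, threshold_rule("ci_upper_plus", c = 1e3),
    n_h = 1e8, true_delta = 0.2, futility = "none", stage2 = "none",
    n = 200, n_reps = 2000, seed = 8, mu_hist = 0
  )
  # an absurdly inflated threshold is never crossed, nothing is futile
  expect_equal(pr$p_promising, 1)
  expect_equal(pr$p_positive, 0)
  # under plan "none" the expected sample size is the stage-1 size
  expect_equal(pr$expected_n, pr$stage1_n)
})

test_that("a futility bar at the critical mean collapses the flow to one stage", {
  pr <- simulate_program(ref_params, "ci", n_h = 1000, true_delta = 0.1,
                         futility = "efficacy_bound", stage2 = "rct",
                         n_reps = 2e4, seed = 13)
  expect_equal(pr$p_promising, 0)
  oracle <- rejection_probability("ci", 1000, pr$stage1_n, ref_params,
                                  true_delta = 0.1)
  expect_lte(abs(pr$p_effective - oracle),
             4 * sqrt(oracle * (1 - oracle) / pr$n_reps))
  expect_equal(pr$expected_n, pr$stage1_n)
})

test_that("the two-stage false-positive rate respects the union bound", {
  pr <- simulate_program(ref_params, "ci", n_h = 1000, true_delta = 0,
                         drift = 0, stage2 = "rct", n_reps = 1e5, seed = 21)
  # stage 1 is conservative (<= alpha) and stage 2 adds at most alpha
  bound <- 0.025 + 0.025
  expect_lte(pr$p_positive, bound + 4 * sqrt(bound * (1 - bound) / pr$n_reps))
  # second single-arm stage against the same random threshold
  pr2 <- simulate_program(ref_params, "ci", n_h = 1000, true_delta = 0,
                          stage2 = "single_arm", n_reps = 1e5, seed = 22)
  expect_lte(pr2$p_positive,
             bound + 4 * sqrt(bound * (1 - bound) / pr2$n_reps))
})

test_that("with ample historical data stage-1 efficacy approaches the design power", {
  pr <- simulate_program(ref_params, "ci", n_h = 1e7, true_delta = 0.2,
                         n_reps = 2e4, seed = 34)
  oracle <- rejection_probability("ci", 1e7, pr$stage1_n, ref_params,
                                  true_delta = 0.2)
  expect_gte(oracle, ref_params$power)
  expect_lte(abs(pr$p_effective - oracle),
             4 * sqrt(oracle * (1 - oracle) / pr$n_reps))
  # overall positive probability grows with the true effect
  p_by_delta <- vapply(c(0, 0.1, 0.2), function(td) {
    simulate_program(ref_params, "ci", n_h = 1000, true_delta = td,
                     n_reps = 1e4, seed = 35)$p_positive
  }, numeric(1))
  expect_true(all(diff(p_by_delta) > 0))
})
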