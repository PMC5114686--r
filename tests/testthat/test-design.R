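test_that("sample-size formulas reproduce the closed-form values", {
  expect_identical(parallel_group_size(ref_params), 393L)
  expect_identical(single_arm_size(0.2), 197L)
  # huge effects need minimal patients
  expect_identical(single_arm_size(4), 1L)
  expect_identical(parallel_group_size(design_params(delta = 4)), 1L)
  # ceiling never drops below the real-valued formula
  z2 <- (qnorm(0.975) + qnorm(0.8))^2
  expect_gte(parallel_group_size(ref_params), 2 * z2 / 0.04)
  expect_gte(single_arm_size(0.2), z2 / 0.04)
})

test_that("sample sizes respond monotonically to delta, power, and alpha", {
  deltas <- c(0.1, 0.2, 0.3, 0.5)
  n_by_delta <- vapply(deltas, function(d) {
    parallel_group_size(design_params(delta = d))
  }, integer(1))
  expect_true(all(diff(n_by_delta) < 0))

  powers <- c(0.7, 0.8, 0.9, 0.95)
  n_by_power <- vapply(powers, function(p) {
    single_arm_size(0.2, power = p)
  }, integer(1))
  expect_true(all(diff(n_by_power) > 0))

  alphas <- c(0.1, 0.05, 0.025, 0.01)
  n_by_alpha <- vapply(alphas, function(a) {
    single_arm_size(0.2, alpha = a)
  }, integer(1))
  expect_true(all(diff(n_by_alpha) > 0))
})

test_that("nearest-hundred reporting matches the headline sizes", {
  expect_identical(round_hundred(393), 400L)
  expect_identical(round_hundred(2 * 393), 800L)
  expect_identical(round_hundred(197), 200L)
  expect_identical(round_hundred(413), 400L)
})

test_that("threshold rules place t as specified", {
  hist <- tibble::tibble(source_id = "h", n = 1000L, mean = 0, sd = NA_real_)
  expect_identical(compute_threshold(hist, "naive", ref_params)$t, 0)
  expect_equal(compute_threshold(hist, "ci", ref_params)$t,
               qnorm(0.975) / sqrt(1000), tolerance = 1e-12)
  expect_equal(compute_threshold(hist, "ci", ref_params)$t, 0.06198,
               tolerance = 1e-4)
  expect_equal(compute_threshold(hist, "ci+0.2", ref_params)$t, 0.10198,
               tolerance = 1e-4)
  # c = 0 reduces the inflated rule to the plain CI rule
  expect_identical(
    compute_threshold(hist, threshold_rule("ci_upper_plus", c = 0), ref_params)$t,
    compute_threshold(hist, "ci", ref_params)$t
  )
  # CI-based t never falls below the historical mean
  for (n_h in c(5L, 50L, 5000L)) {
    h <- tibble::tibble(n = n_h, mean = -0.3)
    expect_gte(compute_threshold(h, "ci", ref_params)$t, h$mean)
  }
  expect_error(compute_threshold(tibble::tibble(n = 10L, mean = NA_real_),
                                 "naive", ref_params),
               class = "threshtrial_config_error")
})

test_that("planned trial size accounts for the CI half-width", {
  expect_identical(planned_trial_size("ci", 1000, ref_params), 413L)
  # the rule can consume the whole assumed effect
  expect_error(planned_trial_size("ci", 96, ref_params),
               class = "threshtrial_infeasible_error")
  expect_error(single_arm_size(0), class = "threshtrial_infeasible_error")
  # non-increasing in n_h, converging to the naive single-arm size
  sizes <- vapply(c(150, 400, 1000, 1e4, 1e8), function(nh) {
    planned_trial_size("ci", nh, ref_params)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_identical(sizes[length(sizes)], single_arm_size(0.2))
  expect_identical(planned_trial_size("naive", 50, ref_params),
                   single_arm_size(0.2))
})

test_that("one- and two-sample z-tests match hand-computed statistics", {
  # boundary: mean equal to the threshold never rejects
  expect_false(one_sample_z_test(0.1, 50, 0.1, ref_params)$reject)
  crit_mean <- 0.06 + qnorm(0.975) / sqrt(197)
  expect_true(one_sample_z_test(crit_mean + 1e-6, 197, 0.06, ref_params)$reject)
  expect_false(one_sample_z_test(crit_mean, 197, 0.06, ref_params)$reject)
  res <- one_sample_z_test(0.16, 197, 0.06, ref_params)
  expect_equal(res$statistic, 1.4036, tolerance = 1e-4)
  expect_false(res$reject)

  res2 <- two_sample_z_test(0.2, 393, 0, 393, ref_params)
  expect_equal(res2$statistic, 2.8035, tolerance = 1e-4)
  expect_true(res2$reject)
  res3 <- two_sample_z_test(0.05, 393, 0, 393, ref_params)
  expect_equal(res3$statistic, 0.7009, tolerance = 1e-4)
  expect_false(res3$reject)
  expect_false(two_sample_z_test(0.3, 100, 0.3, 100, ref_params)$reject)
})

test_that("the closed-form oracle reproduces its reference values", {
  # with infinite historical data the naive threshold is the true mean
  expect_equal(rejection_probability("naive", 1e12, 197, ref_params),
               0.025, tolerance = 1e-6)
  expect_equal(rejection_probability("naive", 100, 197, ref_params),
               0.1277, tolerance = 1e-4)
  expect_equal(rejection_probability("ci", 100, 197, ref_params),
               0.00313, tolerance = 1e-3)
  expect_equal(
    rejection_probability("naive", 1000, 197, ref_params, drift = 0.05),
    0.1251, tolerance = 1e-3
  )
})

test_that("the CI-upper rule controls the type-I error at every grid point", {
  grid <- expand.grid(n_h = c(10, 30, 100, 500, 1000, 5000),
                      n = c(10, 100, 413, 2000))
  p <- rejection_probability("ci", grid$n_h, grid$n, ref_params)
  expect_true(all(p <= ref_params$alpha + 1e-12))
})

test_that("the oracle is monotone in effect, drift, inflation, and n_h", {
  deltas <- seq(0, 0.4, by = 0.05)
  p_delta <- rejection_probability("ci", 500, 413, ref_params,
                                   true_delta = deltas)
  expect_true(all(diff(p_delta) > 0))

  drifts <- seq(-0.1, 0.2, by = 0.05)
  p_drift <- rejection_probability("naive", 500, 197, ref_params,
                                   drift = drifts)
  expect_true(all(diff(p_drift) > 0))

  p_c <- vapply(c(0, 0.1, 0.2, 0.3), function(cc) {
    rejection_probability(threshold_rule("ci_upper_plus", c = cc),
                          1000, 413, ref_params, true_delta = 0.2)
  }, numeric(1))
  expect_true(all(diff(p_c) < 0))

  # naive type-I error shrinks toward alpha as historical data accrue
  p_nh <- rejection_probability("naive", c(50, 100, 500, 1000, 1e5), 197,
                                ref_params)
  expect_true(all(diff(p_nh) < 0))
  expect_true(all(p_nh > ref_params$alpha))
})

test_that("the two-arm design meets its target power at the planned size", {
  n <- parallel_group_size(ref_params)
  expect_gte(two_arm_power(n, ref_params, true_delta = 0.2), 0.80)
  expect_equal(two_arm_power(n, ref_params, true_delta = 0), 0.025,
               tolerance = 1e-12)
})
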