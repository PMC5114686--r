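# Reference planning scenario used throughout the tests: normal endpoint,
# sigma 1, standardized effect 0.2, one-sided alpha 2.5%, 80% power.
ref_params <- design_params(delta = 0.2, sigma = 1, alpha = 0.025, power = 0.80)

# Two equal cohorts with means 0 and 0.4: the hand-workable DerSimonian-Laird
# example (Q = 8, tau2 = 0.07, pooled se = 0.2).
dl_cohorts <- tibble::tibble(
  source_id = c("trial_A", "registry_B"),
  n = c(100L, 100L), mean = c(0.0, 0.4), sd = c(1, 1)
)

make_cohorts <- function(k, seed = 99, n_range = c(50L, 300L),
                         mu = 0.1, tau = 0.1, sigma = 1) {
  withr::with_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
    tibble::tibble(
      source_id = sprintf("src_%02d", seq_len(k)),
      n = n,
      mean = rnorm(k, mu, tau),
      sd = runif(k, 0.8, 1.2) * sigma
    )
  })
}
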