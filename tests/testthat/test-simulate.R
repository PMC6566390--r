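test_that("the simulator is seed-deterministic and leaves the RNG alone", {
  a <- simulate_two_sample(seed = 5)
  b <- simulate_two_sample(seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c2 <- simulate_two_sample(seed = 6)
  expect_false(identical(a$beta_exposure, c2$beta_exposure))
  # the global RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_two_sample(seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("the noiseless limit returns the causal effect exactly everywhere", {
  set <- simulate_two_sample(n_snps = 6, causal_effect = 0.5,
                             se_exposure = 0, se_outcome = 0, seed = 2)
  r <- wald_ratios(set)
  expect_equal(r$beta, rep(0.5, 6))
  expect_equal(mr_ivw(set)$beta, 0.5)
  expect_equal(mr_ivw(set)$Q, 0, tolerance = 1e-12)
  expect_equal(mr_egger(set)$beta, 0.5, tolerance = 1e-6)
  expect_equal(mr_egger(set)$intercept$beta, 0, tolerance = 1e-8)
  expect_equal(mr_weighted_median(set, n_boot = 10, seed = 1)$beta, 0.5)
  expect_equal(mr_mode(set, n_boot = 10, seed = 1)$beta, 0.5,
               tolerance = 1e-6)
})

test_that("generated fields satisfy their invariants", {
  sim <- simulate_two_sample(n_snps = 20, allele_model = TRUE, seed = 4,
                             invalid_fraction = 0.5, pleiotropy_sd = 0.01)
  expect_true(all(sim$exposure$se > 0))
  expect_true(all(sim$outcome$se > 0))
  expect_true(all(sim$exposure$eaf > 0 & sim$exposure$eaf < 1))
  expect_true(all(sim$outcome$eaf > 0 & sim$outcome$eaf < 1))
  truth <- attr(sim$harmonized, "truth")
  expect_equal(sum(truth$invalid), 10)
  expect_true(all(truth$pleiotropy[!truth$invalid] == 0))
})

test_that("allele-labelled output round-trips through harmonization", {
  for (seed in c(1, 2, 3)) {
    sim <- simulate_two_sample(n_snps = 10, causal_effect = 0.2,
                               allele_model = TRUE, seed = seed)
    set <- harmonize(sim$exposure, sim$outcome)
    cols <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
              "se_outcome")
    expect_equal(tibble::as_tibble(set)[cols],
                 tibble::as_tibble(sim$harmonized)[cols],
                 ignore_attr = TRUE)
    # flips in the audit log match the orientation the generator used
    expect_equal(sum(set$orientation_flipped) > 0,
                 any(mr_audit(set)$action == "flipped"))
  }
})

test_that("the IVW z-statistic is standard normal under the sharp null", {
  n_rep <- 400
  z <- vapply(seq_len(n_rep), function(r) {
    set <- simulate_two_sample(causal_effect = 0, seed = 1000 + r)
    fit <- mr_ivw(set)
    fit$beta / fit$se
  }, numeric(1))
  expect_lt(abs(mean(z)), 3 / sqrt(n_rep))
  # flooring makes the SE conservative, so |z| has sd at or below 1
  expect_lt(sd(z), 1.1)
  expect_gt(sd(z), 0.8)
})

test_that("recovery experiments report calibrated IVW estimates", {
  rep_tab <- recovery_experiment(n_reps = 200, methods = "ivw",
                                 causal_effect = 0.1, seed = 77)
  expect_equal(rep_tab$method, "ivw")
  expect_lt(abs(rep_tab$bias), 3 * rep_tab$mc_se)
  expect_gt(rep_tab$ci_coverage, 0.9)
  expect_equal(rep_tab$rmse^2,
               rep_tab$bias^2 + rep_tab$empirical_se^2 * (199 / 200),
               tolerance = 1e-10)
})

test_that("directional pleiotropy biases IVW but not the Egger slope", {
  # large J and small SEs: the asymptotic regime where Egger is unbiased
  rep_tab <- recovery_experiment(
    n_reps = 100, methods = c("ivw", "egger"), causal_effect = 0.1,
    n_snps = 40, se_exposure = 5e-4, se_outcome = 5e-4,
    pleiotropy_mean = 0.005, pleiotropy_sd = 0.002, invalid_fraction = 1,
    seed = 42)
  ivw_row <- rep_tab[rep_tab$method == "ivw", ]
  egger_row <- rep_tab[rep_tab$method == "egger", ]
  expect_gt(ivw_row$bias, 3 * ivw_row$mc_se)       # biased upward
  expect_lt(abs(egger_row$bias), 3 * egger_row$mc_se)
})

test_that("simulator and experiment configs are validated", {
  expect_error(simulate_two_sample(seed = 1, invalid_fraction = 2),
               "invalid_fraction")
  expect_error(simulate_two_sample(seed = 1, n_snps = 0), "n_snps")
  expect_error(simulate_two_sample(n_snps = 3), "seed")
  expect_error(recovery_experiment(n_reps = 1, seed = 1), "n_reps")
  expect_error(recovery_experiment(n_reps = 5, methods = "magic", seed = 1),
               "unknown method")
})
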