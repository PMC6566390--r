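ds <- mr_fixture("vitd_ds")

test_that("Wald ratios reproduce the published per-variant DS rows", {
  r <- wald_ratios(ds)
  i <- which(r$snp == "rs17216707")
  expect_equal(r$beta[i], -0.1538, tolerance = 1e-3)
  expect_equal(r$se[i], 0.1538, tolerance = 1e-3)
  expect_equal(round(r$pval[i], 3), 0.317)
  j <- which(r$snp == "rs8018720")
  expect_equal(round(r$beta[j], 4), -0.0588)
  expect_equal(round(r$se[j], 4), 0.2941)
  # a zero outcome effect gives a zero ratio with p exactly 1
  k <- which(r$snp == "rs10745742")
  expect_equal(r$beta[k], 0)
  expect_equal(r$pval[k], 1)
})

test_that("a zero exposure effect is an undefined-ratio error naming the SNP", {
  x <- tibble::tibble(snp = c("rs_ok", "rs_bad"),
                      beta_exposure = c(0.1, 0), se_exposure = 0.01,
                      beta_outcome = 0.01, se_outcome = 0.01)
  expect_error(wald_ratios(x), "rs_bad")
})

test_that("IVW matches the published DS and BD combined rows", {
  fit <- mr_ivw(ds)
  expect_equal(round(fit$beta, 4), 0.0246)
  expect_equal(round(fit$se, 4), 0.0384)
  expect_equal(round(fit$pval, 3), 0.521)
  expect_equal(fit$residual_scale, 1)  # DS set is underdispersed; floored

  bd <- mr_ivw(mr_fixture("vitd_bd_ratios"))
  expect_equal(round(bd$beta, 4), -0.0202)
  expect_equal(round(bd$pval, 3), 0.099)
})

test_that("IVW with a single instrument is the Wald ratio", {
  one <- ds[3, ]
  fit <- mr_ivw(one)
  r <- wald_ratios(one)
  expect_equal(fit$beta, r$beta)
  expect_equal(fit$se, r$se)
  expect_equal(fit$residual_scale, 1)
  expect_equal(fit$n_snps, 1)
  expect_error(mr_ivw(tibble::tibble(beta = numeric(), se = numeric())),
               "at least one")
})

test_that("IVW as weighted mean of ratios equals the zero-intercept WLS slope", {
  for (seed in 1:20) {
    x <- random_set(sample(3:10, 1), seed)
    fit <- mr_ivw(x)
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = x,
              weights = 1 / x$se_outcome^2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-10)
    # dispersion floor: never narrower than the fixed-effect SE
    w <- 1 / (x$se_outcome / abs(x$beta_exposure))^2
    expect_gte(fit$se, sqrt(1 / sum(w)) - 1e-12)
  }
})

test_that("Wald ratios are invariant under joint negation of both betas", {
  x <- random_set(6, 11)
  flipped <- dplyr::mutate(x, beta_exposure = -beta_exposure,
                           beta_outcome = -beta_outcome)
  expect_equal(wald_ratios(flipped), wald_ratios(x))
})

test_that("MR-Egger reproduces the published DS slope and intercept", {
  fit <- mr_egger(ds)
  expect_equal(round(fit$beta, 4), 0.0209)
  expect_equal(round(fit$se, 4), 0.0674)
  expect_equal(round(fit$pval, 3), 0.772)
  expect_equal(fit$df, 4)
  expect_equal(round(fit$intercept$beta, 4), 0.0002)
  expect_equal(round(fit$intercept$pval, 3), 0.949)
  # the floor is what yields 0.0674; the unfloored dispersion is < 1
  expect_equal(fit$residual_scale, 1)
})

test_that("MR-Egger needs at least three instruments", {
  expect_error(mr_egger(ds[1:2, ]), "at least 3")
})

test_that("exactly collinear points through the origin recover slope and zero intercept", {
  x <- tibble::tibble(snp = c("a", "b", "c"),
                      beta_exposure = c(0.02, 0.05, 0.08),
                      se_exposure = 0.001,
                      beta_outcome = 0.5 * c(0.02, 0.05, 0.08),
                      se_outcome = 0.01)
  fit <- mr_egger(x)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$beta, 0, tolerance = 1e-12)
  expect_equal(fit$residual_scale, 1)
  expect_equal(mr_ivw(x)$beta, fit$beta, tolerance = 1e-10)
})

test_that("MR-Egger is invariant to pre-orienting any subset", {
  ref <- mr_egger(ds)
  for (seed in 1:5) {
    flip <- withr::with_seed(seed, sample(c(TRUE, FALSE), nrow(ds), TRUE))
    x <- tibble::as_tibble(ds)
    x$beta_exposure[flip] <- -x$beta_exposure[flip]
    x$beta_outcome[flip] <- -x$beta_outcome[flip]
    fit <- mr_egger(x)
    expect_equal(fit$beta, ref$beta)
    expect_equal(fit$intercept$beta, ref$intercept$beta)
    expect_equal(fit$se, ref$se)
  }
})

test_that("the weighted median with equal weights is the ordinary median", {
  x <- set_from_ratios(c(1, 2, 3))
  fit <- mr_weighted_median(x, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 2)
  x4 <- set_from_ratios(c(1, 2, 3, 10))
  expect_equal(mr_weighted_median(x4, n_boot = 50, seed = 1)$beta, 2.5)
})

test_that("the weighted median matches the cumulative-weight oracle", {
  cases <- list(
    list(r = c(0.1, 0.5, 0.9, 1.5, 2.0), w = c(5, 1, 1, 1, 8)),
    list(r = c(-1, 0, 1, 2, 3), w = c(1, 2, 3, 2, 1)),
    list(r = c(2, -3, 0.5, 0.7, 0.71), w = c(0.1, 0.1, 4, 4, 2))
  )
  for (cs in cases) {
    x <- set_from_ratios(cs$r, cs$w)
    fit <- mr_weighted_median(x, n_boot = 50, seed = 2)
    expect_equal(fit$beta, oracle_weighted_median(cs$r, cs$w),
                 tolerance = 1e-6)
  }
})

test_that("the weighted median is seeded, bounded by the ratio range", {
  a <- mr_weighted_median(ds, n_boot = 300, seed = 7)
  b <- mr_weighted_median(ds, n_boot = 300, seed = 7)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(ds, n_boot = 300, seed = 8)
  expect_false(identical(a$se, c2$se))
  r <- wald_ratios(ds)
  expect_gte(a$beta, min(r$beta))
  expect_lte(a$beta, max(r$beta))
  expect_error(mr_weighted_median(ds, n_boot = 1, seed = 1), "n_boot")
})

test_that("the mode estimator finds point masses and degenerate inputs", {
  x <- set_from_ratios(c(1, 1, 5))
  expect_equal(mr_mode(x, weighted = FALSE, n_boot = 50, seed = 1)$beta, 1)
  xd <- set_from_ratios(c(0.3, 0.3, 0.3))
  fit <- mr_mode(xd, n_boot = 50, seed = 1)
  expect_equal(fit$beta, 0.3)
  expect_gt(fit$se, 0)
})

test_that("the mode estimator matches the grid-argmax oracle", {
  for (seed in c(3, 4, 5)) {
    r <- withr::with_seed(seed, rnorm(7, 0.5, 0.3))
    w <- withr::with_seed(seed + 100, runif(7, 0.5, 3))
    h <- mad(r)
    x <- set_from_ratios(r, w)
    wfit <- mr_mode(x, weighted = TRUE, n_boot = 50, seed = 1)
    expect_lt(abs(wfit$beta - oracle_mode(r, w, h)), 1e-3)
    sfit <- mr_mode(x, weighted = FALSE, n_boot = 50, seed = 1)
    expect_lt(abs(sfit$beta - oracle_mode(r, rep(1, 7), h)), 1e-3)
  }
})

test_that("tidy and glance expose broom-style summaries", {
  fit <- mr_egger(ds)
  td <- tidy(fit, conf.int = TRUE)
  expect_equal(td$term, c("causal_effect", "pleiotropy_intercept"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_snps, 6L)
  expect_equal(gl$df, 4L)
  gl_ivw <- glance(mr_ivw(ds))
  expect_true(is.na(gl_ivw$df))
})

test_that("mr_estimate collects methods and rejects unknown ones", {
  tab <- mr_estimate(ds, methods = c("ivw", "egger", "weighted_median"),
                     n_boot = 100, seed = 5)
  expect_equal(tab$method, c("ivw", "egger", "weighted_median"))
  expect_true(all(tab$conf.low <= tab$beta & tab$beta <= tab$conf.high))
  expect_equal(tab$beta[1], mr_ivw(ds)$beta)
  expect_error(mr_estimate(ds, methods = "magic"), "unknown method")
})

test_that("two-sided p-values lie in (0, 1] across random inputs", {
  for (seed in 1:10) {
    x <- random_set(6, seed + 50)
    p <- c(wald_ratios(x)$pval, mr_ivw(x)$pval, mr_egger(x)$pval,
           mr_egger(x)$intercept$pval)
    expect_true(all(p > 0 & p <= 1))
  }
})
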