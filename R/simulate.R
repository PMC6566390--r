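# Resolve a per-SNP scale argument: a constant, a (min, max) range drawn
# uniformly, or a length-n vector used as-is.
resolve_scale <- function(value, n, name) {
  if (any(value < 0)) abort(paste0("`", name, "` must be non-negative"))
  if (length(value) == 1) return(rep(value, n))
  if (length(value) == 2) return(runif(n, value[1], value[2]))
  if (length(value) == n) return(value)
  abort(paste0("`", name, "` must have length 1, 2 (range) or n_snps"))
}

random_allele_pair <- function(n) {
  # non-palindromic pairs only, so harmonization is exactly invertible
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  idx <- sample.int(4, n, replace = TRUE)
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  t(vapply(seq_len(n), function(i) {
    p <- pairs[[idx[i]]]
    if (swap[i]) rev(p) else p
  }, character(2)))
}

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates per-variant exposure and outcome associations under the
#' standard two-sample data model: true exposure effects are drawn
#' uniformly from `exposure_effect_range`, observed exposure effects are
#' normal around them with SD `se_exposure`; true outcome effects are
#' `causal_effect` times the true exposure effect, plus — for a random
#' `invalid_fraction` of variants — a direct (horizontally pleiotropic)
#' effect drawn from normal(`pleiotropy_mean`, `pleiotropy_sd`)
#' (directional pleiotropy when the mean is nonzero, balanced when it is
#' zero); observed outcome effects are normal around the truth with SD
#' `se_outcome`. Defaults mirror the bundled vitamin D instrument set: six
#' variants, exposure effects up to ~0.09 so one draw can dominate,
#' exposure SEs ~0.0025 and outcome SEs ~0.004.
#'
#' @param n_snps Number of instruments (default 6).
#' @param causal_effect True causal effect of the exposure on the outcome
#'   (default 0).
#' @param exposure_effect_range Range of true per-variant exposure effects
#'   (default `c(0.015, 0.09)`).
#' @param se_exposure,se_outcome Per-variant standard errors: a constant,
#'   a length-2 range (drawn uniformly), or a length-`n_snps` vector.
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of direct
#'   effects for invalid instruments.
#' @param invalid_fraction Fraction of variants receiving a pleiotropic
#'   direct effect, in \[0, 1\].
#' @param allele_model If `TRUE`, emit raw allele-labelled exposure and
#'   outcome summary-statistic tables (random non-palindromic allele
#'   pairs, random effect/other orientation per table, random allele
#'   frequencies) to exercise [harmonize()]; otherwise return the
#'   harmonized set directly.
#' @param seed Integer seed; the same seed reproduces the draw exactly and
#'   the global RNG state is left untouched.
#' @return If `allele_model = FALSE`, an `mr_set` whose attribute
#'   `truth` is a list with the true per-variant effects and
#'   `causal_effect`. Otherwise a list with elements `exposure` and
#'   `outcome` (summary-statistic tibbles in the [read_summary_stats()]
#'   layout) and `harmonized` (the same draw as an `mr_set`).
#' @export
#' @examples
#' sim <- simulate_two_sample(causal_effect = 0.1, seed = 1)
#' mr_ivw(sim)
simulate_two_sample <- function(n_snps = 6, causal_effect = 0,
                                exposure_effect_range = c(0.015, 0.09),
                                se_exposure = 0.0025, se_outcome = 0.004,
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                invalid_fraction = 0,
                                allele_model = FALSE, seed) {
  if (missing(seed)) abort("`seed` is required (no hidden global RNG)")
  if (n_snps < 1) abort("`n_snps` must be at least 1")
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort("`invalid_fraction` must lie in [0, 1]")
  }
  if (pleiotropy_sd < 0) abort("`pleiotropy_sd` must be non-negative")

  withr::with_seed(seed, {
    bx_true <- runif(n_snps, exposure_effect_range[1],
                     exposure_effect_range[2])
    sex <- resolve_scale(se_exposure, n_snps, "se_exposure")
    sey <- resolve_scale(se_outcome, n_snps, "se_outcome")
    n_invalid <- round(invalid_fraction * n_snps)
    invalid <- seq_len(n_snps) %in% sample.int(n_snps, n_invalid)
    pleio <- ifelse(invalid,
                    rnorm(n_snps, pleiotropy_mean, pleiotropy_sd), 0)
    by_true <- causal_effect * bx_true + pleio
    bx_obs <- if (all(sex == 0)) bx_true else rnorm(n_snps, bx_true, sex)
    by_obs <- if (all(sey == 0)) by_true else rnorm(n_snps, by_true, sey)
    snp <- sprintf("rs%06d", seq_len(n_snps))
    # SEs of exactly zero mark the noiseless limit; estimator weights
    # still need positive SEs, so floor at a tiny epsilon
    sex_pos <- pmax(sex, 1e-12)
    sey_pos <- pmax(sey, 1e-12)

    truth <- list(beta_exposure_true = bx_true, beta_outcome_true = by_true,
                  pleiotropy = pleio, invalid = invalid,
                  causal_effect = causal_effect)

    harmonized <- as_mr_set(
      tibble::tibble(snp = snp, beta_exposure = bx_obs,
                     se_exposure = sex_pos, beta_outcome = by_obs,
                     se_outcome = sey_pos),
      exposure = "simulated exposure", outcome = "simulated outcome")
    attr(harmonized, "truth") <- truth

    if (!allele_model) return(harmonized)

    alleles <- random_allele_pair(n_snps)
    eaf <- runif(n_snps, 0.05, 0.95)
    expo <- tibble::tibble(
      snp = snp, effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = bx_obs, se = sex_pos,
      pval = p_normal(bx_obs / sex_pos))
    # outcome records report a random allele of the pair as the effect
    # allele; beta and eaf are expressed accordingly
    flip <- sample(c(TRUE, FALSE), n_snps, replace = TRUE)
    outc <- tibble::tibble(
      snp = snp,
      effect_allele = ifelse(flip, alleles[, 2], alleles[, 1]),
      other_allele = ifelse(flip, alleles[, 1], alleles[, 2]),
      eaf = ifelse(flip, 1 - eaf, eaf),
      beta = ifelse(flip, -by_obs, by_obs), se = sey_pos,
      pval = p_normal(by_obs / sey_pos))
    list(exposure = expo, outcome = outc, harmonized = harmonized)
  })
}

#' Parameter-recovery experiment over seeded replicates
#'
#' Repeats [simulate_two_sample()] `n_reps` times and, for each requested
#' estimator, reports the mean estimate, bias against the true causal
#' effect, empirical standard error, root-mean-square error, 95%
#' confidence-interval coverage, and the rejection rate of the two-sided
#' test at level `alpha` (type-I error under the null, power otherwise).
#' The Monte-Carlo standard error of the bias (`empirical_se /
#' sqrt(n_reps)`) is included for calibration checks.
#'
#' @param n_reps Number of replicates (>= 2).
#' @param methods Estimators to evaluate: subset of `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`.
#' @param alpha Test level for the rejection rate.
#' @param seed Integer master seed; replicate r uses seed `seed + r`.
#' @param n_boot Bootstrap replicates for median/mode standard errors
#'   (kept small by default here since each replicate refits).
#' @param ... Passed to [simulate_two_sample()] (e.g. `causal_effect`,
#'   `n_snps`, `pleiotropy_mean`).
#' @return A tibble with one row per method: `method`, `n_reps`,
#'   `mean_estimate`, `bias`, `mc_se`, `empirical_se`, `rmse`,
#'   `ci_coverage`, `rejection_rate`.
#' @export
#' @examples
#' recovery_experiment(n_reps = 50, methods = "ivw",
#'                     causal_effect = 0.1, seed = 1)
recovery_experiment <- function(n_reps, methods = c("ivw", "egger"),
                                alpha = 0.05, seed, n_boot = 100, ...) {
  if (missing(seed)) abort("`seed` is required")
  if (n_reps < 2) abort("`n_reps` must be at least 2")
  known <- c("ivw", "egger", "weighted_median", "simple_mode",
             "weighted_mode")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  }
  sim_args <- list(...)
  b_true <- sim_args$causal_effect %||% 0

  fits <- purrr::map(seq_len(n_reps), function(r) {
    set <- do.call(simulate_two_sample,
                   c(sim_args, list(seed = seed + r)))
    purrr::map(setNames(methods, methods), function(m) {
      switch(m,
        ivw = mr_ivw(set),
        egger = mr_egger(set),
        weighted_median = mr_weighted_median(set, n_boot = n_boot,
                                             seed = seed + r),
        simple_mode = mr_mode(set, weighted = FALSE, n_boot = n_boot,
                              seed = seed + r),
        weighted_mode = mr_mode(set, weighted = TRUE, n_boot = n_boot,
                                seed = seed + r))
    })
  })

  purrr::map_dfr(methods, function(m) {
    est <- purrr::map_dbl(fits, ~ .x[[m]]$beta)
    se <- purrr::map_dbl(fits, ~ .x[[m]]$se)
    df <- fits[[1]][[m]]$df
    crit <- if (is.null(df)) qnorm(1 - alpha / 2) else qt(1 - alpha / 2, df)
    covered <- abs(est - b_true) <= crit * se
    rejected <- abs(est / se) > crit
    tibble::tibble(
      method = m, n_reps = n_reps,
      mean_estimate = mean(est), bias = mean(est) - b_true,
      mc_se = sd(est) / sqrt(n_reps),
      empirical_se = sd(est), rmse = sqrt(mean((est - b_true)^2)),
      ci_coverage = mean(covered), rejection_rate = mean(rejected))
  })
}
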