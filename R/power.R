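# Noncentrality of the two-sample Wald test of the causal effect, per the
# asymptotic approximation for summary-data designs: the estimator's
# variance is 1/(n r2) for a continuous outcome and
# 1/(n r2 K (1 - K)) for a binary one (K = case fraction).
mr_noncentrality <- function(effect, n_outcome, r2, outcome_type,
                             case_fraction) {
  if (outcome_type == "binary") {
    abs(log(effect)) * sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  } else {
    abs(effect) * sqrt(n_outcome * r2)
  }
}

check_power_config <- function(n_outcome, r2, outcome_type, case_fraction,
                               alpha) {
  if (is.na(r2) || r2 <= 0 || r2 >= 1) abort("`r2` must lie in (0, 1)")
  if (is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  if (is.na(n_outcome) || n_outcome <= 1) abort("`n_outcome` must exceed 1")
  if (outcome_type == "binary") {
    if (is.null(case_fraction) || is.na(case_fraction) ||
        case_fraction <= 0 || case_fraction >= 1) {
      abort("a binary outcome needs `case_fraction` in (0, 1)")
    }
  }
}

#' Analytic power of a two-sample MR study
#'
#' Power of the two-sided Wald test of the causal effect at level `alpha`,
#' under the asymptotic approximation for summary-data two-sample designs:
#' the noncentrality is `|b| * sqrt(n * r2)` for a continuous outcome and
#' `|log(OR)| * sqrt(n * r2 * K * (1 - K))` for a binary outcome with case
#' fraction `K`; power includes both rejection tails, so the null effect
#' gives exactly `alpha`. Effects may be supplied on either orientation
#' (an odds ratio and its reciprocal give identical power).
#'
#' @param effect Causal effect per 1 SD of the exposure: an odds ratio for
#'   a binary outcome, a standardized beta for a continuous one. May be a
#'   vector.
#' @param n_outcome Outcome-GWAS sample size (cases + controls when
#'   binary).
#' @param r2 Fraction of exposure variance explained by the instruments.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Cases / (cases + controls); required when binary.
#' @param alpha Two-sided significance level; default 0.05.
#' @return A tibble with one row per effect: `effect`, `noncentrality`,
#'   `power`, plus the configuration columns.
#' @export
#' @examples
#' mr_power(1.1, n_outcome = 322580, r2 = 0.028,
#'          outcome_type = "binary", case_fraction = 113769 / 322580)
mr_power <- function(effect, n_outcome, r2,
                     outcome_type = c("binary", "continuous"),
                     case_fraction = NULL, alpha = 0.05) {
  outcome_type <- match.arg(outcome_type)
  check_power_config(n_outcome, r2, outcome_type, case_fraction, alpha)
  if (outcome_type == "binary" && any(effect <= 0)) {
    abort("odds-ratio effects must be positive")
  }
  ncp <- mr_noncentrality(effect, n_outcome, r2, outcome_type, case_fraction)
  zcrit <- qnorm(1 - alpha / 2)
  pow <- pnorm(ncp - zcrit) + pnorm(-ncp - zcrit)
  tibble::tibble(effect = effect, noncentrality = ncp, power = pow,
                 n_outcome = n_outcome, r2 = r2,
                 outcome_type = outcome_type,
                 case_fraction = case_fraction %||% NA_real_,
                 alpha = alpha)
}

#' Power across a grid of effect sizes
#'
#' Evaluates [mr_power()] on a grid of effects. The default grid covers
#' odds ratios 0.80 to 1.20 in steps of 0.01 (41 values), i.e. relative
#' differences of up to 20% per 1 SD of the exposure.
#'
#' @inheritParams mr_power
#' @param effect_grid Ordered vector of effect values.
#' @return A tibble with columns `effect` and `power` (plus configuration
#'   columns), one row per grid value.
#' @export
#' @examples
#' power_curve(n_outcome = 322580, r2 = 0.028, outcome_type = "binary",
#'             case_fraction = 113769 / 322580)
power_curve <- function(n_outcome, r2,
                        outcome_type = c("binary", "continuous"),
                        case_fraction = NULL, alpha = 0.05,
                        effect_grid = seq(0.80, 1.20, by = 0.01)) {
  if (length(effect_grid) < 1) abort("`effect_grid` must be nonempty")
  mr_power(effect_grid, n_outcome = n_outcome, r2 = r2,
           outcome_type = outcome_type, case_fraction = case_fraction,
           alpha = alpha)
}

#' Minimum detectable effect at a target power
#'
#' The smallest effect above the null (odds ratio > 1 for binary, |beta| >
#' 0 for continuous) whose power reaches `target_power`, found by
#' bisection on the closed-form power function to a tolerance of 1e-6. By
#' the symmetry of the test, the reciprocal odds ratio (or negated beta)
#' is detectable with the same power.
#'
#' @inheritParams mr_power
#' @param target_power Required power, in (0, 1); must exceed `alpha`
#'   (below `alpha` no effect above the null is the *smallest* detectable
#'   one).
#' @return A single effect value (odds ratio or standardized beta).
#' @export
#' @examples
#' minimum_detectable_effect(n_outcome = 322580, r2 = 0.028,
#'                           outcome_type = "binary",
#'                           case_fraction = 113769 / 322580,
#'                           target_power = 0.8)
minimum_detectable_effect <- function(n_outcome, r2,
                                      outcome_type = c("binary", "continuous"),
                                      case_fraction = NULL, alpha = 0.05,
                                      target_power = 0.8) {
  outcome_type <- match.arg(outcome_type)
  check_power_config(n_outcome, r2, outcome_type, case_fraction, alpha)
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must lie in (0, 1)")
  }
  if (target_power <= alpha) {
    abort("`target_power` at or below `alpha` is reached at the null; no minimum detectable effect exists")
  }
  pow <- function(eff) {
    mr_power(eff, n_outcome = n_outcome, r2 = r2,
             outcome_type = outcome_type, case_fraction = case_fraction,
             alpha = alpha)$power
  }
  lo <- if (outcome_type == "binary") 1 else 0
  hi <- if (outcome_type == "binary") 1.001 else 1e-3
  while (pow(hi) < target_power) {
    hi <- if (outcome_type == "binary") 1 + (hi - 1) * 2 else hi * 2
    if ((outcome_type == "binary" && hi > 1e6) || hi > 1e12) {
      abort("target power unreachable on the admissible effect range")
    }
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
    if (hi - lo < 1e-6 * max(1e-6, hi)) break
  }
  hi
}
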