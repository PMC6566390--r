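#' Approximate F statistic for instrument strength
#'
#' The standard GWAS approximation from the variance explained:
#' `F = r2 * (n - k - 1) / ((1 - r2) * k)`. Values above 10 conventionally
#' indicate instruments strong enough to make weak-instrument bias
#' negligible in a two-sample design.
#'
#' @param r2 Fraction of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param n Exposure-GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments (>= 1).
#' @return A one-row tibble: `f_stat`, `r2`, `n`, `k`, `strong`
#'   (`f_stat > 10`).
#' @export
#' @examples
#' f_statistic(r2 = 0.028, n = 79366, k = 6)
f_statistic <- function(r2, n, k) {
  if (length(r2) != 1 || is.na(r2) || r2 <= 0 || r2 >= 1) {
    abort("`r2` must be a single value in (0, 1)")
  }
  if (length(k) != 1 || is.na(k) || k < 1) abort("`k` must be at least 1")
  if (length(n) != 1 || is.na(n) || n <= k + 1) {
    abort("`n` must exceed k + 1")
  }
  f <- r2 * (n - k - 1) / ((1 - r2) * k)
  tibble::tibble(f_stat = f, r2 = r2, n = n, k = k, strong = f > 10)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate J times, each time excluding one
#' instrument, to reveal whether any single variant drives the combined
#' estimate. The returned table carries the full-set estimate and the
#' maximum absolute deviation from it as attributes `full_beta` and
#' `max_abs_deviation`.
#'
#' @param data An `mr_set` or data frame with at least 2 instruments.
#' @return A tibble with one row per excluded variant: `excluded_snp`,
#'   `beta`, `se`, `pval`, `n_snps`.
#' @export
#' @examples
#' leave_one_out(mr_fixture("vitd_ds"))
leave_one_out <- function(data) {
  x <- instrument_table(data, min_snps = 2, caller = "leave_one_out()")
  full <- mr_ivw(x)
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    fit <- mr_ivw(x[-i, ])
    tibble::tibble(excluded_snp = x$snp[i], beta = fit$beta, se = fit$se,
                   pval = fit$pval, n_snps = fit$n_snps)
  })
  attr(out, "full_beta") <- full$beta
  attr(out, "max_abs_deviation") <- max(abs(out$beta - full$beta))
  out
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Thin wrapper around [mr_egger()] returning only the intercept term: the
#' estimated average direct (pleiotropic) effect per variant, its standard
#' error (dispersion-floored) and the two-sided Student-t p-value with
#' `J - 2` degrees of freedom. An intercept significantly different from
#' zero indicates directional horizontal pleiotropy, violating the
#' exclusion-restriction assumption.
#'
#' @param data An `mr_set` or data frame with at least 3 instruments.
#' @return A one-row tibble: `intercept`, `se`, `statistic`, `p.value`,
#'   `df`, `n_snps`.
#' @export
#' @examples
#' pleiotropy_test(mr_fixture("vitd_ds"))
pleiotropy_test <- function(data) {
  fit <- mr_egger(data)
  tibble::tibble(
    intercept = fit$intercept$beta, se = fit$intercept$se,
    statistic = fit$intercept$beta / fit$intercept$se,
    p.value = fit$intercept$pval, df = fit$intercept$df,
    n_snps = fit$n_snps
  )
}

#' Forest-plot data: per-variant and combined estimates with intervals
#'
#' One row per single-variant Wald ratio (in input order) followed by the
#' combined IVW and, when at least three instruments are available,
#' MR-Egger rows. Intervals are normal for ratio and IVW rows and Student
#' t (`J - 2` df) for MR-Egger.
#'
#' @param data An `mr_set` or data frame of instruments.
#' @param conf_level Interval level; default 0.95.
#' @return A tibble: `label`, `type` (`"single"`/`"combined"`), `beta`,
#'   `se`, `conf.low`, `conf.high`, `pval`.
#' @export
#' @examples
#' forest_data(mr_fixture("vitd_ds"))
forest_data <- function(data, conf_level = 0.95) {
  x <- instrument_table(data, caller = "forest_data()")
  z <- qnorm(1 - (1 - conf_level) / 2)
  singles <- wald_ratios(x) |>
    dplyr::transmute(label = .data$snp, type = "single", beta = .data$beta,
                     se = .data$se, conf.low = .data$beta - z * .data$se,
                     conf.high = .data$beta + z * .data$se,
                     pval = .data$pval)
  ivw <- mr_ivw(x)
  combined <- tibble::tibble(
    label = "All - IVW", type = "combined", beta = ivw$beta, se = ivw$se,
    conf.low = ivw$beta - z * ivw$se, conf.high = ivw$beta + z * ivw$se,
    pval = ivw$pval)
  if (nrow(x) >= 3) {
    eg <- mr_egger(x)
    tq <- qt(1 - (1 - conf_level) / 2, eg$df)
    combined <- dplyr::bind_rows(combined, tibble::tibble(
      label = "All - MR Egger", type = "combined", beta = eg$beta,
      se = eg$se, conf.low = eg$beta - tq * eg$se,
      conf.high = eg$beta + tq * eg$se, pval = eg$pval))
  }
  dplyr::bind_rows(singles, combined)
}

#' Scatter-plot data: instrument effects with fitted regression lines
#'
#' Exposure effects against outcome effects, one point per instrument
#' after orientation to the exposure-increasing allele (all x >= 0), with
#' the fitted IVW line (through the origin) and, when J >= 3, the MR-Egger
#' line (free intercept) attached as the `lines` attribute (a tibble with
#' columns `method`, `slope`, `intercept`).
#'
#' @param data An `mr_set` or data frame of instruments.
#' @return A tibble of points (`snp`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`) with attribute `lines`.
#' @export
#' @examples
#' pts <- scatter_data(mr_fixture("vitd_ds"))
#' attr(pts, "lines")
scatter_data <- function(data) {
  x <- instrument_table(data, caller = "scatter_data()")
  x <- orient_exposure_increasing(x)
  pts <- tibble::as_tibble(x)[, c("snp", "beta_exposure", "se_exposure",
                                  "beta_outcome", "se_outcome")]
  ivw <- mr_ivw(x)
  lines <- tibble::tibble(method = "ivw", slope = ivw$beta, intercept = 0)
  if (nrow(x) >= 3) {
    eg <- mr_egger(x)
    lines <- dplyr::bind_rows(lines, tibble::tibble(
      method = "egger", slope = eg$beta, intercept = eg$intercept$beta))
  }
  attr(pts, "lines") <- lines
  # a unit exposure effect is on the natural-log scale: exp(beta) is the
  # multiplicative change in the exposure
  attr(pts, "x_scale_note") <-
    "exposure effects on the natural-log scale; exp(beta) = fold change"
  pts
}
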