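# Construct a fitted-estimate object. Lightweight S3, in the broom mold:
# inspect with tidy() / glance(), or read fields directly.
new_mr_fit <- function(method, beta, se, pval, n_snps,
                       residual_scale = 1, df = NULL, Q = NA_real_,
                       intercept = NULL) {
  structure(
    list(method = method, beta = beta, se = se, pval = pval,
         n_snps = n_snps, residual_scale = residual_scale, df = df,
         Q = Q, intercept = intercept),
    class = c(if (!is.null(intercept)) "mr_egger_fit", "mr_fit")
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit: %s>  %d instrument(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4f  se = %.4f  p = %.4g", x$beta, x$se, x$pval))
  if (!is.null(x$df)) cat(sprintf("  (t, %d df)", x$df))
  cat("\n")
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f  se = %.4f  p = %.4g  (t, %d df)\n",
                x$intercept$beta, x$intercept$se, x$intercept$pval,
                x$intercept$df))
  }
  invisible(x)
}

#' Tidy a fitted MR estimate
#'
#' @param x An `mr_fit` object from [mr_ivw()], [mr_egger()],
#'   [mr_weighted_median()] or [mr_mode()].
#' @param conf.int Include a confidence interval (normal, or Student t for
#'   MR-Egger terms)?
#' @param conf.level Interval level; default 0.95.
#' @param ... Unused.
#' @return A tibble with one row per model term (`causal_effect`, and for
#'   MR-Egger also `pleiotropy_intercept`) with broom-standard columns
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.mr_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  crit <- function(df) {
    if (is.null(df)) qnorm(1 - (1 - conf.level) / 2)
    else qt(1 - (1 - conf.level) / 2, df)
  }
  out <- tibble::tibble(
    term = "causal_effect", method = x$method,
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval
  )
  if (!is.null(x$intercept)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "pleiotropy_intercept", method = x$method,
      estimate = x$intercept$beta, std.error = x$intercept$se,
      statistic = x$intercept$beta / x$intercept$se,
      p.value = x$intercept$pval
    ))
  }
  if (conf.int) {
    k <- crit(x$df)
    out$conf.low <- out$estimate - k * out$std.error
    out$conf.high <- out$estimate + k * out$std.error
  }
  out
}

#' Glance at a fitted MR estimate
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_snps`, `Q` (Cochran's
#'   heterogeneity statistic about the fit, where defined),
#'   `residual_scale` (multiplicative dispersion after flooring at 1) and
#'   `df` (degrees of freedom of the reference distribution; `NA` when the
#'   p-value is normal-based).
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n_snps = x$n_snps, Q = x$Q,
                 residual_scale = x$residual_scale,
                 df = if (is.null(x$df)) NA_integer_ else as.integer(x$df))
}

#' Per-variant Wald ratio estimates
#'
#' The causal effect identified by a single instrument: the outcome effect
#' divided by the exposure effect, with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (exposure-side uncertainty
#' ignored, the convention under which the published per-variant standard
#' errors are recovered exactly) and a two-sided normal p-value.
#'
#' @param data An `mr_set` or data frame of instruments.
#' @return A tibble with columns `snp`, `beta`, `se`, `pval`, one row per
#'   instrument, in input order.
#' @export
#' @examples
#' wald_ratios(mr_fixture("vitd_ds"))
wald_ratios <- function(data) {
  x <- instrument_table(data, caller = "wald_ratios()")
  zero <- x$beta_exposure == 0
  if (any(zero)) {
    abort(paste0("Wald ratio undefined (exposure effect is 0) for: ",
                 paste(x$snp[zero], collapse = ", ")))
  }
  beta <- x$beta_outcome / x$beta_exposure
  se <- x$se_outcome / abs(x$beta_exposure)
  tibble::tibble(snp = x$snp, beta = beta, se = se,
                 pval = p_normal(beta / se))
}

# Ratio-level IVW combination: weighted mean with weights 1/se^2 and a
# multiplicative random-effects dispersion Q/(J-1) floored at 1.
ivw_combine <- function(beta, se, n_snps = length(beta)) {
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  if (n_snps > 1) {
    Q <- sum(w * (beta - b)^2)
    scale <- max(1, Q / (n_snps - 1))
  } else {
    Q <- 0
    scale <- 1
  }
  se_b <- sqrt(scale / sum(w))
  new_mr_fit("ivw", b, se_b, p_normal(b / se_b), n_snps,
             residual_scale = scale, Q = Q)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Combines the per-variant Wald ratios by inverse-variance weighting —
#' equivalently, the slope of the zero-intercept weighted least-squares
#' regression of outcome effects on exposure effects with weights
#' `1/se_outcome^2`. The standard error uses a multiplicative
#' random-effects model: the residual dispersion `Q/(J-1)` (Cochran's Q
#' about the IVW estimate) scales the fixed-effect variance but is floored
#' at 1, so heterogeneity can widen the interval while apparent
#' underdispersion never narrows it. The p-value is two-sided normal.
#'
#' @param data An `mr_set` / data frame of instruments (columns
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`), or a
#'   table of pre-computed ratio estimates (columns `beta`, `se`), e.g.
#'   `mr_fixture("vitd_bd_ratios")`.
#' @return An `mr_fit` object; see [tidy.mr_fit()].
#' @export
#' @examples
#' mr_ivw(mr_fixture("vitd_ds"))         # from instruments
#' mr_ivw(mr_fixture("vitd_bd_ratios"))  # from published ratios
mr_ivw <- function(data) {
  x <- tibble::as_tibble(data)
  if (all(c("beta_exposure", "beta_outcome") %in% names(x))) {
    r <- wald_ratios(data)
  } else if (all(c("beta", "se") %in% names(x))) {
    if (nrow(x) < 1) abort("mr_ivw() needs at least one ratio estimate")
    if (any(x$se <= 0)) abort("all standard errors must be strictly positive")
    r <- x
  } else {
    abort("mr_ivw() needs instrument columns (beta_exposure, ...) or ratio columns (beta, se)")
  }
  ivw_combine(r$beta, r$se)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects *with* a
#' free intercept (weights `1/se_outcome^2`), after re-orienting every
#' instrument to its exposure-increasing allele (the intercept is only
#' interpretable on a consistent orientation; the set is oriented
#' internally, so pre-orienting any subset changes nothing). The slope
#' estimates the causal effect under the weaker InSIDE assumption; the
#' intercept estimates average directional pleiotropy per variant, and its
#' test is the standard pleiotropy diagnostic. Residual dispersion
#' `RSS_w/(J-2)` is floored at 1 and scales both standard errors;
#' both p-values are two-sided Student t with `J - 2` degrees of freedom.
#'
#' @param data An `mr_set` or data frame with at least 3 instruments.
#' @return An `mr_fit` (subclass `mr_egger_fit`) whose `intercept` field
#'   holds the pleiotropy intercept estimate, SE, p-value and df;
#'   [tidy.mr_fit()] returns both terms.
#' @export
#' @examples
#' fit <- mr_egger(mr_fixture("vitd_ds"))
#' tidy(fit)
mr_egger <- function(data) {
  x <- instrument_table(data, min_snps = 3, caller = "mr_egger()")
  x <- orient_exposure_increasing(x)
  J <- nrow(x)
  w <- 1 / x$se_outcome^2
  fit <- lm(beta_outcome ~ beta_exposure, data = x, weights = w)
  rss_w <- sum(w * resid(fit)^2)
  scale <- max(1, rss_w / (J - 2))
  # unit-dispersion covariance straight from the weighted design, then
  # rescaled by the floored dispersion (robust to exact fits)
  X <- cbind(1, x$beta_exposure)
  V <- solve(crossprod(X * sqrt(w)))
  est <- coef(fit)
  se_adj <- sqrt(diag(V) * scale)
  tval <- est / se_adj
  pv <- p_t(tval, J - 2)
  new_mr_fit(
    "egger", beta = est[[2]], se = se_adj[[2]], pval = pv[[2]],
    n_snps = J, residual_scale = scale, df = J - 2, Q = rss_w,
    intercept = list(beta = est[[1]], se = se_adj[[1]], pval = pv[[1]],
                     df = J - 2)
  )
}

# Weighted empirical median of `values`: sort, accumulate normalized
# weights at midpoints, linearly interpolate at probability 1/2.
weighted_median_core <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap shared by the median and mode estimators: redraw
# each instrument's exposure and outcome betas from their sampling
# distributions and recompute the point estimator.
ratio_bootstrap <- function(x, estimator, n_boot, seed) {
  if (n_boot < 2) abort("`n_boot` must be at least 2")
  J <- nrow(x)
  withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(J, x$beta_exposure, x$se_exposure)
      by <- rnorm(J, x$beta_outcome, x$se_outcome)
      bx[bx == 0] <- .Machine$double.eps  # guard a measure-zero event
      r <- by / bx
      s <- x$se_outcome / abs(bx)
      estimator(r, 1 / s^2)
    }, numeric(1))
  })
}

#' Weighted median causal estimate
#'
#' The weighted empirical median of the per-variant Wald ratios, with
#' inverse-variance weights: consistent when instruments carrying at least
#' half the weight are valid. The point estimate interpolates linearly on
#' the cumulative-weight grid at probability 1/2 (with equal weights this
#' is the ordinary median). The standard error is the standard deviation of
#' the estimator over a seeded parametric bootstrap that redraws each
#' variant's exposure and outcome betas from normal(beta, se); the p-value
#' is two-sided normal.
#'
#' @param data An `mr_set` or data frame with at least 3 instruments.
#' @param n_boot Number of bootstrap replicates (default 1000; must be >= 2).
#' @param seed Integer seed for the bootstrap; the global RNG state is left
#'   untouched.
#' @return An `mr_fit` object with method `"weighted_median"`.
#' @export
#' @examples
#' mr_weighted_median(mr_fixture("vitd_ds"), n_boot = 200, seed = 7)
mr_weighted_median <- function(data, n_boot = 1000, seed = 20190516) {
  x <- instrument_table(data, min_snps = 3, caller = "mr_weighted_median()")
  r <- wald_ratios(x)
  w <- 1 / r$se^2
  beta <- weighted_median_core(r$beta, w)
  boots <- ratio_bootstrap(x, weighted_median_core, n_boot, seed)
  se <- sd(boots)
  new_mr_fit("weighted_median", beta, se, p_normal(beta / se), nrow(x))
}

# Mode of the weighted smoothed density of the ratios: normal kernel with
# MAD-based bandwidth, argmax located on a grid and refined by optimize().
mode_core <- function(bandwidth_factor) {
  function(values, weights) {
    w <- weights / sum(weights)
    h <- bandwidth_factor * mad(values)
    if (h == 0 || length(unique(values)) == 1) {
      # point-mass fallback: the most-weighted distinct value
      agg <- tapply(w, values, sum)
      return(as.numeric(names(agg))[which.max(agg)])
    }
    dens <- function(x) {
      vapply(x, function(xi) sum(w * stats::dnorm(xi, values, h)), numeric(1))
    }
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 2048)
    i <- which.max(dens(grid))
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
  }
}

#' Mode-based causal estimate
#'
#' The mode of the smoothed empirical density of the per-variant Wald
#' ratios: consistent when the largest group of instruments sharing the
#' same ratio is valid (zero-modal-pleiotropy assumption). A normal kernel
#' is used with bandwidth `bandwidth_factor` times the median absolute
#' deviation (scaled, via [stats::mad()]) of the ratios; the density is
#' weighted by inverse-variance weights when `weighted = TRUE` and equal
#' weights otherwise (the "simple mode"). Standard error by the same
#' seeded parametric bootstrap as [mr_weighted_median()]; two-sided normal
#' p-value.
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights (`TRUE`, the weighted
#'   mode) or equal weights (`FALSE`, the simple mode)?
#' @param bandwidth_factor Multiplier on the MAD-based kernel bandwidth;
#'   default 1. Must be positive.
#' @return An `mr_fit` object with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
#' @examples
#' mr_mode(mr_fixture("vitd_ds"), weighted = TRUE, n_boot = 200, seed = 7)
mr_mode <- function(data, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 20190516) {
  if (bandwidth_factor <= 0) abort("`bandwidth_factor` must be positive")
  x <- instrument_table(data, min_snps = 3, caller = "mr_mode()")
  core <- mode_core(bandwidth_factor)
  r <- wald_ratios(x)
  w <- if (weighted) 1 / r$se^2 else rep(1, nrow(r))
  beta <- core(r$beta, w)
  boot_est <- if (weighted) core else function(v, w) core(v, rep(1, length(v)))
  boots <- ratio_bootstrap(x, boot_est, n_boot, seed)
  se <- sd(boots)
  new_mr_fit(if (weighted) "weighted_mode" else "simple_mode",
             beta, se, p_normal(beta / se), nrow(x))
}

#' Run several MR estimators and collect a combined-estimate table
#'
#' @param data An `mr_set` or data frame of instruments.
#' @param methods Character vector from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`.
#' @param conf_level Confidence level for the reported intervals.
#' @inheritParams mr_weighted_median
#' @inheritParams mr_mode
#' @return A tibble with one row per method: `method`, `n_snps`, `beta`,
#'   `se`, `pval`, `conf.low`, `conf.high` (normal intervals, Student t
#'   for MR-Egger).
#' @export
#' @examples
#' mr_estimate(mr_fixture("vitd_ds"))
mr_estimate <- function(data, methods = c("ivw", "egger"),
                        n_boot = 1000, seed = 20190516,
                        bandwidth_factor = 1, conf_level = 0.95) {
  known <- c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(known, collapse = ", ")))
  }
  fits <- purrr::map(methods, function(m) {
    switch(m,
      ivw = mr_ivw(data),
      egger = mr_egger(data),
      weighted_median = mr_weighted_median(data, n_boot = n_boot, seed = seed),
      simple_mode = mr_mode(data, weighted = FALSE,
                            bandwidth_factor = bandwidth_factor,
                            n_boot = n_boot, seed = seed),
      weighted_mode = mr_mode(data, weighted = TRUE,
                              bandwidth_factor = bandwidth_factor,
                              n_boot = n_boot, seed = seed)
    )
  })
  purrr::map_dfr(fits, function(f) {
    k <- if (is.null(f$df)) qnorm(1 - (1 - conf_level) / 2) else
      qt(1 - (1 - conf_level) / 2, f$df)
    tibble::tibble(method = f$method, n_snps = f$n_snps, beta = f$beta,
                   se = f$se, pval = f$pval,
                   conf.low = f$beta - k * f$se,
                   conf.high = f$beta + k * f$se)
  })
}
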