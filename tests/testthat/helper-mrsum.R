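# Shared builders and independent oracles for the test suite.

# Instruments with exposure effect exactly 1 and negligible exposure SE,
# so the Wald ratios equal `ratios` and the IVW weights equal `weights`.
set_from_ratios <- function(ratios, weights = rep(1, length(ratios))) {
  tibble::tibble(
    snp = paste0("rs", seq_along(ratios)),
    beta_exposure = 1, se_exposure = 1e-8,
    beta_outcome = ratios, se_outcome = 1 / sqrt(weights)
  )
}

# Random instrument set for property-style tests.
random_set <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    snp = paste0("rs", seq_len(n)),
    beta_exposure = runif(n, 0.01, 0.1) * sample(c(-1, 1), n, TRUE),
    se_exposure = runif(n, 0.001, 0.005),
    beta_outcome = rnorm(n, 0, 0.01),
    se_outcome = runif(n, 0.001, 0.01)
  ))
}

# Exhaustive cumulative-weight oracle for the weighted median: walk the
# sorted ratios, find where the midpoint cumulative weight crosses 1/2,
# interpolate linearly between the bracketing order statistics.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  j <- max(which(p < 0.5))
  r[j] + (0.5 - p[j]) / (p[j + 1] - p[j]) * (r[j + 1] - r[j])
}

# Grid-argmax oracle for the kernel-mode estimator.
oracle_mode <- function(r, w, h) {
  w <- w / sum(w)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 100001)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, r, h)), numeric(1))
  grid[which.max(dens)]
}

# Published combined-row anchors (results-table values).
DS_IVW <- list(beta = 0.0246, se = 0.0384, p = 0.521)
DS_EGGER <- list(beta = 0.0209, se = 0.0674, p = 0.772,
                 intercept = 0.0002, intercept_p = 0.949)
BD_IVW <- list(beta = -0.0202, p = 0.099)
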