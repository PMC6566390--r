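---
title: "Two-sample Mendelian randomization with mrsum: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrsum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsum)
```

## The design and its assumptions

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for a modifiable exposure. Because alleles are
assigned at conception, associations between an instrument and an outcome
are protected from the confounding and reverse causation that plague
observational exposure–outcome associations. The "two-sample" flavour
needs only per-variant summary statistics from two non-overlapping GWAS:
one for the exposure, one for the outcome.

Validity rests on three instrument assumptions: (1) the variant is truly
associated with the exposure (enforced here by using genome-wide
significant instruments and checked with the F statistic); (2) the
variant affects the outcome only through the exposure; and (3) the
variant is independent of exposure–outcome confounders. Assumptions 2–3
cannot be verified directly; the MR-Egger intercept test probes their
most common failure mode, directional horizontal pleiotropy.

The bundled fixtures carry the published six-instrument set for serum
25-hydroxyvitamin D on the natural-log scale (so an exposure effect of
0.025 means a 2.5% increase in 25(OH)D per allele, since
`exp(0.025) = 1.025`), with outcome effects on a continuous
depressive-symptoms score and on the log-odds of broad depression.

## Estimators

Writing `θ̂_j = β_yj/β_xj` for the per-variant Wald ratio with
delta-method standard error `σ_yj/|β_xj|`:

* **IVW** combines ratios with weights `w_j = 1/SE(θ̂_j)²`. Its standard
  error multiplies the fixed-effect variance `1/Σw_j` by the residual
  dispersion `Q/(J−1)` (Cochran's Q about the combined estimate), floored
  at 1. This "multiplicative random effects, no underdispersion" policy
  lets heterogeneity widen the interval but never lets sampling noise
  narrow it; the per-variant and IVW p-values use the normal reference.
* **MR-Egger** regresses outcome on exposure effects with a free
  intercept and weights `1/σ_yj²`, after re-signing every instrument so
  its exposure effect is positive. The intercept is the average direct
  (pleiotropic) effect per variant; orientation matters because the
  intercept of an unoriented fit is not identifiable in any meaningful
  direction, so the fit re-orients internally and is invariant to how the
  caller happens to have signed the alleles. Dispersion `RSS_w/(J−2)` is
  floored at 1 and both p-values use Student t with J−2 degrees of
  freedom — with few instruments the estimated dispersion is noisy and
  the t reference accounts for it.
* The **weighted median** interpolates the ratio order statistics on the
  cumulative-weight grid at probability 1/2 (ties resolved by the linear
  interpolation itself); it is consistent when valid instruments carry
  more than half the weight.
* The **mode** estimators take the argmax of a normal-kernel density of
  the ratios (weighted or unweighted), with bandwidth
  `bandwidth_factor × mad(ratios)`; the MAD rule is robust to the single
  outlying ratio that motivates modal estimation in the first place. The
  argmax is located on a 2048-point grid spanning the ratios ±3
  bandwidths and refined with `optimize()`; when the MAD is zero the
  estimate falls back to the most-weighted point mass. Both estimators
  are consistent under the zero-modal-pleiotropy assumption.
* Median and mode standard errors come from a seeded parametric
  bootstrap: each replicate redraws every `β_xj` and `β_yj` from
  normal(estimate, SE) in both samples and recomputes the estimator;
  `n_boot = 1000` by default. There is no numeric anchor for these
  estimators in the source analysis (reported only as similar, not
  shown), so they are validated against brute-force oracles and
  properties rather than printed values.

The delta-method Wald SE deliberately ignores exposure-side uncertainty:
with strong instruments the neglected term is second-order, and this
convention is what reproduces the published per-variant standard errors
digit for digit.

## Harmonization

Exposure and outcome records are matched by rsID only (the fixture tables
carry no positions). The outcome effect is re-signed, and its allele
frequency complemented, when the outcome's effect allele is the
exposure's other allele; strand flips are resolved through base
complements. Palindromic variants (A/T, C/G) are the exception — both
strands show the same allele pair — so strand is inferred from allele
frequency: within `palindromic_eaf_window` (default 0.08) of 0.5 the
frequency is uninformative and the variant is dropped; outside it the
variant is retained, flipped when the exposure and outcome frequencies
disagree about which allele is minor. Every flip and drop lands exactly
once in a machine-readable audit log. In the bundled set, the single C/G
variant has frequency 0.82 and is retained.

## Instrument strength and power

The F statistic uses the summary-level approximation
`F = R²(n−k−1)/((1−R²)k)`; with R² = 0.028, n = 79,366 and k = 6 it
evaluates to 381.0103, far above the conventional threshold of 10.

Analytic power treats the causal estimator as normal with variance
`1/(n R²)` for a continuous outcome and `1/(n R² K(1−K))` for a binary
outcome with case fraction K — the standard asymptotic approximation for
summary-data designs. Power at two-sided level α is
`Φ(λ − z_{1−α/2}) + Φ(−λ − z_{1−α/2})` with noncentrality
`λ = |b|·sqrt(nR²)` or `|ln OR|·sqrt(nR²K(1−K))`; both tails are counted,
so the null effect gives exactly α, and an odds ratio and its reciprocal
give identical power. The original power appendix is not available, so
the binary-variant choice is stated here prominently and the two
published power claims are treated as inequalities (power ≥ 0.99 at
OR 1.1; 80%-power minimum detectable OR in [1.05, 1.10] — this
implementation gives 1.0636). `minimum_detectable_effect()` inverts the
closed form by bisection to 1e-6.

## The simulator and what passing tests mean

`simulate_two_sample()` emulates the fixture's shape by default: 6
instruments, true exposure effects uniform on (0.015, 0.09) so a single
draw can dominate the weight the way the strongest published instrument
does, exposure SEs of 0.0025 and outcome SEs of 0.004 (the order of the
published tables). Pleiotropy is injected as a normal direct effect on a
chosen fraction of instruments — directional when its mean is nonzero,
balanced when zero. True exposure effects are treated as fixed within a
replicate; winner's curse in instrument selection is *not* modelled, nor
is linkage disequilibrium between instruments (the published set is
independent by construction). Allele-labelled output uses non-palindromic
pairs only, so harmonization is exactly invertible and round-trip tests
are sharp.

Calibration findings the test suite recomputes: under the sharp null the
IVW z-statistic is slightly conservative (the dispersion floor inflates
roughly half the standard errors), with type-I error near 0.04 and CI
coverage near 0.96 at these settings. For the Egger intercept test the
relevant null is *balanced* (mean-zero) pleiotropy; with literally zero
heterogeneity the floor truncates exactly the small-dispersion draws that
produce t-rejections and the test becomes extremely conservative (~0.003
at J = 6), whereas under a balanced-pleiotropy null with constant outcome
SEs (pleiotropy SD 0.01) the model's homoskedasticity is preserved, the
floor rarely binds, and the rejection rate sits near the nominal 0.05.
The acceptance-grade calibration checks therefore use the balanced null.
Passing them certifies the estimators under this generative model — not
under real-data features it omits (LD, winner's curse, sample overlap,
non-normal effect distributions).

Problem sizes used by the checked experiments: 1,000 replicates for IVW
recovery (bias within 3 Monte-Carlo SEs, coverage in [0.93, 0.97]) and
for the Egger-intercept type-I rate (in [0.03, 0.07]); 400 replicates for
the null z-distribution; oracle comparisons on sets of up to 10
instruments.

## Numerical and interface choices

* P-values: two-sided; exactly 1 at a zero estimate; normal reference for
  ratios, IVW, median and mode; t(J−2) for both Egger terms.
* A single instrument: IVW degenerates to the Wald ratio with dispersion
  1; Egger requires J ≥ 3 (with dispersion estimated, slope and intercept
  are not jointly identifiable below that).
* An exposure effect of exactly zero is an error for ratio-based
  estimators (the ratio is undefined) and a logged warning for
  orientation (the orientation is undefined but harmless).
* P-values of exactly 0 on input are accepted with an underflow warning:
  genome-wide association p-values below ~5e-324 cannot be represented in
  double precision, and rejecting them would reject real GWAS tables.
* Bootstrap and simulation RNG is always scoped with `withr::with_seed`;
  no function touches the global RNG state, and seeds are explicit
  arguments with deterministic defaults.
* Reported tables round to 4 decimals in the Markdown report only; all
  objects and JSON carry full precision.
* The printed outcome betas for the binary trait in the source's
  instrument table are coarsely rounded and two of them are oriented
  inconsistently with the published per-variant ratios; the package
  therefore ships the published ratios themselves as the quantitative
  fixture (`vitd_bd_ratios`) and documents the instrument-table version
  (`vitd_bd`) as qualitative. This is recorded rather than "corrected":
  the published ratio column is the authoritative output.

## Known limitations

No multivariable MR, outlier-removal (MR-PRESSO), Steiger filtering,
LD-aware instrument selection, proxy lookup or clumping: inputs are
assumed to be independent, pre-selected instruments. Power calculations
cover the IVW/Wald test only, not the median/mode/Egger estimators.
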