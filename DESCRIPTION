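Package: mrsum
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimate causal effects of a modifiable exposure on an outcome
    from harmonized genome-wide association study (GWAS) summary statistics,
    using genetic variants as instrumental variables. Implements per-variant
    Wald ratios, the inverse-variance-weighted (IVW) estimator with a
    multiplicative random-effects dispersion floored at one, MR-Egger
    regression with its intercept test for directional pleiotropy, the
    weighted median, and mode-based estimators with bootstrap standard
    errors; plus allele harmonization with palindromic-variant handling,
    leave-one-out sensitivity analysis, instrument-strength F statistics,
    analytic power calculations for two-sample designs, a seeded
    summary-statistic simulator with known ground truth, and a pipeline that
    produces machine- and human-readable reports. Ships the published
    vitamin D / depression instrument tables as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
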