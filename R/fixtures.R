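# Published instrument tables for the vitamin D / depression analyses.
# Values are stored to exactly the printed decimals of the source tables.

# Exposure: six genome-wide significant variants for natural-log 25(OH)D
# from the SUNLIGHT consortium GWAS (n = 79,366), jointly explaining 2.8%
# of the variance.
vitd_exposure_table <- function() {
  tibble::tribble(
    ~snp,         ~chromosome, ~gene,             ~effect_allele, ~other_allele, ~eaf,  ~beta,   ~se,     ~pval,
    "rs3755967",  "4",         "GC",              "T",            "C",           0.28,  -0.089,  0.0023,  4.74e-343,
    "rs10741657", "11",        "CYP2R1",          "A",            "G",           0.40,   0.031,  0.0022,  2.05e-46,
    "rs12785878", "11",        "NADSYN1_DHCR7",   "T",            "G",           0.75,   0.036,  0.0022,  3.80e-62,
    "rs10745742", "12",        "AMDHD1",          "T",            "C",           0.40,   0.017,  0.0022,  1.88e-14,
    "rs8018720",  "14",        "SEC23A",          "C",            "G",           0.82,  -0.017,  0.0029,  4.72e-09,
    "rs17216707", "20",        "CYP24A1",         "T",            "C",           0.79,   0.026,  0.0027,  8.14e-23
  )
}

# Outcome: depressive symptoms (continuous phenotype, n = 161,460).
vitd_ds_outcome_table <- function() {
  tibble::tribble(
    ~snp,         ~effect_allele, ~other_allele, ~eaf, ~beta,   ~se,   ~pval,
    "rs3755967",  "T", "C", 0.28, -0.001, 0.004, 0.731,
    "rs10741657", "A", "G", 0.40,  0.005, 0.004, 0.309,
    "rs12785878", "T", "G", 0.75,  0.006, 0.005, 0.215,
    "rs10745742", "T", "C", 0.40,  0.000, 0.004, 0.976,
    "rs8018720",  "C", "G", 0.82,  0.001, 0.005, 0.780,
    "rs17216707", "T", "C", 0.79, -0.004, 0.004, 0.340
  )
}

# Outcome: broad depression (binary; 113,769 cases / 208,811 controls).
# NOTE: these betas are printed to 1-2 significant figures and, for
# rs10741657 and rs17216707, with an allele orientation inconsistent with
# the published per-variant ratio estimates; see `mr_fixture("vitd_bd_ratios")`.
vitd_bd_outcome_table <- function() {
  tibble::tribble(
    ~snp,         ~effect_allele, ~other_allele, ~eaf, ~beta,    ~se,    ~pval,
    "rs3755967",  "T", "C", 0.28,  0.0012,  0.0013, 0.350,
    "rs10741657", "A", "G", 0.40,  0.002,   0.001,  0.055,
    "rs12785878", "T", "G", 0.75, -0.002,   0.001,  0.287,
    "rs10745742", "T", "C", 0.40,  0.001,   0.001,  0.412,
    "rs8018720",  "C", "G", 0.82,  0.0003,  0.0015, 0.857,
    "rs17216707", "T", "C", 0.79,  0.0003,  0.0015, 0.862
  )
}

# Published per-variant ratio estimates for broad depression (log-odds per
# unit natural-log 25(OH)D), as printed in the source's results table.
vitd_bd_ratio_table <- function() {
  tibble::tribble(
    ~snp,         ~beta,    ~se,     ~pval,
    "rs3755967",  -0.0136,  0.0145,  0.350,
    "rs10741657", -0.0743,  0.0386,  0.055,
    "rs12785878", -0.0424,  0.0398,  0.287,
    "rs10745742",  0.0586,  0.0715,  0.412,
    "rs8018720",  -0.0163,  0.0907,  0.857,
    "rs17216707", -0.0102,  0.0587,  0.862
  )
}

#' Bundled vitamin D / depression instrument fixtures
#'
#' Harmonized instrument sets for the published two-sample analyses of
#' natural-log 25(OH)vitamin D on depression phenotypes:
#'
#' * `"vitd_ds"` — six instruments with exposure effects from the SUNLIGHT
#'   25(OH)D GWAS (n = 79,366, R² = 0.028) and outcome effects on
#'   depressive symptoms (continuous, n = 161,460).
#' * `"vitd_bd"` — the same instruments with outcome effects on broad
#'   depression (binary, 113,769 cases / 208,811 controls). The printed
#'   outcome betas are coarsely rounded and, for two variants, reported on
#'   an allele orientation inconsistent with the published per-variant
#'   ratios; use `"vitd_bd_ratios"` for quantitative work.
#' * `"vitd_bd_ratios"` — the six published per-variant Wald ratio
#'   estimates and standard errors for broad depression, suitable for
#'   direct inverse-variance-weighted combination via [mr_ivw()].
#'
#' @param name One of `"vitd_ds"`, `"vitd_bd"`, `"vitd_bd_ratios"`.
#' @return An `mr_set` for the first two names; a tibble with columns
#'   `snp`, `beta`, `se`, `pval` for `"vitd_bd_ratios"`.
#' @export
#' @examples
#' mr_fixture("vitd_ds")
#' mr_ivw(mr_fixture("vitd_bd_ratios"))
mr_fixture <- function(name) {
  available <- c("vitd_ds", "vitd_bd", "vitd_bd_ratios")
  if (length(name) != 1 || !name %in% available) {
    abort(paste0("unknown fixture '", paste(name, collapse = ","),
                 "'; available fixtures: ",
                 paste(available, collapse = ", ")))
  }
  if (name == "vitd_bd_ratios") return(vitd_bd_ratio_table())
  expo <- vitd_exposure_table()
  if (name == "vitd_ds") {
    harmonize(expo, vitd_ds_outcome_table(),
              exposure_name = "ln 25(OH)D", outcome_name = "depressive symptoms",
              outcome_type = "continuous", r2_explained = 0.028,
              n_exposure = 79366, n_outcome = 161460)
  } else {
    harmonize(expo, vitd_bd_outcome_table(),
              exposure_name = "ln 25(OH)D", outcome_name = "broad depression",
              outcome_type = "binary", r2_explained = 0.028,
              n_exposure = 79366, n_outcome = 113769 + 208811,
              case_fraction = 113769 / (113769 + 208811))
  }
}
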