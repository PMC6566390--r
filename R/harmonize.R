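COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by identifier, aligns every outcome effect to the
#' exposure's effect allele (re-signing the outcome beta and complementing
#' its allele frequency when the outcome record reports the other allele),
#' resolves strand flips via allele complements, and handles palindromic
#' (A/T, C/G) variants — whose strand cannot be inferred from the alleles —
#' using allele frequency: a palindromic variant whose exposure effect-allele
#' frequency lies within `palindromic_eaf_window` of 0.5 is dropped as
#' ambiguous, otherwise it is retained (with the outcome orientation
#' corrected when the two frequencies disagree about which allele is the
#' minor one). Every flip and drop is recorded in the audit log attached to
#' the result.
#'
#' @param exposure,outcome Data frames of summary statistics as returned by
#'   [read_summary_stats()]: columns `snp`, `beta`, `se`, and optionally
#'   `effect_allele`, `other_allele`, `eaf`. When both tables lack allele
#'   columns the records are assumed pre-aligned.
#' @param palindromic_eaf_window Half-width of the frequency window around
#'   0.5 inside which a palindromic variant is considered strand-ambiguous
#'   and dropped. Default 0.08.
#' @param drop_palindromic Drop all palindromic variants regardless of
#'   frequency. Default `FALSE`.
#' @inheritParams as_mr_set
#'
#' @return An [as_mr_set()] tibble of surviving instruments, in exposure
#'   order, with the audit log available via [mr_audit()].
#' @export
#' @examples
#' expo <- data.frame(snp = "rs10741657", effect_allele = "A",
#'                    other_allele = "G", eaf = 0.4,
#'                    beta = 0.031, se = 0.0022)
#' outc <- data.frame(snp = "rs10741657", effect_allele = "G",
#'                    other_allele = "A", eaf = 0.6,
#'                    beta = -0.005, se = 0.004)
#' harmonize(expo, outc)  # outcome beta re-signed to +0.005
harmonize <- function(exposure, outcome,
                      palindromic_eaf_window = 0.08,
                      drop_palindromic = FALSE,
                      exposure_name = "exposure", outcome_name = "outcome",
                      outcome_type = c("continuous", "binary"),
                      r2_explained = NULL, n_exposure = NULL,
                      n_outcome = NULL, case_fraction = NULL) {
  outcome_type <- match.arg(outcome_type)
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  for (nm in c("exposure", "outcome")) {
    tab <- get(nm)
    miss <- setdiff(c("snp", "beta", "se"), names(tab))
    if (length(miss) > 0) {
      abort(paste0("`", nm, "` lacks column(s): ", paste(miss, collapse = ", ")))
    }
  }
  have_alleles <- all(c("effect_allele", "other_allele") %in% names(exposure)) &&
    all(c("effect_allele", "other_allele") %in% names(outcome))

  audit <- list()
  log_row <- function(snp, action, reason) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      snp = snp, action = action, reason = reason)
  }

  for (s in setdiff(outcome$snp, exposure$snp)) {
    log_row(s, "dropped", "not_in_exposure")
  }

  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    s <- ex$snp
    j <- match(s, outcome$snp)
    if (is.na(j)) {
      log_row(s, "dropped", "not_in_outcome")
      next
    }
    ou <- outcome[j, ]
    flip <- FALSE
    palin <- FALSE
    keep <- TRUE
    reason <- "aligned"

    if (have_alleles) {
      e_ea <- ex$effect_allele; e_oa <- ex$other_allele
      o_ea <- ou$effect_allele; o_oa <- ou$other_allele
      palin <- is_palindromic_pair(e_ea, e_oa)
      if (palin) {
        # direct and complementary matches are indistinguishable by allele
        same_pair <- setequal(c(o_ea, o_oa), c(e_ea, e_oa))
        if (!same_pair) {
          keep <- FALSE; reason <- "allele_mismatch"
        } else if (drop_palindromic) {
          keep <- FALSE; reason <- "palindromic_dropped"
        } else {
          eaf_ex <- if ("eaf" %in% names(ex)) ex$eaf else NA_real_
          eaf_ou <- if ("eaf" %in% names(ou)) ou$eaf else NA_real_
          ambiguous <- !is.na(eaf_ex) &&
            abs(eaf_ex - 0.5) <= palindromic_eaf_window
          if (is.na(eaf_ex)) {
            keep <- FALSE; reason <- "palindromic_no_eaf"
          } else if (ambiguous) {
            keep <- FALSE; reason <- "palindromic_ambiguous_eaf"
          } else {
            # strand inferred from frequency: orient by apparent labels,
            # then correct if the frequencies disagree on the minor allele
            flip <- o_ea == e_oa
            eaf_aligned <- if (flip && !is.na(eaf_ou)) 1 - eaf_ou else eaf_ou
            if (!is.na(eaf_aligned) &&
                sign(eaf_aligned - 0.5) != sign(eaf_ex - 0.5) &&
                abs(eaf_aligned - 0.5) > palindromic_eaf_window) {
              flip <- !flip
              reason <- "palindromic_eaf_flip"
            } else {
              reason <- "palindromic_retained"
            }
          }
        }
      } else if (o_ea == e_ea && o_oa == e_oa) {
        flip <- FALSE
      } else if (o_ea == e_oa && o_oa == e_ea) {
        flip <- TRUE; reason <- "allele_swap"
      } else if (identical(unname(COMPLEMENT[o_ea]), e_ea) &&
                 identical(unname(COMPLEMENT[o_oa]), e_oa)) {
        flip <- FALSE; reason <- "strand_complement"
      } else if (identical(unname(COMPLEMENT[o_ea]), e_oa) &&
                 identical(unname(COMPLEMENT[o_oa]), e_ea)) {
        flip <- TRUE; reason <- "strand_complement_swap"
      } else {
        keep <- FALSE; reason <- "allele_mismatch"
      }
    }

    if (!keep) {
      log_row(s, "dropped", reason)
      next
    }
    log_row(s, if (flip) "flipped" else "kept", reason)
    rows[[length(rows) + 1]] <- tibble::tibble(
      snp = s,
      beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = if (flip) -ou$beta else ou$beta,
      se_outcome = ou$se,
      eaf = if ("eaf" %in% names(ex)) ex$eaf else NA_real_,
      orientation_flipped = flip,
      palindromic = palin
    )
  }

  audit_tbl <- if (length(audit) > 0) {
    dplyr::bind_rows(audit)
  } else {
    tibble::tibble(snp = character(), action = character(),
                   reason = character())
  }
  if (length(rows) == 0) {
    abort("no instruments survived harmonization")
  }
  as_mr_set(dplyr::bind_rows(rows),
            exposure = exposure_name, outcome = outcome_name,
            outcome_type = outcome_type, r2_explained = r2_explained,
            n_exposure = n_exposure, n_outcome = n_outcome,
            case_fraction = case_fraction, audit = audit_tbl)
}

#' Orient all instruments to exposure-increasing alleles
#'
#' Re-signs every instrument so that its exposure effect is non-negative:
#' where `beta_exposure < 0` both betas are negated (nothing else changes)
#' and the `orientation_flipped` audit flag is toggled. The operation is
#' idempotent. Instruments with an exposure effect of exactly zero are left
#' untouched with a warning, since their orientation is undefined.
#'
#' @param data An `mr_set` or data frame of instruments.
#' @return The oriented set, same class as the input.
#' @export
orient_exposure_increasing <- function(data) {
  x <- instrument_table(data, caller = "orient_exposure_increasing()")
  zero <- x$beta_exposure == 0
  if (any(zero)) {
    warn(paste0("exposure effect exactly 0 for: ",
                paste(x$snp[zero], collapse = ", "),
                "; orientation left unchanged"))
  }
  neg <- x$beta_exposure < 0
  x$beta_exposure[neg] <- -x$beta_exposure[neg]
  x$beta_outcome[neg] <- -x$beta_outcome[neg]
  if ("eaf" %in% names(x)) x$eaf[neg] <- 1 - x$eaf[neg]
  if ("orientation_flipped" %in% names(x)) {
    x$orientation_flipped[neg] <- !x$orientation_flipped[neg]
  }
  if (inherits(data, "mr_set")) mr_set_like(data, x) else x
}
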