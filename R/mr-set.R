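#' Instrument sets: a tibble of harmonized exposure/outcome pairs
#'
#' An `mr_set` is a tibble with one row per genetic instrument and columns
#' `snp`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#' `orientation_flipped`, `palindromic`, carrying study-level metadata
#' (trait names, outcome type, variance explained, sample sizes, case
#' fraction) and a harmonization audit table as attributes. All estimator
#' and diagnostic functions accept either an `mr_set` or any data frame
#' with the four effect/SE columns.
#'
#' @param data A data frame with at least `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`. Missing
#'   `orientation_flipped` / `palindromic` columns are filled with `FALSE`.
#' @param exposure,outcome Trait labels.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param r2_explained Fraction of exposure variance explained by the
#'   instruments, in (0, 1), or `NULL` if unknown.
#' @param n_exposure,n_outcome GWAS sample sizes (outcome: cases + controls
#'   for a binary trait), or `NULL`.
#' @param case_fraction Cases / (cases + controls) for a binary outcome.
#' @param audit A tibble with columns `snp`, `action`, `reason` recording
#'   harmonization decisions.
#'
#' @return An `mr_set` tibble.
#' @export
#' @examples
#' as_mr_set(data.frame(
#'   snp = c("rs1", "rs2", "rs3"),
#'   beta_exposure = c(0.09, 0.03, 0.02), se_exposure = 0.002,
#'   beta_outcome = c(0.004, 0.002, 0.001), se_outcome = 0.004
#' ))
as_mr_set <- function(data,
                      exposure = "exposure", outcome = "outcome",
                      outcome_type = c("continuous", "binary"),
                      r2_explained = NULL,
                      n_exposure = NULL, n_outcome = NULL,
                      case_fraction = NULL,
                      audit = NULL) {
  outcome_type <- match.arg(outcome_type)
  required <- c("snp", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(data)
  if (!"orientation_flipped" %in% names(x)) x$orientation_flipped <- FALSE
  if (!"palindromic" %in% names(x)) x$palindromic <- FALSE
  if (nrow(x) < 1) abort("an instrument set needs at least one instrument")
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    abort("all standard errors must be strictly positive")
  }
  if (!is.null(r2_explained) &&
      (r2_explained <= 0 || r2_explained >= 1)) {
    abort("`r2_explained` must lie in (0, 1)")
  }
  if (outcome_type == "binary" && !is.null(case_fraction) &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    abort("`case_fraction` must lie in (0, 1)")
  }
  if (is.null(audit)) {
    audit <- tibble::tibble(snp = character(), action = character(),
                            reason = character())
  }
  structure(
    x,
    class = c("mr_set", class(tibble::tibble()))[!duplicated(
      c("mr_set", class(tibble::tibble())))],
    exposure = exposure, outcome = outcome, outcome_type = outcome_type,
    r2_explained = r2_explained, n_exposure = n_exposure,
    n_outcome = n_outcome, case_fraction = case_fraction,
    audit = tibble::as_tibble(audit)
  )
}

#' Study-level metadata of an instrument set
#'
#' @param x An `mr_set`.
#' @return A named list with elements `exposure`, `outcome`, `outcome_type`,
#'   `r2_explained`, `n_exposure`, `n_outcome`, `case_fraction`.
#' @export
mr_metadata <- function(x) {
  list(
    exposure = attr(x, "exposure") %||% "exposure",
    outcome = attr(x, "outcome") %||% "outcome",
    outcome_type = attr(x, "outcome_type") %||% "continuous",
    r2_explained = attr(x, "r2_explained"),
    n_exposure = attr(x, "n_exposure"),
    n_outcome = attr(x, "n_outcome"),
    case_fraction = attr(x, "case_fraction")
  )
}

#' Harmonization audit log of an instrument set
#'
#' Every flipped or dropped variant appears exactly once, with a
#' machine-readable reason code.
#'
#' @param x An `mr_set`.
#' @return A tibble with columns `snp`, `action`, `reason`.
#' @export
mr_audit <- function(x) {
  attr(x, "audit") %||%
    tibble::tibble(snp = character(), action = character(),
                   reason = character())
}

#' @export
print.mr_set <- function(x, ...) {
  meta <- mr_metadata(x)
  cat(sprintf("<mr_set> %s -> %s (%s outcome), %d instrument(s)\n",
              meta$exposure, meta$outcome, meta$outcome_type, nrow(x)))
  if (!is.null(meta$r2_explained)) {
    cat(sprintf("  r2 explained: %.3f", meta$r2_explained))
    if (!is.null(meta$n_exposure)) {
      cat(sprintf("  (exposure n = %d)", as.integer(meta$n_exposure)))
    }
    cat("\n")
  }
  NextMethod()
  invisible(x)
}

# Rebuild an mr_set around new instrument rows, keeping metadata.
mr_set_like <- function(template, data, audit = NULL) {
  meta <- mr_metadata(template)
  as_mr_set(data,
            exposure = meta$exposure, outcome = meta$outcome,
            outcome_type = meta$outcome_type,
            r2_explained = meta$r2_explained,
            n_exposure = meta$n_exposure, n_outcome = meta$n_outcome,
            case_fraction = meta$case_fraction,
            audit = audit %||% mr_audit(template))
}

# Coerce any acceptable input to a plain instrument tibble, validating
# the effect/SE columns. Used at the top of every estimator.
instrument_table <- function(data, min_snps = 1, caller = "this estimator") {
  if (inherits(data, "mr_set")) {
    x <- tibble::as_tibble(data)
  } else {
    x <- tibble::as_tibble(data)
    required <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
    missing_cols <- setdiff(required, names(x))
    if (length(missing_cols) > 0) {
      abort(paste0(caller, " needs column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
  }
  if (!"snp" %in% names(x)) x$snp <- paste0("snp_", seq_len(nrow(x)))
  if (nrow(x) < min_snps) {
    abort(sprintf("%s needs at least %d instrument(s), got %d",
                  caller, min_snps, nrow(x)))
  }
  if (any(x$se_outcome <= 0) || any(x$se_exposure <= 0)) {
    abort("all standard errors must be strictly positive")
  }
  x
}
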