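#' Run the full two-sample MR analysis pipeline
#'
#' Orchestrates reading (when file paths are given), harmonization,
#' orientation, per-variant Wald ratios, combined estimation with the
#' requested methods, the MR-Egger intercept (pleiotropy) test,
#' leave-one-out sensitivity analysis, the instrument-strength F statistic
#' (when `r2_explained` and `n_exposure` are available), an analytic power
#' curve (when the outcome sample size is available), and figure-data
#' exports — into a single report object that [write_report()] can
#' serialize. Two runs on identical inputs and seed produce identical
#' reports.
#'
#' @param exposure,outcome Summary statistics: file paths (read with
#'   [read_summary_stats()]) or data frames, or a ready-made `mr_set` as
#'   `exposure` (then `outcome` is ignored).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param cases,controls Case/control counts for a binary outcome; used to
#'   derive `n_outcome` and the case fraction.
#' @param n_outcome Outcome sample size (overridden by `cases + controls`).
#' @param r2_explained,n_exposure Exposure-side variance explained and
#'   sample size, for the F statistic and power analysis.
#' @param methods Estimators for the combined table; see [mr_estimate()].
#' @param alpha Per-outcome two-sided significance level (default 0.05; no
#'   further multiplicity correction is applied).
#' @param seed Seed for bootstrap-based estimators.
#' @param n_boot Bootstrap replicates for median/mode estimators.
#' @param power_grid Effect grid for the power curve (odds ratios for a
#'   binary outcome); default 0.80 to 1.20 in 0.01 steps.
#' @param column_map,delimiter Passed to [read_summary_stats()] for path
#'   inputs.
#' @param palindromic_eaf_window,drop_palindromic Passed to [harmonize()].
#' @return An object of class `mr_report`: a list with elements
#'   `instruments` (the oriented `mr_set`), `per_snp`, `combined`,
#'   `pleiotropy`, `strength`, `leave_one_out`, `power`, `forest`,
#'   `scatter`, `audit`, and `provenance` (input hashes, seed, package
#'   version, alpha).
#' @export
#' @examples
#' run_analysis(mr_fixture("vitd_ds"))
run_analysis <- function(exposure, outcome = NULL,
                         outcome_type = c("continuous", "binary"),
                         cases = NULL, controls = NULL, n_outcome = NULL,
                         r2_explained = NULL, n_exposure = NULL,
                         methods = c("ivw", "egger"),
                         alpha = 0.05, seed = 20190516, n_boot = 1000,
                         power_grid = seq(0.80, 1.20, by = 0.01),
                         column_map = NULL, delimiter = "\t",
                         palindromic_eaf_window = 0.08,
                         drop_palindromic = FALSE) {
  outcome_type <- match.arg(outcome_type)
  hashes <- list()

  if (inherits(exposure, "mr_set")) {
    set <- exposure
    meta <- mr_metadata(set)
    outcome_type <- meta$outcome_type
    r2_explained <- r2_explained %||% meta$r2_explained
    n_exposure <- n_exposure %||% meta$n_exposure
    n_outcome <- n_outcome %||% meta$n_outcome
    case_fraction <- meta$case_fraction
  } else {
    load_side <- function(x, label) {
      if (is.character(x) && length(x) == 1) {
        hashes[[label]] <<- unname(tools::md5sum(x))
        read_summary_stats(x, column_map = column_map,
                           delimiter = delimiter)
      } else {
        tibble::as_tibble(x)
      }
    }
    expo <- load_side(exposure, "exposure")
    outc <- load_side(outcome, "outcome")
    if (!is.null(cases) && !is.null(controls)) {
      n_outcome <- cases + controls
      case_fraction <- cases / (cases + controls)
    } else {
      case_fraction <- NULL
    }
    set <- harmonize(expo, outc,
                     palindromic_eaf_window = palindromic_eaf_window,
                     drop_palindromic = drop_palindromic,
                     outcome_type = outcome_type,
                     r2_explained = r2_explained, n_exposure = n_exposure,
                     n_outcome = n_outcome, case_fraction = case_fraction)
  }

  set <- orient_exposure_increasing(set)
  per_snp <- wald_ratios(set)
  combined <- mr_estimate(set, methods = methods, n_boot = n_boot,
                          seed = seed, conf_level = 1 - alpha)
  pleio <- if (nrow(set) >= 3) pleiotropy_test(set) else NULL
  loo <- if (nrow(set) >= 2) leave_one_out(set) else NULL
  strength <- if (!is.null(r2_explained) && !is.null(n_exposure)) {
    f_statistic(r2_explained, n_exposure, nrow(set))
  } else NULL
  power <- if (!is.null(n_outcome) && !is.null(r2_explained) &&
               (outcome_type == "continuous" ||
                !is.null(case_fraction))) {
    power_curve(n_outcome = n_outcome, r2 = r2_explained,
                outcome_type = outcome_type,
                case_fraction = case_fraction, alpha = alpha,
                effect_grid = if (outcome_type == "binary") power_grid
                              else seq(0, 0.1, by = 0.005))
  } else NULL

  structure(list(
    instruments = set,
    per_snp = per_snp,
    combined = combined,
    pleiotropy = pleio,
    strength = strength,
    leave_one_out = loo,
    power = power,
    forest = forest_data(set, conf_level = 1 - alpha),
    scatter = scatter_data(set),
    audit = mr_audit(set),
    provenance = list(
      input_md5 = hashes, seed = seed, alpha = alpha,
      methods = methods, n_boot = n_boot,
      package_version = as.character(utils::packageVersion("mrsum")))
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  meta <- mr_metadata(x$instruments)
  cat(sprintf("Two-sample MR report: %s -> %s\n", meta$exposure,
              meta$outcome))
  cat(sprintf("%d instrument(s); alpha = %g\n", nrow(x$instruments),
              x$provenance$alpha))
  if (!is.null(x$strength)) {
    cat(sprintf("Instrument strength: F = %.4f (%s)\n", x$strength$f_stat,
                if (x$strength$strong) "strong" else "weak"))
  }
  cat("\nCombined estimates:\n")
  print(as.data.frame(x$combined), digits = 4)
  if (!is.null(x$pleiotropy)) {
    cat(sprintf("\nMR-Egger intercept: %.4f (p = %.3f)\n",
                x$pleiotropy$intercept, x$pleiotropy$p.value))
  }
  invisible(x)
}

fmt4 <- function(x) formatC(x, format = "f", digits = 4)

#' Write an analysis report to disk
#'
#' Produces `report.json` (machine-readable, full precision),
#' `report.md` (human-readable, 4-decimal formatting), `forest.tsv`,
#' `scatter.tsv`, `loo.tsv`, `power.tsv` (when computed) and `audit.log`
#' in `dir`.
#'
#' @param report An `mr_report` from [run_analysis()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "mr_report")) abort("`report` must be an mr_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(name) {
    paths[length(paths) + 1] <<- file.path(dir, name)
    file.path(dir, name)
  }

  json <- list(
    per_snp = report$per_snp,
    combined = report$combined,
    pleiotropy = report$pleiotropy,
    strength = report$strength,
    leave_one_out = report$leave_one_out,
    audit = report$audit,
    provenance = report$provenance
  )
  jsonlite::write_json(json, emit("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  readr::write_tsv(report$forest, emit("forest.tsv"))
  pts <- report$scatter
  lines <- attr(pts, "lines")
  readr::write_tsv(tibble::as_tibble(pts), emit("scatter.tsv"))
  readr::write_tsv(lines, file.path(dir, "scatter_lines.tsv"))
  paths[length(paths) + 1] <- file.path(dir, "scatter_lines.tsv")
  if (!is.null(report$leave_one_out)) {
    readr::write_tsv(report$leave_one_out, emit("loo.tsv"))
  }
  if (!is.null(report$power)) {
    readr::write_tsv(report$power[, c("effect", "power")], emit("power.tsv"))
  }

  audit_lines <- sprintf("%s\t%s\t%s", report$audit$snp,
                         report$audit$action, report$audit$reason)
  writeLines(c("snp\taction\treason", audit_lines), emit("audit.log"))

  meta <- mr_metadata(report$instruments)
  md <- c(
    sprintf("# Two-sample MR report: %s on %s", meta$exposure, meta$outcome),
    "",
    sprintf("Instruments: %d; alpha = %g; seed = %s; package mrsum %s",
            nrow(report$instruments), report$provenance$alpha,
            report$provenance$seed, report$provenance$package_version),
    "",
    "## Per-variant ratio estimates",
    "",
    "| SNP | beta | SE | p |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", report$per_snp$snp,
            fmt4(report$per_snp$beta), fmt4(report$per_snp$se),
            fmt4(report$per_snp$pval)),
    "",
    "## Combined estimates",
    "",
    "| method | n SNPs | beta | SE | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %s | %s | %s |", report$combined$method,
            report$combined$n_snps, fmt4(report$combined$beta),
            fmt4(report$combined$se), fmt4(report$combined$pval))
  )
  if (!is.null(report$pleiotropy)) {
    md <- c(md, "",
            sprintf("MR-Egger intercept: %s (SE %s, p = %s, t with %d df)",
                    fmt4(report$pleiotropy$intercept),
                    fmt4(report$pleiotropy$se),
                    fmt4(report$pleiotropy$p.value),
                    report$pleiotropy$df))
  }
  if (!is.null(report$strength)) {
    md <- c(md, "",
            sprintf("Instrument strength: F = %s (R2 = %s, n = %d, k = %d)",
                    fmt4(report$strength$f_stat),
                    format(report$strength$r2),
                    as.integer(report$strength$n), report$strength$k))
  }
  if (!is.null(report$leave_one_out)) {
    md <- c(md, "", "## Leave-one-out (IVW on remaining variants)", "",
            "| excluded | beta | SE | p |", "|---|---|---|---|",
            sprintf("| %s | %s | %s | %s |",
                    report$leave_one_out$excluded_snp,
                    fmt4(report$leave_one_out$beta),
                    fmt4(report$leave_one_out$se),
                    fmt4(report$leave_one_out$pval)))
  }
  writeLines(md, emit("report.md"))
  invisible(paths)
}
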