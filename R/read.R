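#' Read GWAS summary statistics from a delimited text file
#'
#' Reads one association record per row (variant identifier, alleles,
#' effect-allele frequency, effect size, standard error, p-value, sample
#' size) and validates each row. Column names are configurable through
#' `column_map`, so files from different GWAS consortia can be ingested
#' without renaming on disk.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`, optionally `chromosome`, `gene`) to the column names used in the
#'   file. Fields absent from the map keep their canonical name. Only
#'   `snp`, `beta` and `se` are required to be present in the file.
#' @param delimiter Field separator; tab by default, use `","` for CSV.
#'
#' @return A tibble with canonical column names, one row per data row of
#'   the file, in file order. Optional columns missing from the file are
#'   absent from the result.
#'
#' @details Row-level validation: `beta` and `se` must parse as numbers,
#'   `se` must be strictly positive, `eaf` (when present) must lie in
#'   \[0, 1\], `effect_allele`/`other_allele` (when present) must be single
#'   bases A/C/G/T and differ, and `pval` (when present) must lie in
#'   \[0, 1\]. A p-value of exactly zero is accepted with a warning, since
#'   genome-wide association p-values below about 5e-324 underflow double
#'   precision when parsed. Offending rows are reported with their row
#'   numbers (header excluded) and the reason.
#' @export
#' @examples
#' path <- system.file("extdata", "sunlight_vitd_exposure.tsv",
#'                     package = "mrsum")
#' read_summary_stats(path)
read_summary_stats <- function(path, column_map = NULL, delimiter = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  canonical <- c("snp", "chromosome", "gene", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0) {
      abort(paste0("unknown field(s) in `column_map`: ",
                   paste(unknown, collapse = ", ")))
    }
    map[names(column_map)] <- unname(column_map)
  }

  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)

  # Explicitly mapped columns must exist; defaults are optional except the
  # three fields no analysis can proceed without.
  must_have <- unique(c("snp", "beta", "se", names(column_map)))
  for (field in must_have) {
    if (!map[[field]] %in% names(raw)) {
      abort(sprintf("column '%s' (mapped to field '%s') not found in %s",
                    map[[field]], field, path))
    }
  }

  present <- canonical[map[canonical] %in% names(raw)]
  out <- tibble::as_tibble(
    setNames(lapply(present, function(f) raw[[map[[f]]]]), present))
  numeric_fields <- intersect(c("eaf", "beta", "se", "pval", "n"), present)

  problems <- character()
  note <- function(row, why) {
    problems[length(problems) + 1] <<- sprintf("row %d: %s", row, why)
  }
  for (f in numeric_fields) {
    parsed <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(!is.na(out[[f]]) & is.na(parsed))
    for (r in bad) note(r, sprintf("non-numeric %s '%s'", f, out[[f]][r]))
    out[[f]] <- parsed
  }
  if ("se" %in% present) {
    for (r in which(!is.na(out$se) & out$se <= 0)) {
      note(r, sprintf("se must be > 0, got %s", format(out$se[r])))
    }
  }
  if ("eaf" %in% present) {
    for (r in which(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1))) {
      note(r, sprintf("eaf outside [0, 1]: %s", format(out$eaf[r])))
    }
  }
  if ("pval" %in% present) {
    for (r in which(!is.na(out$pval) & (out$pval < 0 | out$pval > 1))) {
      note(r, sprintf("pval outside [0, 1]: %s", format(out$pval[r])))
    }
    if (any(!is.na(out$pval) & out$pval == 0)) {
      warn("p-value(s) of exactly 0 read; values below ~5e-324 underflow double precision")
    }
  }
  if (all(c("effect_allele", "other_allele") %in% present)) {
    ea <- toupper(out$effect_allele); oa <- toupper(out$other_allele)
    for (r in which(!ea %in% c("A", "C", "G", "T"))) {
      note(r, sprintf("effect_allele '%s' is not one of A/C/G/T", ea[r]))
    }
    for (r in which(!oa %in% c("A", "C", "G", "T"))) {
      note(r, sprintf("other_allele '%s' is not one of A/C/G/T", oa[r]))
    }
    for (r in which(ea %in% c("A", "C", "G", "T") & ea == oa)) {
      note(r, "effect_allele equals other_allele")
    }
    out$effect_allele <- ea
    out$other_allele <- oa
  }

  if (length(problems) > 0) {
    abort(paste0("invalid summary-statistic rows in ", path, ":\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  out
}
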