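# Cohort file I/O.
#
# Cohorts travel as plain CSV (UTF-8, comma-separated, "." decimal):
# columns record_id, assay, sa, tyr, phe, and optionally diagnosis,
# original_result and covariates. Header required. Lines starting with
# '#' are provenance comments (tool version, seed, config hash) written by
# the package and skipped on read.

#' Read a screening cohort from CSV
#'
#' Performs strict validation — missing columns, unknown assay/diagnosis
#' labels, non-numeric or negative biomarkers are all reported with row
#' numbers (1-based over the data rows).
#'
#' @param path CSV file path.
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) fail("cohort file not found: %s", path)
  cohort <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = c(record_id = "character"))
  validate_cohort(cohort)
  cohort
}

#' Write a screening cohort to CSV
#'
#' Prepends provenance comment lines (package version, seed, configuration
#' hash) that [read_cohort()] skips; the data round-trips losslessly.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @param seed seed to record in the header, if any.
#' @param config optional R object whose hash is recorded.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL, config = NULL) {
  validate_cohort(cohort)
  writeLines(provenance_header(seed, config), path)
  suppressWarnings(utils::write.table(cohort, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# tt1screen %s",
            as.character(utils::packageVersion("tt1screen"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config_hash=%s", config_hash(config)))
}

# md5 of the deparsed configuration; "none" for NULL
config_hash <- function(config) {
  if (is.null(config)) return("none")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}
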