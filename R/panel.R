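# Derived biomarker panel.
#
# Screening decisions are made on the effective SA (NeoBase 2 scale), the
# raw amino acids, and derived quantities: ratios among SA, tyrosine and
# phenylalanine, and the tyr x SA numeric product (analogous to the
# IRT x PAP product used in cystic fibrosis screening). All derived values
# are computed from the two-decimal effective SA, which is the only
# convention that reproduces the reference patient table cell-for-cell
# (e.g. 833 x 3.85 = 3207.05 -> 3207, where the unrounded conversion
# 3.8514 would give 3208).

#' Panel biomarker keys
#'
#' The biomarkers a screening criterion may reference: the effective SA
#' (NeoBase 2 scale), raw tyrosine and phenylalanine, the tyr x SA product,
#' all pairwise ratios, and `sa_raw` for historical-era rules that applied
#' to the unconverted NeoBase measurement.
#'
#' @return character vector of column names produced by [compute_panel()].
#' @export
panel_biomarkers <- function() {
  c("sa_eff", "tyr", "phe", "tyr_times_sa", "tyr_over_sa", "sa_over_tyr",
    "sa_over_phe", "tyr_over_phe", "phe_over_tyr", "sa_raw")
}

ASSAY_LEVELS <- c("NeoBase", "NeoBase2")
DIAGNOSIS_LEVELS <- c("TT1", "not_TT1", "unknown")
RESULT_LEVELS <- c("positive", "negative", "not_applicable")

# Validate a cohort data frame; returns it invisibly or fails with
# row-addressed diagnostics. Rows are numbered 1..n over the data.
validate_cohort <- function(cohort, require_diagnosis = FALSE) {
  stopifnot(is.data.frame(cohort))
  need <- c("record_id", "assay", "sa", "tyr", "phe")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    fail("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  bad_assay <- which(!(cohort$assay %in% ASSAY_LEVELS))
  if (length(bad_assay))
    fail("unknown assay label(s) '%s' at row(s) %s",
         paste(unique(cohort$assay[bad_assay]), collapse = "', '"),
         paste(utils::head(bad_assay, 10), collapse = ", "))
  for (col in c("sa", "tyr", "phe")) {
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      fail("non-numeric %s value(s) at row(s) %s", col,
           paste(utils::head(bad, 10), collapse = ", "))
    }
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      fail("negative %s value(s) at row(s) %s", col,
           paste(utils::head(neg, 10), collapse = ", "))
  }
  if ("diagnosis" %in% names(cohort)) {
    bad <- which(!(cohort$diagnosis %in% DIAGNOSIS_LEVELS))
    if (length(bad))
      fail("unknown diagnosis label(s) '%s' at row(s) %s",
           paste(unique(cohort$diagnosis[bad]), collapse = "', '"),
           paste(utils::head(bad, 10), collapse = ", "))
  } else if (require_diagnosis) {
    fail("cohort is missing the 'diagnosis' column")
  }
  if ("original_result" %in% names(cohort)) {
    bad <- which(!(cohort$original_result %in% RESULT_LEVELS))
    if (length(bad))
      fail("unknown original_result label(s) '%s' at row(s) %s",
           paste(unique(cohort$original_result[bad]), collapse = "', '"),
           paste(utils::head(bad, 10), collapse = ", "))
  }
  if (anyDuplicated(cohort$record_id))
    fail("duplicated record_id(s): %s",
         paste(utils::head(unique(cohort$record_id[duplicated(cohort$record_id)]), 5),
               collapse = ", "))
  invisible(cohort)
}

#' Drop records with missing core biomarkers
#'
#' Every multi-biomarker protocol needs all three analytes, so records with
#' a missing SA, tyrosine or phenylalanine cannot be evaluated. They are
#' removed, and each removal is reported (one message per record, with the
#' reason), mirroring screening-laboratory audit practice.
#'
#' @param cohort cohort data frame.
#' @param quiet suppress per-record messages.
#' @return list with `cohort` (complete records) and `dropped` (the excluded
#'   rows, with a `reason` column).
#' @export
drop_incomplete <- function(cohort, quiet = FALSE) {
  stopifnot(is.data.frame(cohort))
  miss <- !stats::complete.cases(cohort[, c("sa", "tyr", "phe")])
  dropped <- cohort[miss, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- apply(is.na(dropped[, c("sa", "tyr", "phe")]), 1, function(m)
      paste("missing", paste(c("sa", "tyr", "phe")[m], collapse = "+")))
    if (!quiet)
      for (i in seq_len(nrow(dropped)))
        message(sprintf("excluded record %s: %s",
                        dropped$record_id[i], dropped$reason[i]))
  }
  list(cohort = cohort[!miss, , drop = FALSE], dropped = dropped)
}

#' Effective SA on the NeoBase 2 scale
#'
#' NeoBase-era measurements are converted with the supplied model (and
#' rounded to two decimals); NeoBase 2 measurements pass through unchanged.
#'
#' @param cohort cohort data frame with `assay` and `sa` columns.
#' @param model a [conversion_model()].
#' @return numeric vector of effective SA concentrations, umol/L blood.
#' @examples
#' effective_sa(data.frame(record_id = 1, assay = "NeoBase",
#'                         sa = 16.93, tyr = 236, phe = 56))  # 9.70
#' @export
effective_sa <- function(cohort, model = neobase_conversion()) {
  validate_cohort(cohort)
  out <- cohort$sa
  nb <- cohort$assay == "NeoBase"
  if (any(nb)) out[nb] <- convert_sa(cohort$sa[nb], model)
  out
}

#' Compute the derived biomarker panel for a cohort
#'
#' Produces, per record: effective SA, raw SA, tyrosine, phenylalanine, the
#' tyr x SA product and all pairwise ratios. Ratios and products are
#' computed from the two-decimal effective SA; a zero denominator flags the
#' affected ratio as `NA` (undefined) rather than dropping the record.
#' Stored values keep full precision; [panel_display()] applies the report
#' rounding conventions.
#'
#' @param cohort cohort data frame (columns `record_id`, `assay`, `sa`,
#'   `tyr`, `phe`; `diagnosis` and `original_result` are carried through
#'   when present). Records with missing core biomarkers are an error; use
#'   [drop_incomplete()] first.
#' @param model a [conversion_model()] for NeoBase-era SA.
#' @return data frame with one row per record and the columns of
#'   [panel_biomarkers()].
#' @export
compute_panel <- function(cohort, model = neobase_conversion()) {
  validate_cohort(cohort)
  if (anyNA(cohort$sa) || anyNA(cohort$tyr) || anyNA(cohort$phe)) {
    bad <- cohort$record_id[!stats::complete.cases(cohort[, c("sa", "tyr", "phe")])]
    fail("missing core biomarker(s) for record(s): %s (use drop_incomplete())",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  sa_eff <- effective_sa(cohort, model)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  panel <- data.frame(
    record_id = cohort$record_id,
    assay = cohort$assay,
    sa_raw = cohort$sa,
    sa_eff = sa_eff,
    tyr = cohort$tyr,
    phe = cohort$phe,
    tyr_times_sa = cohort$tyr * sa_eff,
    tyr_over_sa = ratio(cohort$tyr, sa_eff),
    sa_over_tyr = ratio(sa_eff, cohort$tyr),
    sa_over_phe = ratio(sa_eff, cohort$phe),
    tyr_over_phe = ratio(cohort$tyr, cohort$phe),
    phe_over_tyr = ratio(cohort$phe, cohort$tyr),
    stringsAsFactors = FALSE
  )
  for (col in c("diagnosis", "original_result"))
    if (col %in% names(cohort)) panel[[col]] <- cohort[[col]]
  panel
}

#' Apply report rounding to a biomarker panel
#'
#' Rounds panel columns to the conventions of the reference patient table:
#' SA concentrations to 2 decimals, tyr x SA and tyr/SA to the nearest
#' integer, SA/tyr and SA/phe to 3 decimals, tyr/phe and phe/tyr to 2
#' decimals — all half-up.
#'
#' @param panel output of [compute_panel()].
#' @return data frame with the same columns, rounded for display.
#' @export
panel_display <- function(panel) {
  out <- panel
  spec <- c(sa_raw = 2, sa_eff = 2, tyr_times_sa = 0, tyr_over_sa = 0,
            sa_over_tyr = 3, sa_over_phe = 3, tyr_over_phe = 2,
            phe_over_tyr = 2)
  for (col in names(spec))
    if (col %in% names(out)) out[[col]] <- round_half_up(out[[col]], spec[[col]])
  out
}
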