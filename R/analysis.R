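# End-to-end protocol evaluation.

#' Evaluate screening protocols on a cohort
#'
#' Runs the full chain: panel computation (with cross-assay SA
#' harmonization), classification under each protocol, confusion counts
#' against the confirmed diagnoses, performance indicators, and a ranking
#' under the no-new-false-negative constraint. Records with missing core
#' biomarkers or without a confirmed diagnosis label are excluded and each
#' exclusion is logged. The run is deterministic: the same cohort,
#' protocols and seed produce byte-identical outputs.
#'
#' @param cohort a cohort data frame or an `enriched_cohort`.
#' @param protocols named list of [protocol()] objects; default the current
#'   rule plus the three published best alternatives.
#' @param baseline name of the baseline protocol for the ranking
#'   constraint; default the first protocol.
#' @param model a [conversion_model()] for NeoBase-era SA.
#' @param outdir if non-NULL, reports are written there via
#'   [write_reports()].
#' @param seed seed recorded in output headers (no randomness is used
#'   here; the seed documents upstream cohort generation).
#' @param quiet suppress exclusion messages.
#' @return report bundle (class `screening_reports`): `performance` (one
#'   row per protocol: counts, unrounded and display indicators),
#'   `ranking`, `patient_table` (panel of TT1-labelled records, display
#'   rounding), `counts` (list of [confusion_counts()]), `excluded`,
#'   `config`.
#' @export
run_screening_analysis <- function(cohort,
                                   protocols = builtin_protocols()[
                                     c("sa060_current", "alt_L", "alt_N", "alt_O")],
                                   baseline = names(protocols)[1],
                                   model = neobase_conversion(),
                                   outdir = NULL, seed = NULL, quiet = FALSE) {
  if (inherits(cohort, "enriched_cohort")) cohort <- cohort$records
  stopifnot(is.data.frame(cohort))
  if (!nrow(cohort)) fail("run_screening_analysis: empty cohort")
  if (inherits(protocols, "protocol")) protocols <- list(protocols)
  if (is.null(names(protocols)) || any(!nzchar(names(protocols))))
    names(protocols) <- vapply(protocols, `[[`, "", "name")
  validate_cohort(cohort, require_diagnosis = TRUE)

  split <- drop_incomplete(cohort, quiet = quiet)
  cohort <- split$cohort
  excluded <- split$dropped
  unknown <- cohort$diagnosis == "unknown"
  if (any(unknown)) {
    if (!quiet)
      for (id in cohort$record_id[unknown])
        message(sprintf("excluded record %s: diagnosis unknown", id))
    ex2 <- cohort[unknown, , drop = FALSE]
    ex2$reason <- "diagnosis unknown"
    excluded <- if (nrow(excluded)) rbind(excluded, ex2) else ex2
    cohort <- cohort[!unknown, , drop = FALSE]
  }
  if (!nrow(cohort)) fail("run_screening_analysis: no evaluable records")

  panel <- compute_panel(cohort, model)
  counts <- lapply(protocols, function(p)
    tabulate_screen(classify(panel, p), cohort$diagnosis))

  performance <- do.call(rbind, lapply(names(counts), function(nm) {
    rep <- screen_metrics(counts[[nm]])
    disp <- report_display(rep)
    cbind(data.frame(protocol = nm, stringsAsFactors = FALSE), disp,
          data.frame(referral_rate_raw = rep$referral_rate,
                     sensitivity_raw = rep$sensitivity,
                     specificity_raw = rep$specificity,
                     ppv_raw = rep$ppv, npv_raw = rep$npv))
  }))
  rownames(performance) <- NULL

  ranking <- rank_protocols(counts, baseline)
  patient_table <- panel_display(panel[panel$diagnosis == "TT1", , drop = FALSE])
  rownames(patient_table) <- NULL

  bundle <- structure(list(
    performance = performance,
    ranking = ranking,
    patient_table = patient_table,
    counts = counts,
    excluded = excluded,
    config = list(
      protocols = lapply(protocols, function(p) lapply(p$criteria, format)),
      baseline = baseline,
      model = list(slope = model$slope, intercept = model$intercept,
                   variance_ratio = model$variance_ratio),
      seed = seed,
      n_records = nrow(cohort))
  ), class = "screening_reports")
  if (!is.null(outdir)) write_reports(bundle, outdir)
  bundle
}

#' @export
print.screening_reports <- function(x, ...) {
  cat(sprintf("Protocol evaluation on %d records\n\n", x$config$n_records))
  print(x$performance[, c("protocol", "tn", "fn", "tp", "fp", "referral_rate",
                          "sensitivity", "specificity", "ppv", "npv")],
        row.names = FALSE)
  cat(sprintf("\nRanking (baseline '%s', no additional false negatives):\n",
              x$config$baseline))
  print(x$ranking[, c("protocol", "fp", "fn", "ppv", "referral_rate")],
        row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `performance.csv`, `ranking.csv`, `patient_panel.csv` and
#' `run_config.json` into `dir`. Every file embeds the package version,
#' seed and configuration hash; input files are never modified.
#'
#' @param bundle output of [run_screening_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(bundle, dir) {
  stopifnot(inherits(bundle, "screening_reports"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- provenance_header(bundle$config$seed, bundle$config)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
  }
  emit(bundle$performance, "performance.csv")
  emit(bundle$ranking, "ranking.csv")
  emit(bundle$patient_table, "patient_panel.csv")
  cfg <- bundle$config
  cfg$version <- as.character(utils::packageVersion("tt1screen"))
  cfg$config_hash <- config_hash(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
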