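# Synthetic screening cohorts.
#
# The national registry data behind the published evaluation are
# restricted, so the package generates populations with the same
# statistical structure: a healthy background with low SA and moderate
# amino acids, an analytical-noise mechanism that transiently elevates SA
# only (the dominant false-positive cause), affected newborns resampled
# from the 13 published patient records, and the enriched evaluation
# cohort (45 FP referrals, 12 TP, 1 FN, 653,396 TN, 82 borderline
# samples). Every stochastic step is driven by a per-operation stream
# derived from one master seed.

#' The thirteen published TT1 patient records
#'
#' Raw biomarker concentrations of all TT1 patients detected (or, in one
#' case, missed) by the Dutch programme between October 2008 and September
#' 2024, as published: assay generation, the SA cut-off in force at
#' screening time (`era_cov`), raw SA, tyrosine and phenylalanine, and the
#' original screening result. Record `p03` is the 2010 false negative
#' (NeoBase SA 1.08 umol/L, below the then cut-off of 1.2).
#'
#' @return data frame of 13 newborn records.
#' @examples
#' fx <- tt1_patients()
#' panel_display(compute_panel(fx))
#' @export
tt1_patients <- function() {
  path <- system.file("extdata", "tt1_patients.csv", package = "tt1screen")
  if (!nzchar(path)) fail("packaged patient fixture not found")
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("era_cov", "sa", "tyr", "phe")) fx[[col]] <- as.numeric(fx[[col]])
  fx
}

#' Parameters of the synthetic healthy background population
#'
#' Independent log-normal biomarker distributions for screen-negative
#' newborns, on the NeoBase 2 scale. The published evaluation prints no
#' healthy-population distribution parameters; these defaults are chosen to
#' be realistic for newborn dried-blood-spot measurements (median SA about
#' 0.15 umol/L, well below the 0.60 cut-off; median tyrosine about 70 and
#' phenylalanine about 55 umol/L) and are fully configurable.
#'
#' @param sa_log_mean,sa_log_sd log-space parameters of healthy SA (umol/L).
#' @param tyr_log_mean,tyr_log_sd log-space parameters of tyrosine.
#' @param phe_log_mean,phe_log_sd log-space parameters of phenylalanine.
#' @return named list of parameters.
#' @export
population_params <- function(sa_log_mean = log(0.15), sa_log_sd = 0.45,
                              tyr_log_mean = log(70), tyr_log_sd = 0.35,
                              phe_log_mean = log(55), phe_log_sd = 0.25) {
  p <- list(sa_log_mean = sa_log_mean, sa_log_sd = sa_log_sd,
            tyr_log_mean = tyr_log_mean, tyr_log_sd = tyr_log_sd,
            phe_log_mean = phe_log_mean, phe_log_sd = phe_log_sd)
  if (any(!vapply(p, is.finite, TRUE)))
    fail("population_params: all parameters must be finite")
  if (p$sa_log_sd <= 0 || p$tyr_log_sd <= 0 || p$phe_log_sd <= 0)
    fail("population_params: scale parameters must be > 0")
  p
}

# Resample affected newborns from the published patient records with small
# multiplicative jitter. Thirteen patients are too few to fit a parametric
# distribution honestly, so generated patients stay close to observed ones.
# SA is taken on the effective (NeoBase 2) scale.
resample_affected <- function(n, seed, jitter = 0.10,
                              model = neobase_conversion(),
                              id_prefix = "tt1") {
  if (n == 0)
    return(data.frame(record_id = character(), assay = character(),
                      sa = numeric(), tyr = numeric(), phe = numeric(),
                      diagnosis = character(), original_result = character(),
                      stringsAsFactors = FALSE))
  fx <- tt1_patients()
  eff <- effective_sa(fx, model)
  set.seed(derive_seed(seed, "affected_resample"))
  idx <- sample.int(nrow(fx), n, replace = TRUE)
  j <- matrix(stats::runif(3 * n, 1 - jitter, 1 + jitter), nrow = n)
  data.frame(
    record_id = sprintf("%s_%05d", id_prefix, seq_len(n)),
    assay = "NeoBase2",
    sa = eff[idx] * j[, 1],
    tyr = fx$tyr[idx] * j[, 2],
    phe = fx$phe[idx] * j[, 3],
    diagnosis = "TT1",
    original_result = "not_applicable",
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic screening population
#'
#' Healthy newborns are drawn from independent log-normals; affected
#' newborns are resampled from the published patient records with small
#' multiplicative jitter (default 10%). The number of affected newborns is
#' a binomial draw at the given prevalence unless fixed via `n_affected`.
#' Deterministic given `seed`.
#'
#' @param n cohort size.
#' @param prevalence probability a newborn is affected; default about
#'   1:180,000, the rate implied by 13 patients among 2.34 million screened.
#' @param params a [population_params()] list.
#' @param seed master seed.
#' @param n_affected optionally fix the affected count (overrides the
#'   binomial draw); useful for design experiments.
#' @param jitter multiplicative jitter half-width for affected records.
#' @return cohort data frame (`record_id`, `assay`, `sa`, `tyr`, `phe`,
#'   `diagnosis`, `original_result`), assay `"NeoBase2"` throughout.
#' @export
generate_population <- function(n, prevalence = 13 / 2337400,
                                params = population_params(), seed = 1L,
                                n_affected = NULL, jitter = 0.10) {
  stopifnot(is.numeric(n), length(n) == 1, n > 0)
  if (prevalence < 0 || prevalence > 1)
    fail("generate_population: prevalence must be in [0, 1]")
  if (is.null(n_affected)) {
    set.seed(derive_seed(seed, "population_n_affected"))
    n_affected <- stats::rbinom(1, size = n, prob = prevalence)
  }
  if (n_affected > n) fail("generate_population: n_affected exceeds n")
  n_h <- n - n_affected
  set.seed(derive_seed(seed, "population_healthy"))
  healthy <- data.frame(
    record_id = sprintf("bg_%07d", seq_len(n_h)),
    assay = "NeoBase2",
    sa = stats::rlnorm(n_h, params$sa_log_mean, params$sa_log_sd),
    tyr = stats::rlnorm(n_h, params$tyr_log_mean, params$tyr_log_sd),
    phe = stats::rlnorm(n_h, params$phe_log_mean, params$phe_log_sd),
    diagnosis = "not_TT1",
    original_result = "not_applicable",
    stringsAsFactors = FALSE
  )
  rbind(healthy, resample_affected(n_affected, seed, jitter))
}

#' Inject transient analytical SA elevations
#'
#' Emulates the laboratory false-positive mechanism: low total ion
#' intensities inflate the measured SA of otherwise healthy samples while
#' leaving the amino acids untouched. Selected healthy records receive a
#' positive log-normal SA increment; the pre-elevation value is kept in
#' `sa_baseline` and the record is flagged `analytical_fp` so downstream
#' truth-keeping (e.g. re-analysis simulation) can revert to it.
#'
#' @param cohort cohort data frame.
#' @param fp_rate probability a healthy record is affected.
#' @param fp_shift `c(meanlog, sdlog)` of the additive SA increment; the
#'   default concentrates elevations around the 0.60 cut-off for a healthy
#'   background near 0.15 umol/L.
#' @param seed master seed.
#' @return the cohort with columns `sa_baseline` and `analytical_fp` added;
#'   with `fp_rate = 0` all biomarker values are unchanged.
#' @export
inject_analytical_fp <- function(cohort, fp_rate,
                                 fp_shift = c(meanlog = log(0.5), sdlog = 0.4),
                                 seed = 1L) {
  validate_cohort(cohort)
  if (fp_rate < 0 || fp_rate > 1) fail("fp_rate must be in [0, 1]")
  cohort$sa_baseline <- cohort$sa
  cohort$analytical_fp <- FALSE
  healthy <- which(cohort$diagnosis != "TT1")
  if (fp_rate > 0 && length(healthy)) {
    set.seed(derive_seed(seed, "analytical_fp"))
    hit <- healthy[stats::runif(length(healthy)) < fp_rate]
    if (length(hit)) {
      cohort$sa[hit] <- cohort$sa[hit] +
        stats::rlnorm(length(hit), fp_shift[[1]], fp_shift[[2]])
      cohort$analytical_fp[hit] <- TRUE
    }
  }
  cohort
}

#' Simulate confirmatory re-analysis of a screen-positive sample
#'
#' On an SA result above the cut-off, the laboratory re-analyses one to six
#' new extracts from the same card. Transient analytical elevations revert
#' to the underlying baseline and are not confirmed; genuine elevations
#' persist and are confirmed. If the requested repeat spread exceeds the
#' normal day-to-day variation bound, contamination of the card is
#' suspected and a fresh heel-prick sample is requested instead.
#'
#' @param record one cohort row (screen-positive on SA). If flagged
#'   `analytical_fp`, repeats are drawn around `sa_baseline`.
#' @param n_repeats number of new extracts, 1 to 6.
#' @param repeat_noise half-width of the multiplicative repeat error
#'   (uniform on `1 +/- repeat_noise`).
#' @param cov SA cut-off, umol/L.
#' @param day_to_day_cv largest repeat spread considered normal.
#' @param seed master seed.
#' @return `"confirmed"`, `"not_confirmed"` or `"request_new_sample"`.
#' @export
simulate_reanalysis <- function(record, n_repeats, repeat_noise,
                                cov = 0.60, day_to_day_cv = 0.25, seed = 1L) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (!is.numeric(n_repeats) || n_repeats < 1 || n_repeats > 6 ||
      n_repeats != round(n_repeats))
    fail("n_repeats must be an integer in 1..6")
  if (repeat_noise < 0) fail("repeat_noise must be non-negative")
  if (record$sa < cov)
    fail("record %s is not screen-positive on SA (%.2f < %.2f)",
         record$record_id, record$sa, cov)
  if (repeat_noise > day_to_day_cv) return("request_new_sample")
  underlying <- if (isTRUE(record$analytical_fp)) record$sa_baseline else record$sa
  set.seed(derive_seed(seed, paste0("reanalysis_", record$record_id)))
  reps <- underlying * (1 + stats::runif(n_repeats, -repeat_noise, repeat_noise))
  if (stats::median(reps) >= cov) "confirmed" else "not_confirmed"
}

#' Assemble an enriched evaluation cohort
#'
#' Combines a screen-negative background with referred true positives and
#' false positives from other periods, the known false negative, and the
#' borderline samples (SA in [0.60, 0.90) reported screen-negative while
#' the 0.90 cut-off was in force). The borderline samples are a category of
#' their own, disjoint from the background true negatives: the published
#' enriched-cohort arithmetic (TN 653,396 + TP 13 + FP 127 = 653,536,
#' against 45 listed FP referrals) is only consistent if the 82 borderline
#' samples are counted outside the TN background.
#'
#' @param tn_background screen-negative cohort (effective SA < 0.60,
#'   diagnosis `not_TT1`).
#' @param fixtures TT1 patient records ([tt1_patients()] or resamples);
#'   `original_result` `"negative"` marks false-negative cases.
#' @param fp_referrals referred non-TT1 records (effective SA >= 0.60).
#' @param borderline NeoBase 2 records with `0.60 <= sa < 0.90`, original
#'   result `"negative"`.
#' @param model the [conversion_model()] used for NeoBase-era records.
#' @return object of class `enriched_cohort`: list with `records` (one
#'   cohort data frame with a `category` column: `tp_referral`, `fn_case`,
#'   `fp_referral`, `tn_background`, `borderline_2018`), `composition`
#'   (category counts) and `model`. Assembly never alters a biomarker value.
#' @export
assemble_enriched <- function(tn_background, fixtures, fp_referrals,
                              borderline, model = neobase_conversion()) {
  empty <- function() data.frame(record_id = character(), assay = character(),
                                 sa = numeric(), tyr = numeric(), phe = numeric(),
                                 diagnosis = character(),
                                 original_result = character(),
                                 stringsAsFactors = FALSE)
  if (is.null(tn_background)) tn_background <- empty()
  if (is.null(fixtures)) fixtures <- empty()
  if (is.null(fp_referrals)) fp_referrals <- empty()
  if (is.null(borderline)) borderline <- empty()

  parts <- list(tn_background = tn_background, fixtures = fixtures,
                fp_referrals = fp_referrals, borderline = borderline)
  cols <- c("record_id", "assay", "sa", "tyr", "phe", "diagnosis",
            "original_result")
  parts <- lapply(parts, function(p) {
    if (nrow(p)) validate_cohort(p)
    p[, cols, drop = FALSE]
  })

  ids <- unlist(lapply(parts, `[[`, "record_id"))
  if (anyDuplicated(ids))
    fail("assemble_enriched: overlapping record id(s): %s",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))

  if (nrow(parts$tn_background)) {
    eff <- effective_sa(parts$tn_background, model)
    if (any(parts$tn_background$diagnosis != "not_TT1") || any(eff >= 0.60))
      fail("assemble_enriched: background must be not_TT1 with effective SA < 0.60")
  }
  if (nrow(parts$borderline)) {
    b <- parts$borderline
    if (any(b$assay != "NeoBase2") || any(b$original_result != "negative") ||
        any(b$sa < 0.60 | b$sa >= 0.90))
      fail("assemble_enriched: borderline records must be NeoBase2, originally negative, 0.60 <= SA < 0.90")
  }
  if (nrow(parts$fp_referrals)) {
    if (any(parts$fp_referrals$diagnosis == "TT1"))
      fail("assemble_enriched: fp_referrals must not contain TT1 records")
  }
  if (nrow(parts$fixtures) && any(parts$fixtures$diagnosis != "TT1"))
    fail("assemble_enriched: fixtures must all be TT1 records")

  category <- c(
    rep("tn_background", nrow(parts$tn_background)),
    ifelse(parts$fixtures$original_result == "negative", "fn_case", "tp_referral"),
    rep("fp_referral", nrow(parts$fp_referrals)),
    rep("borderline_2018", nrow(parts$borderline))
  )
  records <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  records$category <- category
  structure(list(records = records,
                 composition = table(factor(category, levels = c(
                   "tp_referral", "fp_referral", "fn_case",
                   "tn_background", "borderline_2018"))),
                 model = model),
            class = "enriched_cohort")
}

#' @export
print.enriched_cohort <- function(x, ...) {
  cat(sprintf("Enriched screening cohort: %d records\n", nrow(x$records)))
  print(x$composition)
  invisible(x)
}

#' Simulate the published enriched evaluation cohort
#'
#' Builds a cohort with the published composition: the 13 patient records
#' (12 referred true positives and the 2010 false negative), 45 false
#' positive referrals (15 NeoBase era, 30 NeoBase 2 era), 82 borderline
#' samples (SA in [0.60, 0.90), originally screen-negative) and a
#' synthetic screen-negative background (default 653,396 records).
#' FP-referral biomarker values are synthesized under the SA-only
#' analytical-elevation mechanism — amino acids drawn from the healthy
#' distributions, SA above the era cut-off (so every NeoBase-era FP also
#' converts above 0.60) — since per-record FP values were never published.
#'
#' @param seed master seed.
#' @param n_tn background size; the published count by default. Smaller
#'   values give a proportionally scaled-down cohort.
#' @param n_fp_neobase,n_fp_neobase2 FP referral counts per era.
#' @param n_borderline number of borderline samples.
#' @param params healthy-background [population_params()].
#' @param model the [conversion_model()] for NeoBase-era SA.
#' @return an `enriched_cohort` (see [assemble_enriched()]).
#' @export
simulate_enriched_cohort <- function(seed = 1L, n_tn = 653396L,
                                     n_fp_neobase = 15L, n_fp_neobase2 = 30L,
                                     n_borderline = 82L,
                                     params = population_params(),
                                     model = neobase_conversion()) {
  # background: healthy draws truncated below the current cut-off; the tiny
  # tail above 0.60 belongs to the FP/borderline mechanisms, not the TN pool
  set.seed(derive_seed(seed, "enriched_tn"))
  sa <- stats::rlnorm(n_tn, params$sa_log_mean, params$sa_log_sd)
  while (any(high <- sa >= 0.60))
    sa[high] <- stats::rlnorm(sum(high), params$sa_log_mean, params$sa_log_sd)
  tn <- data.frame(
    record_id = sprintf("bg_%07d", seq_len(n_tn)),
    assay = "NeoBase2", sa = sa,
    tyr = stats::rlnorm(n_tn, params$tyr_log_mean, params$tyr_log_sd),
    phe = stats::rlnorm(n_tn, params$phe_log_mean, params$phe_log_sd),
    diagnosis = "not_TT1", original_result = "negative",
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(seed, "enriched_fp"))
  n_fp <- n_fp_neobase + n_fp_neobase2
  fp <- data.frame(
    record_id = sprintf("fp_%03d", seq_len(n_fp)),
    assay = rep(c("NeoBase", "NeoBase2"), c(n_fp_neobase, n_fp_neobase2)),
    # SA above the era cut-off: raw >= 1.2 (NeoBase era) or >= 0.60 (NeoBase 2)
    sa = c(1.2 + stats::rlnorm(n_fp_neobase, log(0.4), 0.5),
           0.60 + stats::rlnorm(n_fp_neobase2, log(0.15), 0.6)),
    tyr = stats::rlnorm(n_fp, params$tyr_log_mean, params$tyr_log_sd),
    phe = stats::rlnorm(n_fp, params$phe_log_mean, params$phe_log_sd),
    diagnosis = "not_TT1", original_result = "positive",
    stringsAsFactors = FALSE
  )

  set.seed(derive_seed(seed, "enriched_borderline"))
  bl <- data.frame(
    record_id = sprintf("bl_%03d", seq_len(n_borderline)),
    assay = "NeoBase2",
    sa = stats::runif(n_borderline, 0.60, 0.90 - 1e-6),
    tyr = stats::rlnorm(n_borderline, params$tyr_log_mean, params$tyr_log_sd),
    phe = stats::rlnorm(n_borderline, params$phe_log_mean, params$phe_log_sd),
    diagnosis = "not_TT1", original_result = "negative",
    stringsAsFactors = FALSE
  )

  fx <- tt1_patients()[, c("record_id", "assay", "sa", "tyr", "phe",
                           "diagnosis", "original_result")]
  assemble_enriched(tn, fx, fp, bl, model)
}
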