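# Screening performance indicators.
#
# Confusion counts compare the screen result against the confirmed
# diagnosis; the indicators follow national-monitor display conventions:
# sensitivity/PPV/NPV as integer percentages, specificity at three decimals
# of a percent, referral rate at four decimals of a percent (all half-up),
# and prevalence as 1:N of screened newborns. Unrounded values are kept.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v < 0) || any(v != round(v)))
    fail("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Tabulate screen results against confirmed diagnoses
#'
#' @param classification per-record screen results,
#'   `"screen_positive"`/`"screen_negative"`.
#' @param diagnosis aligned per-record labels, `"TT1"`/`"not_TT1"`.
#' @return a [confusion_counts()] object; the four counts always sum to the
#'   number of records.
#' @export
tabulate_screen <- function(classification, diagnosis) {
  if (length(classification) != length(diagnosis))
    fail("classification and diagnosis must be aligned (%d vs %d)",
         length(classification), length(diagnosis))
  if (!all(classification %in% c("screen_positive", "screen_negative")))
    fail("unknown classification label(s): %s",
         paste(unique(setdiff(classification,
                              c("screen_positive", "screen_negative"))), collapse = ", "))
  if (!all(diagnosis %in% c("TT1", "not_TT1")))
    fail("unknown diagnosis label(s): %s",
         paste(unique(setdiff(diagnosis, c("TT1", "not_TT1"))), collapse = ", "))
  pos <- classification == "screen_positive"
  tt1 <- diagnosis == "TT1"
  confusion_counts(tp = sum(pos & tt1), fp = sum(pos & !tt1),
                   tn = sum(!pos & !tt1), fn = sum(!pos & tt1))
}

#' Screening performance indicators from confusion counts
#'
#' Computes referral rate, sensitivity, specificity, PPV, NPV (all in
#' percent, unrounded) and the prevalence denominator
#' `total / (tp + fn)`. Indicators whose denominator is zero are `NA`
#' (displayed as "-"). Sensitivity is provisional in a screening context —
#' false negatives may surface years later — which is carried as an
#' annotation, not a different formula.
#'
#' @param counts a [confusion_counts()] object.
#' @param provisional mark the sensitivity/NPV as provisional.
#' @return object of class `performance_report` with unrounded fields
#'   `referral_rate`, `sensitivity`, `specificity`, `ppv`, `npv` (percent),
#'   `prevalence_n`, `total` and the counts.
#' @seealso [report_display()] for the rounded report cells.
#' @export
screen_metrics <- function(counts, provisional = TRUE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total <= 0) fail("screen_metrics: zero total count")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    counts = counts,
    total = total,
    referral_rate = 100 * (tp + fp) / total,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    prevalence_n = if (tp + fn > 0) total / (tp + fn) else NA_real_,
    provisional = isTRUE(provisional)
  ), class = "performance_report")
}

#' Rounded report cells for a performance report
#'
#' Applies the display conventions: sensitivity, PPV and NPV half-up to
#' integer percent; specificity to 3 decimals of a percent; referral rate
#' to 4 decimals of a percent; the prevalence denominator to the nearest
#' integer (half-to-even, matching the printed national reports).
#'
#' @param report a `performance_report`.
#' @return one-row data frame of display values; undefined indicators are
#'   `NA`, prevalence is a `"1:N"` string.
#' @export
report_display <- function(report) {
  stopifnot(inherits(report, "performance_report"))
  rnd <- function(x, d) if (is.na(x)) NA_real_ else round_half_up(x, d)
  prev <- if (is.na(report$prevalence_n)) NA_character_ else
    paste0("1:", format(round(report$prevalence_n), big.mark = ",", scientific = FALSE))
  data.frame(
    tn = report$counts$tn, fn = report$counts$fn,
    tp = report$counts$tp, fp = report$counts$fp,
    referral_rate = rnd(report$referral_rate, 4),
    sensitivity = rnd(report$sensitivity, 0),
    specificity = rnd(report$specificity, 3),
    ppv = rnd(report$ppv, 0),
    npv = rnd(report$npv, 0),
    prevalence = prev,
    stringsAsFactors = FALSE
  )
}

#' @export
print.performance_report <- function(x, ...) {
  d <- report_display(x)
  fmt <- function(v, suffix = "%") if (is.na(v)) "-" else paste0(v, suffix)
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", d$tp, d$fp, d$tn, d$fn))
  cat(sprintf("referral rate %s  sensitivity %s%s  specificity %s  PPV %s  NPV %s\n",
              fmt(d$referral_rate), fmt(d$sensitivity),
              if (x$provisional) " (provisional)" else "",
              fmt(d$specificity), fmt(d$ppv), fmt(d$npv)))
  if (!is.na(d$prevalence)) cat(sprintf("prevalence %s\n", d$prevalence))
  invisible(x)
}

#' Rank protocols by PPV under a no-new-false-negative constraint
#'
#' Protocols whose false-negative count exceeds the baseline's are excluded
#' (a higher PPV never justifies missing a patient); the remainder are
#' ordered by descending PPV, ties broken by lower referral rate and then
#' by name.
#'
#' @param counts_list named list of [confusion_counts()], one per protocol,
#'   all evaluated on the same cohort.
#' @param baseline name of the baseline protocol; must be in `counts_list`.
#' @return data frame of retained protocols in rank order with counts and
#'   unrounded `ppv` and `referral_rate`; excluded protocol names are in
#'   `attr(, "excluded")`.
#' @export
rank_protocols <- function(counts_list, baseline) {
  if (!length(names(counts_list)) || any(!nzchar(names(counts_list))))
    fail("rank_protocols: counts_list must be a named list")
  if (!baseline %in% names(counts_list))
    fail("rank_protocols: baseline '%s' not among the evaluated protocols", baseline)
  stopifnot(all(vapply(counts_list, inherits, TRUE, "confusion_counts")))
  df <- do.call(rbind, lapply(names(counts_list), function(nm) {
    m <- screen_metrics(counts_list[[nm]])
    data.frame(protocol = nm, tp = m$counts$tp, fp = m$counts$fp,
               tn = m$counts$tn, fn = m$counts$fn,
               ppv = m$ppv, referral_rate = m$referral_rate,
               stringsAsFactors = FALSE)
  }))
  fn_base <- counts_list[[baseline]]$fn
  keep <- df$fn <= fn_base
  excluded <- df$protocol[!keep]
  df <- df[keep, , drop = FALSE]
  # undefined PPV (no positives) sorts last
  ord <- order(-ifelse(is.na(df$ppv), -Inf, df$ppv), df$referral_rate, df$protocol)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "excluded") <- excluded
  df
}
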