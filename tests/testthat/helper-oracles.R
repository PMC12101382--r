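# Independent oracles and random-case generators shared across tests.

# Brute-force classification: explicit per-record, per-criterion loop.
oracle_classify <- function(panel, protocol) {
  vapply(seq_len(nrow(panel)), function(i) {
    ok <- TRUE
    for (cr in protocol$criteria) {
      v <- panel[[cr$biomarker]][i]
      pass <- if (cr$direction == "at_least") v >= cr$cov else v <= cr$cov
      if (!isTRUE(pass)) ok <- FALSE
    }
    if (ok) "screen_positive" else "screen_negative"
  }, character(1))
}

# Random screen cohort spanning healthy-to-pathological biomarker ranges.
random_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    record_id = sprintf("r%06d", seq_len(n)),
    assay = "NeoBase2",
    sa = stats::rlnorm(n, log(0.4), 1.2),
    tyr = stats::rlnorm(n, log(120), 0.8),
    phe = stats::rlnorm(n, log(60), 0.4),
    stringsAsFactors = FALSE
  )
}

# Random protocol over the derived panel (1-4 criteria, positive cut-offs).
random_protocol <- function(panel, seed, name = "rand") {
  set.seed(seed)
  vars <- setdiff(panel_biomarkers(), "sa_raw")
  k <- sample(1:4, 1)
  picks <- sample(vars, k)
  crs <- lapply(picks, function(b) {
    v <- panel[[b]]
    criterion(b, sample(c("at_least", "at_most"), 1),
              stats::runif(1, stats::quantile(v, 0.05), stats::quantile(v, 0.95)))
  })
  protocol(name, crs)
}

# Ranking oracle: explicit pairwise comparator + selection sort.
oracle_rank <- function(counts_list, baseline) {
  rows <- lapply(names(counts_list), function(nm) {
    m <- screen_metrics(counts_list[[nm]])
    list(protocol = nm, fn = m$counts$fn,
         ppv = if (is.na(m$ppv)) -Inf else m$ppv,
         referral = m$referral_rate)
  })
  fn_base <- counts_list[[baseline]]$fn
  rows <- Filter(function(r) r$fn <= fn_base, rows)
  better <- function(a, b) {
    if (a$ppv != b$ppv) return(a$ppv > b$ppv)
    if (a$referral != b$referral) return(a$referral < b$referral)
    a$protocol < b$protocol
  }
  out <- character(0)
  while (length(rows)) {
    best <- 1
    for (j in seq_along(rows)) if (better(rows[[j]], rows[[best]])) best <- j
    out <- c(out, rows[[best]]$protocol)
    rows <- rows[-best]
  }
  out
}

# Printed patient-table derived cells (reference values frozen from the
# published overview of the 13 TT1 patients).
printed_patient_table <- function() {
  data.frame(
    record_id = sprintf("p%02d", 1:13),
    sa_eff = c(2.84, 2.52, 0.64, 3.85, 4.57, 2.95, 3.15, 1.11, 9.70, 3.06,
               0.99, 2.92, 2.03),
    tyr_times_sa = c(2354, 1106, 184, 3207, 1901, 1454, 1575, 999, 2289,
                     1741, 111, 1232, 944),
    tyr_over_sa = c(292, 174, 450, 216, 91, 167, 159, 811, 24, 186, 113,
                    145, 229),
    sa_over_tyr = c(0.003, 0.006, 0.002, 0.005, 0.011, 0.006, 0.006, 0.001,
                    0.041, 0.005, 0.009, 0.007, 0.004),
    sa_over_phe = c(0.035, 0.032, 0.009, 0.028, 0.083, 0.063, 0.053, 0.017,
                    0.173, 0.041, 0.023, 0.097, 0.023),
    tyr_over_phe = c(10.23, 5.63, 4.24, 6.08, 7.56, 10.49, 8.33, 14.06,
                     4.21, 7.59, 2.60, 14.07, 5.34),
    phe_over_tyr = c(0.10, 0.18, 0.24, 0.16, 0.13, 0.10, 0.12, 0.07, 0.24,
                     0.13, 0.38, 0.07, 0.19),
    stringsAsFactors = FALSE
  )
}
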