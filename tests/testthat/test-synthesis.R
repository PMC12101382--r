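# Synthetic cohorts: fixtures, population generator, analytical-noise FP
# mechanism, re-analysis simulation, enriched-cohort assembly.

test_that("patient fixtures carry the published records", {
  fx <- tt1_patients()
  expect_identical(nrow(fx), 13L)
  expect_identical(sum(fx$original_result == "negative"), 1L)
  expect_identical(fx$record_id[fx$original_result == "negative"], "p03")
  p09 <- fx[fx$record_id == "p09", ]
  expect_identical(c(p09$sa, p09$tyr, p09$phe), c(16.93, 236, 56))
  expect_identical(unique(fx$diagnosis), "TT1")
  expect_identical(sum(fx$assay == "NeoBase"), 10L)
})

test_that("population generation is seed-deterministic with the stated structure", {
  a <- generate_population(5000, prevalence = 0.001, seed = 21)
  b <- generate_population(5000, prevalence = 0.001, seed = 21)
  expect_identical(a, b)
  c_ <- generate_population(5000, prevalence = 0.001, seed = 22)
  expect_false(identical(a, c_))
  expect_identical(nrow(a), 5000L)
  # zero prevalence: no affected records
  none <- generate_population(10000, prevalence = 0, seed = 21)
  expect_identical(sum(none$diagnosis == "TT1"), 0L)
  # affected count matches an independent draw under the same seed policy
  set.seed(derive_seed(23, "population_n_affected"))
  expected <- rbinom(1, 100000, 1 / 1700)
  pop <- generate_population(100000, prevalence = 1 / 1700, seed = 23)
  expect_identical(sum(pop$diagnosis == "TT1"), expected)
  # affected biomarkers stay within the 10% jitter band around a fixture
  aff <- pop[pop$diagnosis == "TT1", ]
  fx <- tt1_patients()
  eff <- effective_sa(fx)
  ok <- vapply(seq_len(nrow(aff)), function(i)
    any(aff$sa[i] >= 0.9 * eff & aff$sa[i] <= 1.1 * eff &
        aff$tyr[i] >= 0.9 * fx$tyr & aff$tyr[i] <= 1.1 * fx$tyr &
        aff$phe[i] >= 0.9 * fx$phe & aff$phe[i] <= 1.1 * fx$phe), TRUE)
  expect_true(all(ok))
})

test_that("healthy log-normal parameters are recoverable from a large cohort", {
  p <- population_params()
  pop <- generate_population(100000, prevalence = 0, seed = 31)
  n <- nrow(pop)
  for (bm in c("sa", "tyr", "phe")) {
    lv <- log(pop[[bm]])
    gen_mean <- p[[paste0(bm, "_log_mean")]]
    gen_sd <- p[[paste0(bm, "_log_sd")]]
    expect_lt(abs(mean(lv) - gen_mean), 3 * gen_sd / sqrt(n))
    expect_lt(abs(sd(lv) - gen_sd), 3 * gen_sd / sqrt(2 * n))
  }
})

test_that("analytical FP injection elevates SA only, deterministically", {
  pop <- generate_population(20000, prevalence = 0, seed = 41)
  coh <- inject_analytical_fp(pop, fp_rate = 0.002, seed = 41)
  expect_identical(coh, inject_analytical_fp(pop, fp_rate = 0.002, seed = 41))
  hit <- coh$analytical_fp
  expect_gt(sum(hit), 0)
  expect_true(all(coh$sa[hit] > coh$sa_baseline[hit]))
  expect_identical(coh$tyr, pop$tyr)
  expect_identical(coh$phe, pop$phe)
  expect_identical(coh$sa[!hit], pop$sa[!hit])
  # zero rate leaves every biomarker untouched
  same <- inject_analytical_fp(pop, fp_rate = 0, seed = 41)
  expect_identical(same$sa, pop$sa)
  expect_false(any(same$analytical_fp))
})

test_that("re-analysis confirms persistent elevations and reverts transient ones", {
  pop <- generate_population(5000, prevalence = 0, seed = 51)
  coh <- inject_analytical_fp(pop, fp_rate = 0.01, seed = 51)
  fp1 <- coh[which(coh$analytical_fp & coh$sa >= 0.60)[1], ]
  expect_identical(simulate_reanalysis(fp1, n_repeats = 3, repeat_noise = 0),
                   "not_confirmed")
  # fixture patient 12 (SA 2.92, NeoBase 2) confirms for any noise <= 20%
  p12 <- tt1_patients()[12, ]
  for (noise in c(0, 0.05, 0.1, 0.2))
    for (s in 1:5)
      expect_identical(
        simulate_reanalysis(p12, n_repeats = 4, repeat_noise = noise, seed = s),
        "confirmed")
  # spread beyond the day-to-day bound: suspect contamination
  expect_identical(simulate_reanalysis(p12, n_repeats = 2, repeat_noise = 0.4),
                   "request_new_sample")
  expect_error(simulate_reanalysis(p12, n_repeats = 0, repeat_noise = 0), "1..6")
  expect_error(simulate_reanalysis(p12, n_repeats = 7, repeat_noise = 0), "1..6")
  neg <- coh[coh$sa < 0.5, ][1, ]
  expect_error(simulate_reanalysis(neg, 1, 0), "not screen-positive")
})

test_that("the enriched cohort reproduces the published composition and counts", {
  coh <- simulate_enriched_cohort(seed = 61, n_tn = 20000)
  comp <- as.list(coh$composition)
  expect_identical(comp$tp_referral, 12L)
  expect_identical(comp$fn_case, 1L)
  expect_identical(comp$fp_referral, 45L)
  expect_identical(comp$borderline_2018, 82L)
  expect_identical(comp$tn_background, 20000L)
  expect_identical(nrow(coh$records), 20140L)
  # current rule: non-TT1 screen-positives = 45 FP referrals + 82 borderline
  pan <- compute_panel(coh$records, coh$model)
  cls <- classify(pan, builtin_protocols()$sa060_current)
  expect_identical(sum(cls == "screen_positive" &
                         coh$records$diagnosis != "TT1"), 127L)
  # ...and all 13 patients refer
  expect_identical(sum(cls == "screen_positive" &
                         coh$records$diagnosis == "TT1"), 13L)
  # every NeoBase-era referral converts above the current cut-off
  nb <- coh$records$assay == "NeoBase" &
    coh$records$category %in% c("tp_referral", "fp_referral", "fn_case")
  expect_true(all(pan$sa_eff[nb] >= 0.60))
})

test_that("assembly conserves records and values and rejects bad categories", {
  bg <- generate_population(1000, prevalence = 0, seed = 71)
  bg <- bg[bg$sa < 0.60, ]
  bg$original_result <- "negative"
  fx <- tt1_patients()[, c("record_id", "assay", "sa", "tyr", "phe",
                           "diagnosis", "original_result")]
  coh <- assemble_enriched(bg, fx, NULL, NULL)
  expect_identical(nrow(coh$records), nrow(bg) + 13L)
  merged <- coh$records[coh$records$category %in% c("tp_referral", "fn_case"), ]
  expect_identical(merged$sa, fx$sa)
  expect_identical(merged$tyr, fx$tyr)
  # empty enrichment: cohort equals the background
  bare <- assemble_enriched(bg, NULL, NULL, NULL)
  expect_identical(bare$records[, names(bg)], bg, ignore_attr = TRUE)
  # overlapping ids rejected
  expect_error(assemble_enriched(bg, fx, fx[1, ], NULL), "overlapping")
  # malformed borderline rejected
  bad_bl <- data.frame(record_id = "x", assay = "NeoBase2", sa = 0.95,
                       tyr = 70, phe = 50, diagnosis = "not_TT1",
                       original_result = "negative")
  expect_error(assemble_enriched(bg, NULL, NULL, bad_bl), "borderline")
  # background containing a screen-positive rejected
  hot <- bg
  hot$sa[1] <- 0.8
  expect_error(assemble_enriched(hot, NULL, NULL, NULL), "effective SA < 0.60")
})

test_that("SA-only analytical noise makes the multi-biomarker rule beat the current rule on PPV", {
  pr <- builtin_protocols()
  for (s in 1:20) {
    pop <- generate_population(20000, prevalence = 0, seed = s, n_affected = 13)
    coh <- inject_analytical_fp(pop, fp_rate = 0.002, seed = s)
    pan <- compute_panel(coh)
    ppv <- vapply(pr[c("sa060_current", "alt_O")], function(p)
      screen_metrics(tabulate_screen(classify(pan, p), coh$diagnosis))$ppv,
      numeric(1))
    expect_gt(ppv[["alt_O"]], ppv[["sa060_current"]])
  }
})
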