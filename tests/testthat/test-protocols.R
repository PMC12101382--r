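# Protocol representation, classification, cut-off derivation, enumeration.

test_that("built-in catalogue matches the published protocol definitions", {
  pr <- builtin_protocols()
  expect_true(all(c("tyr500_2007", "sa15_2008", "sa12_2009", "sa060_current",
                    "alt_L", "alt_N", "alt_O") %in% names(pr)))
  expect_length(pr$sa060_current$criteria, 1)
  expect_length(pr$alt_O$criteria, 4)
  alt_o <- vapply(pr$alt_O$criteria, format, "")
  expect_setequal(alt_o, c("sa_eff >= 0.6", "tyr >= 100",
                           "tyr_times_sa >= 110", "tyr_over_phe >= 2.5"))
  # every catalogued protocol satisfies the protocol invariants by construction
  for (p in pr) expect_s3_class(p, "protocol")
})

test_that("classification matches published patient outcomes", {
  pan <- compute_panel(tt1_patients())
  pr <- builtin_protocols()
  # all 13 patients refer under the current rule and all three alternatives
  for (nm in c("sa060_current", "alt_L", "alt_N", "alt_O"))
    expect_identical(classify(pan, pr[[nm]]),
                     rep("screen_positive", 13))
  # the 2010 false negative (raw NeoBase SA 1.08) under the era rule
  expect_identical(classify(pan[pan$record_id == "p03", ], pr$sa12_2009),
                   "screen_negative")
  # patient 11 sits lowest on the alternative criteria and still refers
  expect_identical(classify(pan[pan$record_id == "p11", ], pr$alt_O),
                   "screen_positive")
})

test_that("a value exactly at the cut-off refers (inclusive boundary)", {
  pan <- compute_panel(data.frame(record_id = "b", assay = "NeoBase2",
                                  sa = 0.60, tyr = 100, phe = 40))
  p <- protocol("edge", list(criterion("sa_eff", "at_least", 0.60),
                             criterion("tyr", "at_least", 100)))
  expect_identical(classify(pan, p), "screen_positive")
  p2 <- protocol("edge2", criterion("phe", "at_most", 40))
  expect_identical(classify(pan, p2), "screen_positive")
})

test_that("undefined criterion values surface as errors, never silent negatives", {
  pan <- compute_panel(data.frame(record_id = c("a", "b"), assay = "NeoBase2",
                                  sa = c(0, 0), tyr = c(100, 10), phe = c(50, 50)))
  p <- protocol("needs_ratio", list(criterion("tyr_over_sa", "at_least", 20),
                                    criterion("tyr", "at_least", 100)))
  # record b already fails on tyr, so its undefined ratio is moot; record a
  # cannot be resolved and must raise
  expect_error(classify(pan, p), "unclassified")
  expect_identical(classify(pan[2, ], p), "screen_negative")
})

test_that("classify agrees with the per-criterion brute-force oracle", {
  pan <- compute_panel(random_cohort(2000, seed = 41))
  for (s in 1:8) {
    p <- random_protocol(pan, seed = 100 + s)
    expect_identical(classify(pan, p), oracle_classify(pan, p))
  }
})

test_that("adding criteria or tightening cut-offs never adds referrals", {
  pan <- compute_panel(random_cohort(3000, seed = 42))
  set.seed(7)
  for (s in 1:6) {
    p <- random_protocol(pan, seed = 200 + s)
    n0 <- sum(classify(pan, p) == "screen_positive")
    extra <- random_protocol(pan, seed = 300 + s)$criteria[[1]]
    if (!extra$biomarker %in% vapply(p$criteria, `[[`, "", "biomarker")) {
      p_plus <- protocol("plus", c(p$criteria, list(extra)))
      expect_lte(sum(classify(pan, p_plus) == "screen_positive"), n0)
    }
    # tighten the first criterion
    cr <- p$criteria[[1]]
    cr2 <- criterion(cr$biomarker, cr$direction,
                     if (cr$direction == "at_least") cr$cov * 1.5 else cr$cov * 0.5)
    p_tight <- protocol("tight", c(list(cr2), p$criteria[-1]))
    expect_lte(sum(classify(pan, p_tight) == "screen_positive"), n0)
  }
})

test_that("derive_cov anchors cut-offs to patient extremes with a safety margin", {
  fx <- tt1_patients()
  pan <- compute_panel(fx)
  expect_identical(derive_cov(pan$tyr, "at_least", 50), 100)          # min 112
  expect_identical(derive_cov(pan$phe_over_tyr, "at_most", 0.1), 0.5) # max 0.38
  # single value on the grid: retained, cut-off stays positive
  cov1 <- derive_cov(100, "at_least", 100)
  expect_true(cov1 > 0 && 100 >= cov1)
  # no-exclusion contract, brute force over all 13 patients and several grids
  for (b in c("tyr", "tyr_times_sa", "tyr_over_phe")) {
    for (g in c(1, 5, 10, 50)) {
      cov <- derive_cov(pan[[b]], "at_least", g)
      expect_true(all(pan[[b]] >= cov), info = paste(b, g))
    }
  }
  for (g in c(0.05, 0.1, 0.25)) {
    cov <- derive_cov(pan$phe_over_tyr, "at_most", g)
    expect_true(all(pan$phe_over_tyr <= cov))
  }
  expect_error(derive_cov(numeric(0), "at_least", 1), "empty")
  expect_error(derive_cov(1, "at_least", 0), "granularity")
})

test_that("the default grid enumerates 30 distinct protocols containing L, N and O", {
  grid <- default_alternative_grid()
  expect_length(grid$singletons, 13)
  expect_length(grid$addon_sets, 17)
  protos <- enumerate_alternatives(grid$base, grid$singletons, grid$addon_sets)
  expect_length(protos, 30)
  sig <- function(p) paste(sort(vapply(p$criteria, format, "")), collapse = ";")
  sigs <- vapply(protos, sig, "")
  expect_identical(anyDuplicated(sigs), 0L)
  for (nm in c("alt_L", "alt_N", "alt_O"))
    expect_true(sig(builtin_protocols()[[nm]]) %in% sigs)
  # enumerated protocols classify the published patients as the oracle does
  pan <- compute_panel(tt1_patients())
  for (p in protos)
    expect_identical(classify(pan, p), oracle_classify(pan, p))
  expect_error(enumerate_alternatives(), "empty candidate grid")
  # degenerate grid: a single singleton yields a single protocol
  expect_length(enumerate_alternatives(
    singletons = list(criterion("tyr", "at_least", 100))), 1)
})

test_that("protocol config files round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".cfg")
  pr <- builtin_protocols()[c("sa060_current", "alt_N", "alt_O")]
  write_protocols(pr, path)
  back <- read_protocols(path)
  expect_identical(names(back), names(pr))
  for (nm in names(pr))
    expect_identical(vapply(back[[nm]]$criteria, format, ""),
                     vapply(pr[[nm]]$criteria, format, ""))
  expect_error(protocol("dup", list(criterion("tyr", "at_least", 100),
                                    criterion("tyr", "at_least", 200))),
               "duplicate")
})
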