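Package: tt1screen
Title: Evaluation of Succinylacetone-Based Newborn Screening Protocols for
    Tyrosinemia Type 1
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate and improve dried-blood-spot newborn screening
    for tyrosinemia type 1 (TT1). Provides Deming method-comparison regression
    to harmonize succinylacetone (SA) concentrations across assay generations
    (NeoBase to NeoBase 2), computation of derived biomarker panels (ratios and
    the tyrosine x SA product), conjunction-of-cutoff screening protocols,
    screening performance indicators (sensitivity, specificity, predictive
    values, referral rate, prevalence), protocol ranking under a
    no-new-false-negative constraint, and a synthetic cohort generator that
    emulates an enriched national screening population so protocol changes can
    be tested without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
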