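---
title: "Methods: evaluating succinylacetone-based screening protocols for tyrosinemia type 1"
author: "tt1screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating TT1 screening protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tt1screen)
```

## The screening problem

Tyrosinemia type 1 (TT1) is a rare autosomal recessive defect of
fumarylacetoacetate hydrolase in the tyrosine catabolic pathway. The toxic
metabolite succinylacetone (SA) accumulates and is considered pathognomonic,
so newborn-screening programmes measure SA in dried blood spots (DBS) by
flow-injection tandem mass spectrometry. The Dutch programme screened with
the NeoBase assay (2008–2017, SA cut-offs 1.5 then 1.2 µmol/L blood) and
the NeoBase 2 assay since 2018 (cut-off 0.90, then 0.60 µmol/L from April
2019). A single low cut-off on SA catches essentially every patient but
refers many healthy newborns, because transient analytical artefacts — low
total ion intensities ahead of instrument maintenance — inflate measured SA
only. The package implements the evaluation machinery for this setting:
cross-assay harmonization, derived biomarker panels, conjunction-of-cutoff
protocols, performance indicators, and synthetic cohorts on which protocol
changes can be compared.

## Cross-assay harmonization

SA concentrations differ systematically between the two assay generations.
NeoBase-era values are placed on the NeoBase 2 scale with the published
method-comparison line

$$\mathrm{SA}_{\mathrm{NB2}} = 0.019 + 0.572 \times \mathrm{SA}_{\mathrm{NB}},$$

shipped as `neobase_conversion()`. `fit_deming()` provides the estimator
behind such lines: closed-form errors-in-variables (Deming) regression with
an assumed error-variance ratio $\delta$ (y-error over x-error). With
centred second moments $s_{xx}, s_{yy}, s_{xy}$,

$$\hat\beta = \frac{s_{yy} - \delta s_{xx} +
  \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}},
  \qquad \hat\alpha = \bar y - \hat\beta \bar x.$$

Two algebraically equivalent forms of $\hat\beta$ are switched on the sign
of $s_{yy} - \delta s_{xx}$ to avoid catastrophic cancellation, so the
estimate converges cleanly to ordinary least squares of $y$ on $x$ as
$\delta \to \infty$. The variance ratio used for the original 1093-pair
calibration was never published; the default is $\delta = 1$ (orthogonal
regression), exposed as a parameter rather than inferred. `fit_deming()`
exists to validate and reuse the machinery — the published coefficients are
a constant, since the calibration pairs themselves are restricted.

Converted SA is rounded **half-up to two decimals** before any downstream
use. This is a substantive convention, not cosmetics: recomputing the
13-patient reference table works cell-for-cell only when ratios and
products are formed from the two-decimal effective SA (patient 4:
$833 \times 3.85 = 3207.05 \to 3207$, while the unrounded conversion
3.8514 would give 3208). Half-up rounding uses a $10^{-9}$ epsilon guard
because quotients such as $3.15/60 = 0.0525$ sit just below their decimal
tie in binary floating point. Other biomarkers need no conversion between
the assay generations.

## Derived biomarker panel

`compute_panel()` produces, per newborn: effective SA (`sa_eff`), raw SA,
tyrosine (tyr), phenylalanine (phe), the product `tyr_times_sa`
(µmol²/L², analogous to the IRT × PAP product in cystic fibrosis
screening) and the ratios tyr/SA, SA/tyr, SA/phe, tyr/phe and phe/tyr.
Stored values keep full precision; `panel_display()` applies the report
conventions (products and tyr/SA to integers, SA/tyr and SA/phe to three
decimals, tyr/phe and phe/tyr to two, all half-up). A zero denominator
marks that ratio undefined (`NA`) instead of dropping the record; records
missing a core analyte are excluded explicitly by `drop_incomplete()` with
one logged message each, since every multi-biomarker protocol needs all
three analytes.

## Protocols and classification

A protocol is a conjunction of directional threshold criteria; a newborn is
screen-positive iff **every** criterion holds. Comparisons are inclusive
(≥/≤), matching the notation in which all cut-offs are printed; no
published case sits exactly on a cut-off, so the printed record cannot
discriminate inclusive from strict — we fix the convention once and state
it. Historical-era rules (`sa15_2008`, `sa12_2009`, `sa090_2018`) are
evaluated against the raw era-scale SA (`sa_raw`), because that is the
scale on which they operated; the current rule and all alternatives use the
effective SA. The catalogue `builtin_protocols()` contains the national
protocol history and the three published best alternatives (L, N, O), e.g.
alternative O: SA ≥ 0.60, tyr ≥ 100, tyr × SA ≥ 110, tyr/phe ≥ 2.5.

`derive_cov()` encodes how non-SA cut-offs were anchored to the lowest (or
highest) values among confirmed patients, on a granularity grid with a
safety margin: for elevated markers, the largest grid multiple strictly
below the patient minimum (tyr: minimum 112 → cut-off 100 on a grid of
50); for lowered markers, the smallest multiple at or above the maximum
plus one further step (phe/tyr: maximum 0.38 → 0.5 on a grid of 0.1). The
asymmetric extra step for `at_most` is what the chosen published cut-offs
imply; a derived cut-off never excludes a supplied patient value, and the
fallback when no positive grid multiple exists is the patient extreme
itself.

Thirty alternative protocols were evaluated in the original design — 13
single-biomarker variants and 17 SA-based combinations — but only the
three best are public. `default_alternative_grid()` is therefore a
**reconstruction**: it reproduces the counts (13 + 17) and contains L, N
and O exactly; the other members are plausible grid points anchored to the
patient-derived cut-offs. `enumerate_alternatives()` is fully grid-driven,
so a different reconstruction is one argument away.

## Performance indicators

From TP/FP/TN/FN counts, `screen_metrics()` computes referral rate
$(TP+FP)/n$, sensitivity, specificity, PPV, NPV and the prevalence
denominator $n/(TP+FN)$, all unrounded; `report_display()` renders the
national-report cells (sensitivity/PPV/NPV to integer percent, specificity
to three decimals, referral rate to four, half-up; the prevalence
denominator uses base-R `round()`, whose half-to-even behaviour matches
the printed 693,821/2 → 1:346,910). Undefined indicators (zero
denominator) display as "-", never as 0 or 100. Sensitivity is flagged
provisional: in screening, a false negative can surface a decade after the
heel prick, so 100% is a statement about current knowledge, carried as an
annotation rather than a different formula. `rank_protocols()` implements
the selection rule: any protocol with more false negatives than the
baseline is excluded outright, the rest are ordered by PPV (ties: lower
referral rate, then name) — a higher PPV never buys a missed patient.

## Synthetic cohorts

The national registry data are restricted, so the generator emulates their
structure rather than their records:

* **Healthy background** — independent log-normals per analyte. No healthy
  distribution parameters were ever published; the defaults (SA
  meanlog log 0.15, sdlog 0.45; tyr log 70, 0.35; phe log 55, 0.25, all
  µmol/L whole blood) were chosen once as realistic newborn DBS values
  whose medians sit where the published distribution plots put the
  true-negative mass, and are fully configurable via
  `population_params()`.
* **Affected newborns** — resampled from the 13 published patient records
  with ≤10% multiplicative jitter per analyte (`generate_population()`).
  Thirteen patients are too few to fit a parametric TT1 distribution
  honestly; resampling keeps generated patients inside the observed range.
* **Analytical false positives** — `inject_analytical_fp()` adds a
  positive log-normal increment to SA only (default meanlog log 0.5,
  sdlog 0.4, placing elevations around the 0.60 cut-off), leaving the
  amino acids untouched. This is the mechanism that makes multi-biomarker
  rules pay off, and the pre-elevation baseline is retained so
  `simulate_reanalysis()` can model confirmatory re-testing: one to six
  new extracts, transient elevations revert (not confirmed), persistent
  ones confirm, and a repeat spread beyond normal day-to-day variation
  (default 25%) triggers a fresh-sample request.
* **Enriched evaluation cohort** — `simulate_enriched_cohort()` rebuilds
  the published composition: 12 true-positive referrals and the 2010
  missed case (the packaged fixtures), 45 false-positive referrals
  (15 NeoBase-era with raw SA above 1.2, hence converting above 0.60;
  30 NeoBase 2-era above 0.60), 82 borderline samples (SA in
  [0.60, 0.90), originally reported negative under the interim 0.90
  cut-off) and 653,396 screen-negative background records. The published
  arithmetic (TN 653,396 + TP 13 + FP 127 = 653,536 against 45 listed FP
  referrals) is consistent only if the 82 borderline samples form a
  category **outside** the TN background; `assemble_enriched()` encodes
  exactly that, which is why the current rule's false-positive count of
  127 (45 + 82) is reproduced by construction, independent of the random
  seed. FP-referral amino acids are synthetic draws from the healthy
  distributions — the record-level FP values were never published, so the
  alternatives' exact FP counts (8/7/5) are not reproducible record by
  record; what the synthetic cohort does reproduce is the mechanism:
  SA-only elevations that the added biomarkers filter out.

One master seed drives everything through per-operation streams
(`derive_seed(seed, salt)`), so runs are reproducible and adding draws to
one stage never perturbs another; the seed is recorded in every output
header, and identical configurations produce byte-identical report
bundles.

## What passing tests do and do not show

The test suite reproduces every printed cell of the reference patient
table and era/protocol reports, verifies the estimator and classifier
against independent oracles (PCA-based orthogonal regression, OLS limits,
per-criterion brute force, a pairwise-comparator ranking oracle), and
checks the structural properties — conjunction and threshold monotonicity,
cut-off derivation that never excludes a patient, PPV improvement of the
multi-biomarker rule over 20 seeds under injected SA-only noise, and
parameter recovery of the healthy distributions at n = 100,000 within
three Monte-Carlo standard errors. Problem sizes were chosen for
statistical adequacy: 10,000 random panels for classifier equivalence,
1093 pairs for the noisy calibration (matching the original calibration
size, with tolerances frozen at six sigma of a 2000-replicate Monte-Carlo
of the estimator), 20,000-record cohorts per seed for the PPV experiment,
and the full 653,536-record cohort in the acceptance script.

Passing these tests shows the machinery is correct and the published
evaluation is internally reproducible. It does **not** show that the
synthetic healthy distributions match the Dutch newborn population — real
DBS analytes are correlated, depend on age at sampling, gestational age
and transfusion status (covariates the generator deliberately omits), and
real analytical artefacts cluster in time by instrument rather than
arriving independently. Conclusions about real screening performance
require the restricted registry data.

## Known limitations

* Only conjunctive (AND) threshold rules are represented — no disjunctions,
  scores, or second-tier assays on other analytes.
* The 30-protocol grid is a reconstruction beyond its three published
  members.
* Era-protocol evaluation assumes the raw SA stored for NeoBase-era
  records is the value the era rule saw; re-analysis history of historical
  referrals is not modelled.
* Prevalence, jitter width and false-positive rates are scalar knobs; they
  emulate composition, not biology.
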