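---
title: "Methods: feature model, cohort simulation and the diagnostic rule list"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature model, cohort simulation and the diagnostic rule list}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesiondx)
```

## The problem and the data model

Glioblastoma presenting with multiple foci (mGB) and multifocal CNS
lymphoma (mCNSL) overlap in their initial MRI appearance. The quantitative
handles this package implements are (i) lesion geometry and morphology on
contrast-enhanced T1, (ii) contralateral-normalized ADC and FLAIR ratios of
the tumor and of perilesional tissue at 5, 10 and 20 mm, and (iii)
modality-gated perfusion and SWI findings.

A cohort is a tibble with one row per lesion. Patient-level fields
(entity, subtype, perfusion/SWI availability) repeat across a patient's
rows; each patient carries 2–10 lesions (single-lesion and >10-lesion
presentations are out of scope, matching the study design the defaults
emulate). Normalization is a plain quotient: a tumor ADC ratio of 0.89
means the tumor ADC is 11 % below contralateral normal-appearing white
matter. The modality convention is strict and validated: perfusion flags
(`rcbv_increased`, `typical_curve`) are present on every lesion of a
perfusion-available patient and absent (`NA`) otherwise, never zero; the
same holds for SWI flags. The 10/20 mm gradient ratios may be absent
("when feasible" measurements), the 5 mm ratio is mandatory.

## The synthetic cohort generator

Published cohort summaries report mean ± SD and range per feature, and
counts per category. The generator treats these as the *population* to
emulate:

* **Family.** Each continuous feature is a normal distribution truncated
  to the printed range. With only first and second moments and a range
  published, the truncated normal adds no invented skewness while
  enforcing the printed support exactly. `calibrate_truncated_normal()`
  solves the two closed-form moment equations for the parent (μ, σ):
  the mean equation is solved by root finding in μ at fixed σ (the
  truncated mean is monotone in μ), and σ by a monotone geometric search;
  both moments are matched to a relative tolerance of 1e-6.
* **Infeasible SD targets.** A truncated normal on [L, U] cannot exceed
  the SD of its exponential limit law; in particular the SD can never
  reach mean − L. Several printed triples violate this (e.g. mGB edema
  6.6 ± 8.4 mm on [0, 40]; mGB inter-lesion distance 14.0 ± 14.4 mm on
  [1, 73]; both lesion-count laws). For these the calibrator's strict mode
  raises an error naming the maximal feasible SD, and the generator uses
  its cap mode: the mean is matched exactly and the SD is set to the
  largest value the family attains (for the mGB edema law about 6.4 mm
  instead of 8.4). The affected fields do not drive the classifier's
  headline features.
* **Lesion counts.** Drawn from the calibrated count law, rounded to the
  nearest integer and clamped to the printed range (2–7 for mGB, 2–10 for
  mCNSL). Rounding is not re-calibrated; the induced bias on the mean is
  below 0.1 lesions per patient (the test suite checks recovery of 3.8
  within ±0.1 at ≥10⁴ lesions).
* **Categories and flags.** Morphology and location are drawn from the
  printed proportions renormalized to 1. The published mCNSL location
  rows sum to 194/187 lesions (locations are evidently not mutually
  exclusive); the generator renormalizes, and the deterministic fixture
  apportions the printed counts to 187 by largest remainder. The mCNSL
  morphology rows sum to 184/187 with a further "nodular adjacent to the
  dura" mention; the three unaccounted lesions are tagged
  `extra_axial_nodular`, keeping the five main row counts authoritative.
* **Gradients.** The three perilesional ratios are drawn independently
  and then sorted ascending within each lesion, since the published
  profiles increase with distance in every group. Sorting preserves the
  pooled moments only approximately for the individual distances; the
  tumor-level ratios (which the headline checks use) are unaffected.
* **Independence.** Features are drawn independently within a lesion and
  across lesions. No inter-feature correlation (e.g. size vs edema) is
  published; independence is an explicit modeling choice, not a claim
  about the real cohorts. Likewise the typical perfusion curve is drawn
  per lesion at the printed lesion-level rate (23/73 for mCNSL, 0 for
  mGB); because real typical curves cluster within patients, the
  patient-level "any lesion typical" rate of a synthetic cohort exceeds
  the printed patient-level rate (0.53), so patient-level perfusion
  metrics should be read from the fixture, not the generator.
* **Subtypes** (multifocal/multicentric, PCNSL/SCNSL) are drawn at the
  printed patient proportions (38/12 per 50) independently of the
  lesion-level FLAIR-connection flags; the two are not cross-constrained.

Consequently, passing parameter-recovery tests shows the generator
reproduces the printed *summaries*; it does not show that real lesion
feature joints are captured. Simulated AUCs are expected to land near the
Gaussian closed form rather than exactly on values estimated from the
(skewed) empirical distributions.

## The deterministic fixture

`build_fixture_cohort()` reconstructs every published count exactly
(181/187 lesions, the morphology and location tallies, 37/50 and 17/50
perfusion patients with 134/73 lesions, 23 typical-curve lesions across
exactly 9 patients, contrast/FLAIR-connection/rCBV/SWI counts).
Continuous fields are filled with the group median where one is published
and the group mean otherwise, so the fixture supports count-based checks
only; distributional tests use the generator. Where the running text and
the summary tables disagree (mCNSL inter-lesion distance 22.8 ± 18.7 in
text vs 19.4 ± 14.7 in both tables; mGB edema 6.6 ± 8.4 in text vs
5.9 ± 8.2 in one table), the package follows the tables when they agree
with each other and the text when it alone supplies the range needed for
truncation.

## Statistics

* **t-test.** The sources say only "two-sided t-tests"; the default here
  is Welch (unequal variances not assumed away) with Student's pooled
  variant behind a flag for reproduction. Identical constant groups
  return statistic 0, p = 1; zero variance in both groups with different
  means is a domain error.
* **Two-proportion test.** The published tables label these "binomial
  test" without specifying the construction; the package uses Fisher's
  exact conditional test, which is exact at the small denominators
  involved and is verified against full hypergeometric enumeration for
  n ≤ 30 in the test suite.
* **Tukey HSD** uses the studentized range with Tukey–Kramer standard
  errors via a one-way fit, the standard approach for unequal group
  sizes.
* **Bonferroni** is the plain α/m identity; which m parameters form the
  family is taken as an explicit argument (the published family was
  m = 20, giving 0.0025).
* The SD of a single observation is reported absent, not zero.

## ROC and threshold selection

The AUC is computed by the rank (Mann–Whitney) formula with half credit
for ties, which equals the trapezoidal area under the empirical
staircase; it is invariant under strictly monotone transforms of the
scores. Candidate thresholds sit at midpoints between adjacent distinct
scores plus ∓∞ sentinels, so a reported cut-off like "< 0.87 for
detecting mCNSL" is reproducible as an open-interval rule
(`positive_class_low`). When no direction is given, the orientation with
AUC ≥ 0.5 is chosen. At equal Youden's J the tie-break prefers the more
specific cut, then the cut closest to the grand score median — the
specificity preference mirrors the rule ordering of the diagnostic
algorithm, and the median proximity keeps degenerate all-tied inputs at a
central, reproducible cut. The optimizer is verified against exhaustive
search on every random instance up to 50 scores, and the empirical AUC
against the Gaussian closed form Φ(Δμ/√(σ₁²+σ₀²)) at n = 10⁵.

## The diagnostic rule list

Each candidate feature yields one directed rule voting for mCNSL:
boolean/morphology features take the direction (present/absent) in which
they are more frequent in mCNSL; continuous features are cut at the
Youden optimum of their patient-level means (the published rule rows are
"mean" ratios; boolean features use any-lesion semantics, which is the
only reading that reconciles the published perfusion row with its patient
counts). Rules are retained when significant at α (default 0.05/20) and
ordered: perfusion first, specificity-1.00 rules next, the rest by
descending J. Pre-registered thresholds (e.g. diameter < 20 mm, tumor ADC
ratio < 0.87, perilesional ADC ratio > 1.88) can be injected to bypass
fitting; injected rules skip the significance gate.

The published flowchart does not specify what happens when an early rule
does not fire, so traversal is a design choice here: under the default
`first_hit`, one-sided rules (direction "present", and threshold rules)
fall through when the marker is on the non-voting side, while the
morphology rule (direction "absent") is a two-sided split — a patient
*with* cystic or cystic–solid lesions is classified mGB at that node.
Rules whose modality is unavailable are skipped and logged in the trace;
a patient no rule can classify is an abstention (or the cohort majority
class under the `majority` policy). The alternative `weighted_vote`
aggregation lets every evaluable rule vote both ways with weight J and
decides by the sign of the sum. Per-rule evaluation metrics always use
the two-sided reading over the records where the rule's modality is
available, which is what reproduces the published per-rule table
denominators.

Because the fixture fills continuous features with group constants,
tree fitting on the fixture is restricted to the categorical/boolean
candidates (a Welch test on zero-variance groups is undefined);
full-tree fits are exercised on synthetic cohorts.

## Problem sizes and tolerances

The test and acceptance runs use 3 000 patients per entity (≈11 000
lesions) for parameter recovery, 10⁵ lesions per class for AUC
convergence, 100 replicates at the printed group sizes (181 vs 187) for
the separation p-value, and 60–200 random instances for each oracle
equivalence sweep. Moment calibration is exact to 1e-6 relative; sampled
moments are checked within three standard errors; simulated AUCs within
0.01–0.03 of their anchors. One published-frequency check deserves a
caveat: at group sizes 181/187 and moments 1.05 ± 0.35 vs 0.89 ± 0.36 the
noncentrality of the two-sample t-test is ≈4.3, so the power of a
two-sided level-0.001 test is ≈0.85 — a requirement that ≥95 % of
replicates reach p < 0.001 cannot be met by these population parameters,
although the median replicate p is on the order of 10⁻⁵.

## Known limitations

* No image processing: features arrive as measured values; DICOM/NIfTI
  handling, segmentation and perfusion curve fitting are out of scope.
* The generator's independence and truncated-normal assumptions make it a
  summary-faithful surrogate, not a joint-distribution model of real
  cohorts; SD-capped fields under-disperse relative to the printed SDs.
* Only the perfusion rule's published metrics can be reconciled exactly
  (its evaluation unit and denominators are printed); the remaining
  published rule rows are covered by rank/ordering checks, not value
  reproduction.
* No cross-validation or external validation machinery is provided; the
  rule list is evaluated on its fitting cohort, as in the source design.
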