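# lesiondx

Differentiating **multifocal CNS lymphoma (mCNSL)** from **glioblastoma with
multiple foci (mGB)** on initial MRI is a recurring clinical problem: both
entities present with 2–10 enhancing lesions, and the work-up and treatment
differ sharply (biopsy + chemotherapy for lymphoma, resection for
glioblastoma). `lesiondx` packages the quantitative side of that
differential for neuroradiology researchers: lesion-level feature tables,
contralateral-normalized signal ratios, the standard comparison statistics,
ROC/Youden threshold derivation, and an interpretable ordered rule-list
classifier — plus a synthetic cohort generator calibrated to published
group summaries, so every step can be exercised and tested without patient
data.

## What it computes

**Features.** Each lesion carries geometry (mean diameter over three axes,
edema extent, nearest-lesion distance), a morphology category (solid,
cystic, mixed cystic–solid, cortical infiltration, stripe-/tree-shaped,
extra-axial nodular), and contralateral-normalized intensity ratios

```
ratio = S_lesion / S_contralateral_white_matter
```

for ADC and FLAIR, in the tumor and in perilesional tissue at 5/10/20 mm
(the infiltration-zone gradient). Perfusion (increased rCBV, the typical
time–signal intensity curve with T1-leakage and high signal recovery) and
SWI findings (hemorrhage, vascularization) enter as modality-gated boolean
flags.

**Statistics.** Two-sided Welch/Student t-tests, an exact two-proportion
test, Tukey HSD across subgroups (Tukey–Kramer for unequal n), and the
Bonferroni per-test level α/m.

**ROC / Youden.** Empirical ROC curves with Mann–Whitney AUC (half credit
for ties), threshold selection by maximizing Youden's
J = sensitivity + specificity − 1 (cut-offs reported at midpoints between
adjacent scores), and the Gaussian closed form
Φ(|μ₁ − μ₀| / √(σ₁² + σ₀²)) as an analytic oracle.

**Classifier.** `fit_tree()` derives one directed rule per candidate
feature, keeps those significant at the Bonferroni level, and orders them
as the published algorithm prescribes: MR perfusion first, then rules with
specificity 1.00, then the rest by descending J. `classify_patient()`
walks the list (skipping rules whose modality is missing and logging a
trace); `evaluate_tree()` scores each rule and the full traversal with
accuracy / sensitivity / specificity / PPV / NPV.

**Simulation.** `default_config()` holds the published per-entity
summaries (e.g. mCNSL tumor ADC ratio 0.89 ± 0.36; mGB diameter
24.8 ± 16.0 mm on [2, 83]); `calibrate_truncated_normal()` solves for the
parent (μ, σ) whose truncated law attains the printed mean and SD exactly,
and `sample_cohort()` draws labeled cohorts that recover the printed
moments and category frequencies.

## Worked example

```r
library(lesiondx)

# the published perfusion rule as a 2x2 worked example:
# 9/17 mCNSL perfusion patients with a typical curve, 0/37 mGB patients
confusion_metrics(tp = 9, fp = 0, tn = 37, fn = 8)[, 5:9]
#>   accuracy sensitivity specificity ppv   npv
#> 1    0.852       0.529           1   1 0.822

# fit the rule list on a synthetic study-style cohort
co   <- sample_study_cohort(n_mgb = 200, n_mcnsl = 200, seed = 42)
tree <- fit_tree(co)
tree$rules[, c("feature", "direction", "threshold", "J")]
#>                 feature direction threshold     J
#> 1         typical_curve   present        NA 0.812
#> 2        stripe_or_tree   present        NA 0.450
#> 3     cystic_morphology    absent        NA 0.665
#> 4 flair_ratio_edema_5mm less_than     1.344 0.515
#> 5       adc_ratio_tumor less_than     0.954 0.365
#> 6   adc_ratio_edema_5mm less_than     1.361 0.270
#> 7           diameter_mm less_than    21.018 0.250

evaluate_tree(tree, co)$overall$accuracy
#> [1] 0.885

# lesion-level ROC for the tumor ADC ratio (lower values flag lymphoma)
rc <- roc_curve(co$adc_ratio_tumor, co$entity == "mCNSL")
round(auc(rc), 3)
#> [1] 0.625
```

The rule order shows the algorithm's logic: the perfusion rule leads, the
perfect-specificity stripe rule follows, and the remaining significant
rules descend by J. The AUC of 0.625 matches the Gaussian closed form for
group moments 0.89 ± 0.36 vs 1.05 ± 0.35 — tumor ADC is a real but modest
discriminator at the lesion level, which is exactly why the algorithm
stacks several rules.

Deterministic count-exact reconstruction of the published cohorts is
available via `build_fixture_cohort()`; `run_pipeline(pipeline_config())`
executes generate → summarize → compare → roc → fit → evaluate end to end
and writes all artifacts (cohort CSV, summary tables, tree JSON,
evaluation CSV, log) deterministically.

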