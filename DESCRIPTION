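Package: lesiondx
Title: MRI Feature Analysis and Rule-Based Differentiation of Multifocal
    CNS Lymphoma and Multifocal Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lesion-level feature tables, contralateral-normalized ADC and
    FLAIR ratio computations, the statistical battery (Welch/Student t,
    exact two-proportion, Tukey HSD, Bonferroni) and ROC analysis with
    Youden's-J-optimal thresholds used to differentiate central nervous
    system lymphoma with multiple lesions (mCNSL) from glioblastoma with
    multiple foci (mGB) on initial MRI. Includes a moment-calibrated
    truncated-normal synthetic cohort generator, a deterministic
    count-exact fixture cohort, and an ordered rule-list diagnostic
    classifier (perfusion first, perfect-specificity rules next, the rest
    by descending Youden's J) scored with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
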