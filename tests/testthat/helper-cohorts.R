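# Small hand-built cohorts used across test files.

# A minimal well-formed lesion row; override fields as needed.
lesion_row <- function(patient_id, entity = "mGB",
                       subtype = if (entity == "mGB") "multifocal" else "PCNSL",
                       lesion_id = 1L,
                       perfusion_available = FALSE, swi_available = FALSE,
                       diameter_mm = 20, morphology = "solid",
                       location = "frontal_lobe", edema_mm = 5,
                       nearest_lesion_distance_mm = 10,
                       flair_connected = TRUE, contrast_enhancing = TRUE,
                       adc_ratio_tumor = 1.0, adc_ratio_edema_5mm = 1.8,
                       adc_ratio_edema_10mm = 2.0, adc_ratio_edema_20mm = 2.2,
                       flair_ratio_tumor = 1.6, flair_ratio_edema_5mm = 1.8,
                       flair_ratio_edema_10mm = 1.8,
                       flair_ratio_edema_20mm = 1.8,
                       rcbv_increased = NA, typical_curve = NA,
                       swi_hemorrhage = NA, swi_vascularization = NA) {
  tibble::tibble(
    patient_id = patient_id, entity = entity, subtype = subtype,
    perfusion_available = perfusion_available, swi_available = swi_available,
    lesion_id = as.integer(lesion_id), diameter_mm = diameter_mm,
    morphology = morphology, location = location, edema_mm = edema_mm,
    nearest_lesion_distance_mm = nearest_lesion_distance_mm,
    flair_connected = flair_connected, contrast_enhancing = contrast_enhancing,
    adc_ratio_tumor = adc_ratio_tumor,
    adc_ratio_edema_5mm = adc_ratio_edema_5mm,
    adc_ratio_edema_10mm = adc_ratio_edema_10mm,
    adc_ratio_edema_20mm = adc_ratio_edema_20mm,
    flair_ratio_tumor = flair_ratio_tumor,
    flair_ratio_edema_5mm = flair_ratio_edema_5mm,
    flair_ratio_edema_10mm = flair_ratio_edema_10mm,
    flair_ratio_edema_20mm = flair_ratio_edema_20mm,
    rcbv_increased = rcbv_increased, typical_curve = typical_curve,
    swi_hemorrhage = swi_hemorrhage,
    swi_vascularization = swi_vascularization
  )
}

# Two-patient, two-entity, well-formed mini cohort.
tiny_cohort <- function() {
  as_cohort(dplyr::bind_rows(
    lesion_row("gb1", "mGB", lesion_id = 1, morphology = "cystic"),
    lesion_row("gb1", "mGB", lesion_id = 2, morphology = "solid"),
    lesion_row("ly1", "mCNSL", lesion_id = 1, adc_ratio_tumor = 0.7),
    lesion_row("ly1", "mCNSL", lesion_id = 2, adc_ratio_tumor = 0.8)
  ), provenance = "test")
}

# Independent brute-force Youden search: every candidate cut (midpoints and
# sentinels), both one direction, exhaustive maximum of J.
brute_force_youden <- function(scores, labels, direction) {
  s <- sort(unique(scores))
  cuts <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  best <- NULL
  for (t in cuts) {
    pred <- if (direction == "positive_class_low") scores < t else scores > t
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12) {
      best <- list(J = J, sens = sens, spec = spec)
    }
  }
  best
}

# Independent two-sided Fisher oracle: enumerate the hypergeometric
# distribution of the top-left cell given fixed margins and sum the
# probabilities of tables no more probable than the observed one.
enumerate_fisher_p <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  lo <- max(0, k - n2)
  hi <- min(k, n1)
  probs <- stats::dhyper(lo:hi, n1, n2, k)
  obs <- stats::dhyper(k1, n1, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
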