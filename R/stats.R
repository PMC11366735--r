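# Ratio features and the statistical battery used to compare the two
# entities: two-sided t-tests, an exact two-proportion test, Tukey HSD
# across subgroups, and the Bonferroni family-level correction.

#' Contralateral-normalized signal ratio
#'
#' ADC and FLAIR intensities are normalized by dividing the lesion (or
#' perilesional) measurement by the contralateral normal-appearing white
#' matter value, which removes scanner and field-strength effects.
#'
#' @param lesion_value Signal intensity measured in the lesion or
#'   perilesional tissue.
#' @param reference_value Contralateral white-matter intensity; must be
#'   positive.
#' @return `lesion_value / reference_value`.
#' @export
ratio <- function(lesion_value, reference_value) {
  if (any(!is.finite(reference_value) | reference_value <= 0)) {
    abort("reference_value must be positive", class = "lesiondx_domain_error")
  }
  lesion_value / reference_value
}

#' Perilesional gradient profile
#'
#' Normalized ratios at 5, 10 and 20 mm from the enhancing lesion margin.
#' The 10 and 20 mm measurements exist only when lesion size and edema
#' extent permit; absent inputs yield absent ratios.
#'
#' @param value_5mm,value_10mm,value_20mm Signal intensities at the three
#'   distances; `value_10mm`/`value_20mm` may be `NA`.
#' @param reference Contralateral white-matter intensity; positive.
#' @return A tibble with `distance_mm` (5, 10, 20) and `ratio` (`NA` where
#'   the measurement was not feasible).
#' @export
gradient_profile <- function(value_5mm, value_10mm = NA_real_,
                             value_20mm = NA_real_, reference) {
  if (is.na(value_5mm)) {
    abort("the 5 mm measurement is mandatory", class = "lesiondx_domain_error")
  }
  vals <- c(value_5mm, value_10mm, value_20mm)
  tibble(
    distance_mm = c(5, 10, 20),
    ratio = ifelse(is.na(vals), NA_real_, vals / ratio_check_ref(reference))
  )
}

ratio_check_ref <- function(reference) {
  if (!is.finite(reference) || reference <= 0) {
    abort("reference must be positive", class = "lesiondx_domain_error")
  }
  reference
}

test_result <- function(test_name, statistic, p_value, n1, n2) {
  tibble(test_name = test_name, statistic = statistic, p_value = p_value,
         n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Two-sided two-sample t-test
#'
#' Welch by default (equal variances not assumed); Student's pooled-variance
#' variant available. The statistic carries the sign of
#' `mean(group_a) - mean(group_b)`.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values
#'   and positive variance.
#' @param variant `"welch"` or `"student"`.
#' @return A one-row tibble: `test_name`, `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @export
two_sided_t_test <- function(group_a, group_b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least two observations",
          class = "lesiondx_domain_error")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      # identical constant groups: no evidence of a difference
      return(test_result(paste0(variant, "_t"), 0, 1,
                         length(group_a), length(group_b)))
    }
    abort("degenerate groups: zero variance in both groups",
          class = "lesiondx_domain_error")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = variant == "student",
                      alternative = "two.sided")
  test_result(paste0(variant, "_t"), unname(ht$statistic), ht$p.value,
              length(group_a), length(group_b))
}

#' Exact two-sided test for two proportions
#'
#' The published tables test category frequencies between the entities; the
#' exact conditional (Fisher) test is used here, which matches the very
#' small p-values reported on small denominators.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A one-row tibble; `statistic` is the difference in proportions
#'   `k1/n1 - k2/n2`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  counts <- c(k1, n1, k2, n2)
  if (any(counts < 0) || n1 == 0 || n2 == 0 || k1 > n1 || k2 > n2 ||
        any(counts != round(counts))) {
    abort("counts must satisfy 0 <= k_i <= n_i with n_i > 0",
          class = "lesiondx_domain_error")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  test_result("fisher_exact", k1 / n1 - k2 / n2, min(p, 1), n1, n2)
}

#' Tukey HSD pairwise comparisons
#'
#' Adjusted p-values for all unordered pairs of three or more groups via
#' the studentized-range distribution, with Tukey-Kramer standard errors
#' for unequal group sizes (as implemented by [stats::TukeyHSD()] on a
#' one-way fit).
#'
#' @param groups A named list of numeric vectors (>= 3 groups, each with
#'   >= 2 values).
#' @return A tibble with `group1`, `group2`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    abort("Tukey HSD needs at least three groups",
          class = "lesiondx_domain_error")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, function(g) sum(!is.na(g)), integer(1)) < 2)) {
    abort("each group needs at least two observations",
          class = "lesiondx_domain_error")
  }
  df <- dplyr::bind_rows(lapply(names(groups), function(nm) {
    tibble(group = nm, value = groups[[nm]])
  }))
  df$group <- factor(df$group, levels = names(groups))
  fit <- stats::aov(value ~ group, data = df)
  hsd <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble(
    group1 = vapply(pairs, `[`, character(1), 1),
    group2 = vapply(pairs, `[`, character(1), 2),
    diff = hsd[, "diff"], lwr = hsd[, "lwr"], upr = hsd[, "upr"],
    p_adj = hsd[, "p adj"]
  )
}

#' Bonferroni per-test significance level
#'
#' @param family_alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons in the family (>= 1).
#' @return `family_alpha / m`, e.g. 0.05 / 20 = 0.0025.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  if (!(family_alpha > 0 && family_alpha < 1)) {
    abort("family_alpha must lie in (0, 1)", class = "lesiondx_domain_error")
  }
  if (m < 1 || m != round(m)) {
    abort("m must be a positive integer count", class = "lesiondx_domain_error")
  }
  family_alpha / m
}

summary_continuous_features <- function() {
  c("diameter_mm", "edema_mm", "nearest_lesion_distance_mm",
    "adc_ratio_tumor", "adc_ratio_edema_5mm", "adc_ratio_edema_10mm",
    "adc_ratio_edema_20mm", "flair_ratio_tumor", "flair_ratio_edema_5mm",
    "flair_ratio_edema_10mm", "flair_ratio_edema_20mm")
}

#' Per-stratum cohort summary
#'
#' Reproduces the layout of the published cohort tables: per-feature mean,
#' SD, range, median and n for continuous lesion-level features, and
#' count/proportion/denominator for categorical and boolean features.
#' Denominators follow the published conventions: lesion counts for
#' lesion-level fields, patient counts for patient-level fields, and
#' modality-restricted lesion counts for perfusion/SWI flags. The SD of a
#' single observation is reported absent, not zero.
#'
#' @param cohort A cohort table.
#' @param stratify_by `"entity"` or `"subtype"`.
#' @return A list of class `"group_summary"` with tibbles `continuous` and
#'   `categorical`.
#' @export
group_summary <- function(cohort, stratify_by = c("entity", "subtype")) {
  stratify_by <- match.arg(stratify_by)
  strata <- unique(cohort[[stratify_by]])
  if (length(strata) == 0 || anyNA(strata)) {
    abort("stratification variable contains empty or missing strata",
          class = "lesiondx_domain_error")
  }

  cont <- purrr::map_dfr(strata, function(s) {
    rows <- cohort[cohort[[stratify_by]] == s, ]
    purrr::map_dfr(summary_continuous_features(), function(f) {
      x <- rows[[f]][!is.na(rows[[f]])]
      tibble(
        stratum = s, feature = f, n = length(x),
        mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        min = min(x), max = max(x), median = stats::median(x)
      )
    })
  })

  cat_specs <- list(
    list(feature = "morphology", type = "category"),
    list(feature = "location", type = "category"),
    list(feature = "contrast_enhancing", type = "lesion_flag"),
    list(feature = "flair_connected", type = "lesion_flag"),
    list(feature = "rcbv_increased", type = "modality_flag"),
    list(feature = "typical_curve", type = "modality_flag"),
    list(feature = "swi_hemorrhage", type = "modality_flag"),
    list(feature = "swi_vascularization", type = "modality_flag"),
    list(feature = "perfusion_available", type = "patient_flag"),
    list(feature = "swi_available", type = "patient_flag")
  )
  cat <- purrr::map_dfr(strata, function(s) {
    rows <- cohort[cohort[[stratify_by]] == s, ]
    pats <- patient_table(rows)
    purrr::map_dfr(cat_specs, function(spec) {
      f <- spec$feature
      if (spec$type == "category") {
        levels <- if (f == "morphology") MORPHOLOGY_LEVELS else LOCATION_LEVELS
        denom <- nrow(rows)
        purrr::map_dfr(levels, function(lv) {
          tibble(stratum = s, feature = f, category = lv,
                 count = sum(rows[[f]] == lv), denominator = denom,
                 proportion = sum(rows[[f]] == lv) / denom)
        })
      } else if (spec$type == "patient_flag") {
        denom <- nrow(pats)
        cnt <- sum(pats[[f]], na.rm = TRUE)
        tibble(stratum = s, feature = f, category = "TRUE", count = cnt,
               denominator = denom, proportion = cnt / denom)
      } else {
        x <- rows[[f]]
        denom <- sum(!is.na(x))
        cnt <- sum(x, na.rm = TRUE)
        tibble(stratum = s, feature = f, category = "TRUE", count = cnt,
               denominator = denom,
               proportion = if (denom > 0) cnt / denom else NA_real_)
      }
    })
  })

  structure(list(continuous = cont, categorical = cat,
                 stratify_by = stratify_by),
            class = "group_summary")
}

#' Entity-wise comparison table
#'
#' Runs the published battery on a labeled cohort: a two-sided Welch t-test
#' per continuous feature and an exact two-proportion test per categorical
#' level, mGB versus mCNSL.
#'
#' @param cohort A cohort containing both entities.
#' @param variant t-test variant, `"welch"` or `"student"`.
#' @return A tibble with `feature`, `category` (NA for continuous),
#'   `statistic`, `p_value`, `n1` (mGB), `n2` (mCNSL).
#' @export
compare_entities <- function(cohort, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(unique(cohort$entity)) < 2) {
    abort("cohort must contain both entities", class = "lesiondx_domain_error")
  }
  gb <- cohort[cohort$entity == "mGB", ]
  ly <- cohort[cohort$entity == "mCNSL", ]

  cont <- purrr::map_dfr(summary_continuous_features(), function(f) {
    res <- two_sided_t_test(gb[[f]], ly[[f]], variant = variant)
    tibble(feature = f, category = NA_character_,
           statistic = res$statistic, p_value = res$p_value,
           n1 = res$n1, n2 = res$n2)
  })
  cats <- purrr::map_dfr(MORPHOLOGY_LEVELS, function(lv) {
    res <- two_proportion_test(sum(gb$morphology == lv), nrow(gb),
                               sum(ly$morphology == lv), nrow(ly))
    tibble(feature = "morphology", category = lv,
           statistic = res$statistic, p_value = res$p_value,
           n1 = res$n1, n2 = res$n2)
  })
  flags <- purrr::map_dfr(
    c("contrast_enhancing", "flair_connected", "rcbv_increased",
      "typical_curve", "swi_hemorrhage", "swi_vascularization"),
    function(f) {
      x1 <- gb[[f]][!is.na(gb[[f]])]
      x2 <- ly[[f]][!is.na(ly[[f]])]
      if (length(x1) == 0 || length(x2) == 0) {
        return(tibble(feature = f, category = "TRUE",
                      statistic = NA_real_, p_value = NA_real_,
                      n1 = length(x1), n2 = length(x2)))
      }
      res <- two_proportion_test(sum(x1), length(x1), sum(x2), length(x2))
      tibble(feature = f, category = "TRUE", statistic = res$statistic,
             p_value = res$p_value, n1 = res$n1, n2 = res$n2)
    }
  )
  dplyr::bind_rows(cont, cats, flags)
}
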