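# The ordered rule-list diagnostic classifier: MR perfusion first, then
# perfect-specificity rules, then the remaining significant rules in
# descending order of Youden's J.

#' Confusion-matrix metrics
#'
#' @param tp,fp,tn,fn Non-negative counts; the four cannot all be zero.
#' @return A one-row tibble: counts plus accuracy, sensitivity,
#'   specificity, PPV and NPV. Ratios with a zero denominator are reported
#'   absent (`NA`), not zero.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "lesiondx_domain_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort("all-zero confusion table", class = "lesiondx_domain_error")
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / total,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn)
  )
}

# Candidate feature definitions. "kind" follows the rule taxonomy:
# boolean_flag (modality-gated lesion flag), category_membership
# (morphology-derived), threshold (continuous, cut by Youden's J).
candidate_catalog <- function() {
  tibble(
    feature = c("typical_curve", "stripe_or_tree", "cystic_morphology",
                "swi_hemorrhage", "swi_vascularization",
                "adc_ratio_edema_5mm", "flair_ratio_edema_5mm",
                "adc_ratio_tumor", "flair_ratio_tumor", "diameter_mm",
                "edema_mm", "nearest_lesion_distance_mm"),
    kind = c("boolean_flag", "category_membership", "category_membership",
             "boolean_flag", "boolean_flag",
             rep("threshold", 7)),
    requires_modality = c("perfusion", "none", "none", "swi", "swi",
                          rep("none", 7))
  )
}

#' Default candidate features of the diagnostic algorithm
#'
#' The seven features evaluated in the published decision tree: the
#' typical perfusion time-signal intensity curve, stripe-/tree-shaped
#' enhancement, cystic or cystic-solid morphology, mean perilesional ADC
#' ratio at 5 mm, mean perilesional FLAIR ratio at 5 mm, mean tumor ADC
#' ratio, and mean lesion diameter.
#'
#' @return A character vector of feature names.
#' @export
default_candidates <- function() {
  c("typical_curve", "stripe_or_tree", "cystic_morphology",
    "adc_ratio_edema_5mm", "flair_ratio_edema_5mm", "adc_ratio_tumor",
    "diameter_mm")
}

#' Candidate feature values at patient or lesion level
#'
#' Patient-level reduction follows the published convention: continuous
#' lesion features are averaged per patient ("mean ratio" rows), boolean
#' and morphology features use any-lesion semantics (e.g. a patient is
#' typical-curve positive when at least one lesion shows the curve).
#' Modality-gated features are `NA` when the modality is unavailable.
#'
#' @param cohort A cohort table.
#' @param unit `"patient"` or `"lesion"`.
#' @return A tibble with `id`, `entity`, and one column per catalog
#'   feature.
#' @export
feature_values <- function(cohort, unit = c("patient", "lesion")) {
  unit <- match.arg(unit)
  any_or_na <- function(x) {
    if (all(is.na(x))) NA else any(x, na.rm = TRUE)
  }
  mean_or_na <- function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  cont <- c("adc_ratio_edema_5mm", "flair_ratio_edema_5mm",
            "adc_ratio_tumor", "flair_ratio_tumor", "diameter_mm",
            "edema_mm", "nearest_lesion_distance_mm")
  if (unit == "patient") {
    cohort |>
      dplyr::group_by(id = .data$patient_id) |>
      dplyr::summarise(
        entity = dplyr::first(.data$entity),
        typical_curve = any_or_na(.data$typical_curve),
        stripe_or_tree = any(.data$morphology == "stripe_or_tree"),
        cystic_morphology = any(.data$morphology %in%
                                  c("cystic", "cystic_solid")),
        swi_hemorrhage = any_or_na(.data$swi_hemorrhage),
        swi_vascularization = any_or_na(.data$swi_vascularization),
        dplyr::across(dplyr::all_of(cont), mean_or_na),
        .groups = "drop"
      )
  } else {
    tibble(
      id = paste0(cohort$patient_id, "/", cohort$lesion_id),
      entity = cohort$entity,
      typical_curve = cohort$typical_curve,
      stripe_or_tree = cohort$morphology == "stripe_or_tree",
      cystic_morphology = cohort$morphology %in% c("cystic", "cystic_solid"),
      swi_hemorrhage = cohort$swi_hemorrhage,
      swi_vascularization = cohort$swi_vascularization
    ) |>
      dplyr::bind_cols(cohort[, cont])
  }
}

#' Order diagnostic rules per the published construction
#'
#' Perfusion-requiring rules come first, then rules with specificity 1.0,
#' then the remaining rules in descending order of Youden's J (ties by
#' higher specificity, then feature name).
#'
#' @param rules A rule tibble (columns `feature`, `requires_modality`,
#'   `specificity`, `J`, ...).
#' @return The reordered rule tibble.
#' @export
order_rules <- function(rules) {
  tier <- ifelse(rules$requires_modality == "perfusion", 0L,
                 ifelse(rules$specificity >= 1 - 1e-12, 1L, 2L))
  rules[order(tier, -rules$J, -rules$specificity, rules$feature), ]
}

rule_predicts_positive <- function(rule, value) {
  # two-sided reading: TRUE -> votes_for side, FALSE -> other side, NA ->
  # not evaluable
  switch(rule$direction,
    less_than = value < rule$threshold,
    greater_than = value > rule$threshold,
    present = value,
    absent = !value
  )
}

binary_rule_metrics <- function(pred_pos, is_pos) {
  keep <- !is.na(pred_pos)
  pred_pos <- pred_pos[keep]
  is_pos <- is_pos[keep]
  confusion_metrics(
    tp = sum(pred_pos & is_pos), fp = sum(pred_pos & !is_pos),
    tn = sum(!pred_pos & !is_pos), fn = sum(!pred_pos & is_pos)
  )
}

#' Fit the ordered rule-list diagnostic classifier
#'
#' For each candidate feature a directed rule voting for
#' `positive_entity` is derived: boolean/morphology features take the
#' direction (`present`/`absent`) in which the feature is more frequent in
#' the positive class; continuous features get a Youden's-J-optimal
#' threshold from [roc_curve()] with automatic orientation. Rules are
#' retained when the group difference is significant (Welch t-test for
#' continuous features, exact two-proportion test otherwise) at `alpha`
#' (default the Bonferroni level 0.05/20 = 0.0025), then ordered by
#' [order_rules()]. Pre-registered thresholds can be injected to bypass
#' fitting for reproduction runs; injected rules are always retained.
#'
#' @param cohort A labeled cohort containing both entities.
#' @param candidate_features Character vector of catalog features; default
#'   [default_candidates()].
#' @param positive_entity Entity the rules vote for (default `"mCNSL"`).
#' @param alpha Per-test significance level for rule retention.
#' @param unit Evaluation unit for fitting (default `"patient"`).
#' @param injected_thresholds Optional named list
#'   `feature = list(direction =, threshold =)` with direction
#'   `"less_than"` or `"greater_than"`.
#' @param aggregation `"first_hit"` or `"weighted_vote"`.
#' @param default_class_policy `"abstain"` or `"majority"`.
#' @return A `dx_tree` object (ordered `rules` tibble plus fitting
#'   metadata).
#' @export
fit_tree <- function(cohort,
                     candidate_features = default_candidates(),
                     positive_entity = "mCNSL",
                     alpha = bonferroni_alpha(0.05, 20),
                     unit = c("patient", "lesion"),
                     injected_thresholds = NULL,
                     aggregation = c("first_hit", "weighted_vote"),
                     default_class_policy = c("abstain", "majority")) {
  unit <- match.arg(unit)
  aggregation <- match.arg(aggregation)
  default_class_policy <- match.arg(default_class_policy)
  entities <- unique(cohort$entity)
  if (length(entities) < 2) {
    abort("cohort must contain both entities", class = "lesiondx_domain_error")
  }
  negative_entity <- setdiff(ENTITY_LEVELS, positive_entity)
  catalog <- candidate_catalog()
  unknown <- setdiff(candidate_features, catalog$feature)
  if (length(unknown) > 0) {
    abort(paste0("unknown candidate feature(s): ",
                 paste(unknown, collapse = ", ")),
          class = "lesiondx_domain_error")
  }

  feats <- feature_values(cohort, unit)
  is_pos <- feats$entity == positive_entity

  rules <- purrr::map_dfr(candidate_features, function(f) {
    meta <- catalog[catalog$feature == f, ]
    v <- feats[[f]]
    injected <- !is.null(injected_thresholds[[f]])
    if (meta$kind == "threshold") {
      if (injected) {
        direction <- match.arg(injected_thresholds[[f]]$direction,
                               c("less_than", "greater_than"))
        threshold <- injected_thresholds[[f]]$threshold
        p <- NA_real_
      } else {
        tt <- two_sided_t_test(v[is_pos], v[!is_pos])
        p <- tt$p_value
        rc <- roc_curve(v, is_pos)
        ch <- youden_optimal_threshold(rc)
        direction <- if (rc$direction == "positive_class_low")
          "less_than" else "greater_than"
        threshold <- ch$threshold
      }
      pred <- switch(direction, less_than = v < threshold,
                     greater_than = v > threshold)
      m <- binary_rule_metrics(pred, is_pos)
      tibble(
        feature = f, kind = meta$kind, direction = direction,
        threshold = threshold, votes_for = positive_entity,
        J = m$sensitivity + m$specificity - 1,
        sensitivity = m$sensitivity, specificity = m$specificity,
        p_value = p, requires_modality = meta$requires_modality,
        injected = injected
      )
    } else {
      ok <- !is.na(v)
      k1 <- sum(v[ok & is_pos])
      m1 <- sum(ok & is_pos)
      k2 <- sum(v[ok & !is_pos])
      m2 <- sum(ok & !is_pos)
      p <- two_proportion_test(k1, m1, k2, m2)$p_value
      direction <- if (k1 / m1 >= k2 / m2) "present" else "absent"
      pred <- if (direction == "present") v else !v
      m <- binary_rule_metrics(pred, is_pos)
      tibble(
        feature = f, kind = meta$kind, direction = direction,
        threshold = NA_real_, votes_for = positive_entity,
        J = m$sensitivity + m$specificity - 1,
        sensitivity = m$sensitivity, specificity = m$specificity,
        p_value = p, requires_modality = meta$requires_modality,
        injected = injected
      )
    }
  })

  keep <- rules$injected | (!is.na(rules$p_value) & rules$p_value < alpha)
  if (!any(keep)) {
    warn("no candidate feature is significant at the configured alpha; the tree is empty")
  }
  rules <- order_rules(rules[keep, ])

  structure(
    list(
      rules = rules, positive_entity = positive_entity,
      negative_entity = negative_entity, aggregation = aggregation,
      default_class_policy = default_class_policy, alpha = alpha,
      unit = unit,
      majority_class = names(which.max(table(feats$entity)))
    ),
    class = "dx_tree"
  )
}

traverse_rules <- function(tree, feat_row) {
  rules <- tree$rules
  n <- nrow(rules)
  trace <- vector("list", n)
  prediction <- NA_character_
  votes <- 0
  for (i in seq_len(n)) {
    rule <- rules[i, ]
    v <- feat_row[[rule$feature]]
    if (is.na(v)) {
      outcome <- if (rule$requires_modality != "none")
        "skipped: modality unavailable" else "skipped: feature missing"
      trace[[i]] <- tibble(feature = rule$feature, outcome = outcome,
                           vote = NA_character_)
      next
    }
    pred_pos <- rule_predicts_positive(rule, v)
    if (tree$aggregation == "weighted_vote") {
      vote <- if (pred_pos) tree$positive_entity else tree$negative_entity
      votes <- votes + rule$J * (if (pred_pos) 1 else -1)
      trace[[i]] <- tibble(feature = rule$feature, outcome = "voted",
                           vote = vote)
      next
    }
    # first_hit traversal: one-sided rules fall through when the marker is
    # on the non-voting side; "absent"-direction rules are two-sided splits
    if (pred_pos) {
      prediction <- rule$votes_for
      trace[[i]] <- tibble(feature = rule$feature, outcome = "fired",
                           vote = prediction)
      trace <- trace[seq_len(i)]
      break
    }
    if (rule$direction == "absent") {
      prediction <- tree$negative_entity
      trace[[i]] <- tibble(feature = rule$feature, outcome = "fired",
                           vote = prediction)
      trace <- trace[seq_len(i)]
      break
    }
    trace[[i]] <- tibble(feature = rule$feature, outcome = "not fired",
                         vote = NA_character_)
  }
  if (tree$aggregation == "weighted_vote" && n > 0) {
    prediction <- if (votes > 0) tree$positive_entity else
      if (votes < 0) tree$negative_entity else NA_character_
  }
  if (is.na(prediction) && tree$default_class_policy == "majority") {
    prediction <- tree$majority_class
  }
  list(prediction = prediction,
       trace = dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))]))
}

#' Classify one patient with a fitted tree
#'
#' Rules whose modality is unavailable (or whose feature is missing) are
#' skipped and logged in the trace. Under `first_hit` the first firing
#' rule's vote is returned; under `weighted_vote` every evaluable rule
#' votes with weight J and the sign of the sum decides. A patient with no
#' applicable rule yields an abstention (not an error) under the
#' `abstain` policy.
#'
#' @param patient The cohort rows of one patient (or a one-row
#'   [feature_values()] table).
#' @param tree A `dx_tree`.
#' @return A list with `prediction` (entity label or `NA` for abstention)
#'   and `trace` (tibble of `feature`, `outcome`, `vote`).
#' @export
classify_patient <- function(patient, tree) {
  stopifnot(inherits(tree, "dx_tree"))
  if (nrow(tree$rules) == 0) {
    prediction <- if (tree$default_class_policy == "majority")
      tree$majority_class else NA_character_
    return(list(prediction = prediction,
                trace = tibble(feature = character(), outcome = character(),
                               vote = character())))
  }
  feat_row <- if ("patient_id" %in% names(patient)) {
    feature_values(patient, unit = "patient")
  } else {
    patient
  }
  traverse_rules(tree, feat_row)
}

#' Classify every record of a cohort
#'
#' @param cohort A cohort table.
#' @param tree A `dx_tree`.
#' @param unit `"patient"` (default) or `"lesion"`.
#' @return A tibble with `id`, `entity`, `prediction` (`NA` = abstained).
#' @export
classify_cohort <- function(cohort, tree, unit = tree$unit) {
  feats <- feature_values(cohort, unit)
  preds <- vapply(seq_len(nrow(feats)), function(i) {
    if (nrow(tree$rules) == 0) {
      if (tree$default_class_policy == "majority") tree$majority_class
      else NA_character_
    } else {
      traverse_rules(tree, feats[i, ])$prediction
    }
  }, character(1))
  tibble(id = feats$id, entity = feats$entity, prediction = preds)
}

#' Evaluate a fitted tree on a labeled cohort
#'
#' Per-rule metrics treat each rule as a standalone binary classifier over
#' the records where its feature is measurable (denominators therefore
#' follow the per-modality record counts); the overall row scores the full
#' traversal over non-abstaining records.
#'
#' @param tree A `dx_tree`.
#' @param cohort A labeled cohort.
#' @param unit `"patient"` or `"lesion"`.
#' @return A `tree_evaluation` list: `per_rule` (rule columns plus
#'   confusion metrics and `n_evaluated`), `overall` (confusion metrics or
#'   `NULL` when everything abstained), `n_abstained`, `unit`.
#' @export
evaluate_tree <- function(tree, cohort, unit = tree$unit) {
  stopifnot(inherits(tree, "dx_tree"))
  feats <- feature_values(cohort, unit)
  is_pos <- feats$entity == tree$positive_entity

  per_rule <- purrr::map_dfr(seq_len(nrow(tree$rules)), function(i) {
    rule <- tree$rules[i, ]
    v <- feats[[rule$feature]]
    pred <- rule_predicts_positive(rule, v)
    m <- binary_rule_metrics(pred, is_pos)
    dplyr::bind_cols(
      rule[, c("feature", "kind", "direction", "threshold", "votes_for",
               "requires_modality")],
      m,
      tibble(n_evaluated = sum(!is.na(pred)))
    )
  })

  preds <- classify_cohort(cohort, tree, unit)
  classified <- preds[!is.na(preds$prediction), ]
  overall <- if (nrow(classified) > 0) {
    cp <- classified$prediction == tree$positive_entity
    ct <- classified$entity == tree$positive_entity
    confusion_metrics(
      tp = sum(cp & ct), fp = sum(cp & !ct),
      tn = sum(!cp & !ct), fn = sum(!cp & ct)
    )
  } else {
    NULL
  }

  structure(
    list(per_rule = per_rule, overall = overall,
         n_abstained = sum(is.na(preds$prediction)), unit = unit),
    class = "tree_evaluation"
  )
}

#' Serialize a fitted tree to JSON
#'
#' @param tree A `dx_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  doc <- list(
    positive_entity = tree$positive_entity,
    negative_entity = tree$negative_entity,
    aggregation = tree$aggregation,
    default_class_policy = tree$default_class_policy,
    alpha = tree$alpha,
    unit = tree$unit,
    majority_class = tree$majority_class,
    rules = tree$rules
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Deserialize a tree written by [write_tree_json()]
#'
#' @param path JSON path.
#' @return A `dx_tree`.
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- as_tibble(doc$rules)
  rules$threshold <- as.numeric(rules$threshold)
  structure(
    list(rules = rules, positive_entity = doc$positive_entity,
         negative_entity = doc$negative_entity,
         aggregation = doc$aggregation,
         default_class_policy = doc$default_class_policy,
         alpha = doc$alpha, unit = doc$unit,
         majority_class = doc$majority_class),
    class = "dx_tree"
  )
}
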