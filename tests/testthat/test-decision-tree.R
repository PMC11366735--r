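test_that("confusion metrics reproduce the perfusion-rule worked example", {
  # 9/17 mCNSL perfusion patients with the typical curve, 0/37 mGB
  m <- confusion_metrics(tp = 9, fp = 0, tn = 37, fn = 8)
  expect_equal(m$accuracy, 46 / 54)
  expect_equal(m$accuracy, 0.85, tolerance = 0.005 / 0.85)
  expect_equal(m$sensitivity, 9 / 17)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 37 / 45)
  expect_equal(m$npv, 0.82, tolerance = 0.005 / 0.82)

  perfect <- confusion_metrics(1, 0, 1, 0)
  expect_true(all(unlist(perfect[, c("accuracy", "sensitivity",
                                     "specificity", "ppv", "npv")]) == 1))

  none_pred_pos <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(none_pred_pos$ppv))
  expect_equal(none_pred_pos$npv, 0.5)

  expect_error(confusion_metrics(0, 0, 0, 0), class = "lesiondx_domain_error")
  expect_error(confusion_metrics(-1, 0, 1, 0), class = "lesiondx_domain_error")
})

test_that("rule ordering reproduces the published row order from printed metrics", {
  # printed sensitivity/specificity pairs of the seven evaluated rules,
  # deliberately shuffled
  printed <- tibble::tibble(
    feature = c("diameter_mm", "adc_ratio_tumor", "cystic_morphology",
                "typical_curve", "flair_ratio_edema_5mm", "stripe_or_tree",
                "adc_ratio_edema_5mm"),
    sensitivity = c(0.64, 0.59, 0.86, 0.53, 0.57, 0.16, 0.62),
    specificity = c(0.56, 0.64, 0.80, 1.00, 0.69, 1.00, 0.76),
    requires_modality = c("none", "none", "none", "perfusion", "none",
                          "none", "none")
  )
  printed$J <- printed$sensitivity + printed$specificity - 1
  ordered <- order_rules(printed)
  expect_identical(
    ordered$feature,
    c("typical_curve", "stripe_or_tree", "cystic_morphology",
      "adc_ratio_edema_5mm", "flair_ratio_edema_5mm", "adc_ratio_tumor",
      "diameter_mm")
  )
})

test_that("fitted trees satisfy the ordering invariant structurally", {
  co <- sample_study_cohort(150, 150, seed = 51)
  tree <- fit_tree(co)
  rules <- tree$rules
  expect_gt(nrow(rules), 2)
  tier <- ifelse(rules$requires_modality == "perfusion", 0,
                 ifelse(rules$specificity >= 1 - 1e-12, 1, 2))
  expect_true(all(diff(tier) >= 0))
  imperfect <- rules$J[tier == 2]
  expect_true(all(diff(imperfect) <= 1e-12))
  # every retained non-injected rule passed the significance gate
  expect_true(all(rules$p_value[!rules$injected] < tree$alpha))
  # stored metrics are internally consistent
  expect_equal(rules$J, rules$sensitivity + rules$specificity - 1)
})

test_that("fit_tree rejects degenerate inputs and injects thresholds", {
  co <- sample_study_cohort(60, 60, seed = 52)
  expect_error(fit_tree(co[co$entity == "mGB", ]),
               class = "lesiondx_domain_error")
  expect_error(fit_tree(co, candidate_features = "not_a_feature"),
               class = "lesiondx_domain_error")

  inj <- list(
    adc_ratio_tumor = list(direction = "less_than", threshold = 0.87),
    adc_ratio_edema_5mm = list(direction = "greater_than", threshold = 1.88),
    diameter_mm = list(direction = "less_than", threshold = 20)
  )
  tree <- fit_tree(co, injected_thresholds = inj)
  r <- tree$rules
  expect_equal(r$threshold[r$feature == "adc_ratio_tumor"], 0.87)
  expect_equal(r$threshold[r$feature == "adc_ratio_edema_5mm"], 1.88)
  expect_equal(r$threshold[r$feature == "diameter_mm"], 20)
  expect_identical(r$direction[r$feature == "adc_ratio_tumor"], "less_than")
})

test_that("classification follows the flowchart semantics", {
  fx <- build_fixture_cohort()
  tree <- fit_tree(fx, candidate_features = c("typical_curve",
                                              "stripe_or_tree",
                                              "cystic_morphology"))

  # typical-curve patient: classified mCNSL by the first rule alone
  typ_pat <- fx[fx$patient_id == "mCNSL_01", ]
  res <- classify_patient(typ_pat, tree)
  expect_identical(res$prediction, "mCNSL")
  expect_identical(nrow(res$trace), 1L)
  expect_identical(res$trace$feature, "typical_curve")

  # cystic lesion, no perfusion, no stripe lesions -> mGB via the
  # two-sided morphology split
  gb_pat <- as_cohort(dplyr::bind_rows(
    lesion_row("g9", "mGB", lesion_id = 1, morphology = "cystic"),
    lesion_row("g9", "mGB", lesion_id = 2, morphology = "solid")
  ), "test")
  res2 <- classify_patient(gb_pat, tree)
  expect_identical(res2$prediction, "mGB")
  expect_identical(res2$trace$outcome[1], "skipped: modality unavailable")

  # no stripe, no cystic lesions, no perfusion -> mCNSL via the same split
  ly_pat <- as_cohort(dplyr::bind_rows(
    lesion_row("l9", "mCNSL", lesion_id = 1),
    lesion_row("l9", "mCNSL", lesion_id = 2)
  ), "test")
  expect_identical(classify_patient(ly_pat, tree)$prediction, "mCNSL")

  # empty tree abstains under the abstain policy
  empty_tree <- tree
  empty_tree$rules <- tree$rules[0, ]
  expect_true(is.na(classify_patient(typ_pat, empty_tree)$prediction))
  ev0 <- evaluate_tree(empty_tree, fx)
  expect_null(ev0$overall)
  expect_identical(ev0$n_abstained, 100L)
})

test_that("first-hit classification ignores rules after the firing rule", {
  co <- sample_study_cohort(80, 80, seed = 53)
  tree <- fit_tree(co)
  stub <- tree
  stub$rules <- tree$rules[1:2, ]
  full_first <- classify_cohort(co, tree)
  # patients decided within the first two rules get the same answer
  two_first <- classify_cohort(co, stub)
  decided <- !is.na(two_first$prediction)
  expect_true(any(decided))
  expect_identical(two_first$prediction[decided],
                   full_first$prediction[decided])
})

test_that("a perfectly separating feature yields accuracy 1 in both modes", {
  rows <- dplyr::bind_rows(lapply(1:10, function(i) {
    ent <- if (i <= 5) "mGB" else "mCNSL"
    dplyr::bind_rows(
      lesion_row(paste0("p", i), ent, lesion_id = 1,
                 perfusion_available = TRUE, rcbv_increased = TRUE,
                 typical_curve = ent == "mCNSL"),
      lesion_row(paste0("p", i), ent, lesion_id = 2,
                 perfusion_available = TRUE, rcbv_increased = FALSE,
                 typical_curve = FALSE)
    )
  }))
  co <- as_cohort(rows, "test")
  for (agg in c("first_hit", "weighted_vote")) {
    tree <- fit_tree(co, candidate_features = "typical_curve",
                     alpha = 0.05, aggregation = agg)
    expect_equal(tree$rules$J[1], 1)
    ev <- evaluate_tree(tree, co)
    expect_equal(ev$overall$accuracy, 1)
  }
})

test_that("per-rule metrics recompute exactly from their 2x2 counts", {
  co <- sample_study_cohort(100, 100, seed = 54)
  tree <- fit_tree(co)
  ev <- evaluate_tree(tree, co)
  for (i in seq_len(nrow(ev$per_rule))) {
    row <- ev$per_rule[i, ]
    again <- confusion_metrics(row$tp, row$fp, row$tn, row$fn)
    expect_equal(row$accuracy, again$accuracy)
    expect_equal(row$sensitivity, again$sensitivity)
    expect_equal(row$specificity, again$specificity)
    expect_identical(row$tp + row$fp + row$tn + row$fn,
                     row$n_evaluated)
  }
  # fitting metrics agree with evaluation on the fitting cohort
  joined <- merge(tree$rules, ev$per_rule, by = "feature")
  expect_equal(joined$sensitivity.x, joined$sensitivity.y)
  expect_equal(joined$specificity.x, joined$specificity.y)
})

test_that("per-rule denominators follow modality availability", {
  fx <- build_fixture_cohort()
  tree <- fit_tree(fx, candidate_features = c("typical_curve",
                                              "stripe_or_tree",
                                              "cystic_morphology"))
  ev <- evaluate_tree(tree, fx)
  perf_row <- ev$per_rule[ev$per_rule$feature == "typical_curve", ]
  # only the 37 + 17 perfusion-available patients are evaluable
  expect_identical(perf_row$n_evaluated, 54L)
  expect_equal(perf_row$accuracy, 46 / 54)
  expect_equal(perf_row$sensitivity, 9 / 17)
  expect_equal(perf_row$specificity, 1)
  expect_equal(perf_row$npv, 37 / 45)
  morph_row <- ev$per_rule[ev$per_rule$feature == "cystic_morphology", ]
  expect_identical(morph_row$n_evaluated, 100L)
})

test_that("stripe rule keeps near-perfect specificity on synthetic cohorts", {
  co <- sample_study_cohort(400, 400, seed = 55)
  tree <- fit_tree(co)
  ev <- evaluate_tree(tree, co, unit = "lesion")
  stripe <- ev$per_rule[ev$per_rule$feature == "stripe_or_tree", ]
  expect_gt(stripe$specificity, 0.999)
})

test_that("trees survive a JSON round trip", {
  co <- sample_study_cohort(80, 80, seed = 56)
  tree <- fit_tree(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path)
  expect_equal(back$rules$feature, tree$rules$feature)
  expect_equal(back$rules$threshold, tree$rules$threshold)
  expect_equal(back$rules$J, tree$rules$J)
  expect_identical(back$positive_entity, tree$positive_entity)
  preds_a <- classify_cohort(co, tree)
  preds_b <- classify_cohort(co, back)
  expect_identical(preds_a$prediction, preds_b$prediction)
})
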