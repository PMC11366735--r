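test_that("ratios normalize against the contralateral reference", {
  expect_equal(ratio(890, 1000), 0.89)
  expect_equal(ratio(3.7, 3.7), 1.0)
  expect_error(ratio(1, 0), class = "lesiondx_domain_error")
  expect_error(ratio(1, -5), class = "lesiondx_domain_error")
})

test_that("gradient profiles honor the feasibility rule", {
  gp <- gradient_profile(1.79 * 250, 2.07 * 250, 2.28 * 250, reference = 250)
  expect_equal(gp$ratio, c(1.79, 2.07, 2.28))
  expect_equal(gp$distance_mm, c(5, 10, 20))

  one <- gradient_profile(300, reference = 250)
  expect_equal(one$ratio, c(1.2, NA, NA))
  expect_error(gradient_profile(NA, NA, NA, reference = 250),
               class = "lesiondx_domain_error")
  same <- gradient_profile(5, 5, 5, reference = 5)
  expect_equal(same$ratio, c(1, 1, 1))
})

test_that("two-sided t-test matches closed form and is symmetric", {
  # identical constant groups carry no evidence
  res <- two_sided_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # pooled-variance closed form for {1,2,3} vs {11,12,13}:
  # t = -10 / sqrt(1 * 2/3) = -12.2474, df = 4
  res2 <- two_sided_t_test(c(1, 2, 3), c(11, 12, 13), variant = "student")
  expect_equal(res2$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res2$p_value, 2 * pt(-10 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)
  expect_lt(res2$p_value, 0.01)

  # swapping groups negates the statistic and preserves p
  withr::with_seed(3, {
    a <- rnorm(20, 1, 0.3)
    b <- rnorm(25, 0.8, 0.4)
  })
  r1 <- two_sided_t_test(a, b)
  r2 <- two_sided_t_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_gt(r1$statistic * (mean(a) - mean(b)), 0)

  expect_error(two_sided_t_test(c(1), c(1, 2)),
               class = "lesiondx_domain_error")
})

test_that("synthetic groups at printed sizes separate tumor ADC ratios", {
  withr::with_seed(31, {
    gb <- rnorm(181, 1.05, 0.35)
    ly <- rnorm(187, 0.89, 0.36)
  })
  expect_lt(two_sided_t_test(gb, ly)$p_value, 0.001)
})

test_that("exact two-proportion test matches hypergeometric enumeration", {
  expect_equal(two_proportion_test(10, 100, 10, 100)$p_value, 1)
  expect_equal(two_proportion_test(1, 2, 1, 2)$p_value, 1)
  expect_lt(two_proportion_test(23, 73, 0, 134)$p_value, 1e-8)
  expect_error(two_proportion_test(5, 3, 1, 2),
               class = "lesiondx_domain_error")

  withr::with_seed(17, {
    for (i in 1:200) {
      n1 <- sample(1:30, 1)
      n2 <- sample(1:30, 1)
      k1 <- sample(0:n1, 1)
      k2 <- sample(0:n2, 1)
      expect_equal(
        two_proportion_test(k1, n1, k2, n2)$p_value,
        enumerate_fisher_p(k1, n1, k2, n2),
        tolerance = 1e-9,
        label = sprintf("fisher(%d/%d vs %d/%d)", k1, n1, k2, n2)
      )
    }
  })
})

test_that("Tukey HSD behaves on null and structured subgroup data", {
  withr::with_seed(5, {
    null_groups <- list(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  })
  th <- tukey_hsd(null_groups)
  expect_identical(nrow(th), 3L)
  expect_true(all(th$p_adj > 0.01))

  expect_error(tukey_hsd(list(a = 1:5, b = 1:5)),
               class = "lesiondx_domain_error")

  # four subgroups at the printed sizes/moments of the tumor ADC ratio:
  # the PCNSL vs multifocal-GB contrast carries the largest n at the
  # largest separation, so its adjusted p is the smallest of the six
  withr::with_seed(6, {
    groups <- list(
      multifocal_gb = rnorm(153, 1.05, 0.34),
      multicentric_gb = rnorm(28, 1.06, 0.41),
      pcnsl = rnorm(144, 0.89, 0.29),
      scnsl = rnorm(43, 0.90, 0.56)
    )
  })
  th2 <- tukey_hsd(groups)
  smallest <- th2[which.min(th2$p_adj), ]
  expect_setequal(c(smallest$group1, smallest$group2),
                  c("pcnsl", "multifocal_gb"))

  # adjusted p dominates the unadjusted pairwise p in the vast majority
  # of random small instances
  withr::with_seed(7, {
    dominated <- replicate(40, {
      g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
      th <- tukey_hsd(g)
      raw <- c(
        t.test(g$a, g$b)$p.value,
        t.test(g$a, g$c)$p.value,
        t.test(g$b, g$c)$p.value
      )
      all(th$p_adj >= raw - 0.05)
    })
  })
  expect_gte(mean(dominated), 0.95)
})

test_that("Bonferroni correction reproduces the published family level", {
  expect_identical(bonferroni_alpha(0.05, 20), 0.0025)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.05, 2), 0.025)
  expect_identical(bonferroni_alpha(0.01, 4) * 4, 0.01)
  expect_error(bonferroni_alpha(0.05, 0), class = "lesiondx_domain_error")
  expect_error(bonferroni_alpha(1.2, 5), class = "lesiondx_domain_error")
})

test_that("group summaries reproduce fixture proportions and conventions", {
  fx <- build_fixture_cohort()
  gs <- group_summary(fx, "entity")
  solid <- gs$categorical[gs$categorical$stratum == "mCNSL" &
                            gs$categorical$feature == "morphology" &
                            gs$categorical$category == "solid", ]
  expect_identical(solid$count, 139L)
  expect_identical(solid$denominator, 187L)
  expect_equal(solid$proportion, 139 / 187)

  perf <- gs$categorical[gs$categorical$feature == "perfusion_available" &
                           gs$categorical$stratum == "mGB", ]
  expect_identical(perf$count, 37L)
  expect_identical(perf$denominator, 50L)

  typ <- gs$categorical[gs$categorical$feature == "typical_curve" &
                          gs$categorical$stratum == "mCNSL", ]
  expect_identical(typ$count, 23L)
  expect_identical(typ$denominator, 73L)

  cont <- gs$continuous[gs$continuous$stratum == "mGB" &
                          gs$continuous$feature == "adc_ratio_tumor", ]
  expect_equal(cont$mean, 1.05)
  expect_identical(cont$n, 181L)

  # synthetic moment recovery through the summary path
  co <- sample_cohort(default_config("mGB", n_patients = 1000, seed = 12))
  gs2 <- group_summary(co, "entity")
  row <- gs2$continuous[gs2$continuous$feature == "adc_ratio_tumor", ]
  expect_equal(row$mean, 1.05, tolerance = 0.02 / 1.05)
})

test_that("sd of a single observation is reported absent", {
  co <- dplyr::bind_rows(
    lesion_row("p1", "mGB", lesion_id = 1),
    lesion_row("p1", "mGB", lesion_id = 2),
    lesion_row("q1", "mCNSL", subtype = "SCNSL", lesion_id = 1),
    lesion_row("q1", "mCNSL", subtype = "SCNSL", lesion_id = 2)
  )
  gs <- group_summary(as_cohort(co, "test"), "subtype")
  one <- gs$continuous[gs$continuous$stratum == "SCNSL" &
                         gs$continuous$feature == "diameter_mm", ]
  expect_identical(one$n, 2L)
  # constant pair still has sd 0; a true singleton stratum reports NA
  sub <- as_cohort(co, "test")
  gs1 <- group_summary(sub[c(1, 3), ] |> dplyr::mutate(lesion_id = 1L),
                       "subtype")
  row1 <- gs1$continuous[gs1$continuous$stratum == "SCNSL" &
                           gs1$continuous$feature == "diameter_mm", ]
  expect_true(is.na(row1$sd))
})
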