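test_that("paired test statistics match independent closed-form references", {
  set.seed(71)
  a <- rnorm(20, 26, 2)
  b <- a + rnorm(20, 0.5, 0.8)
  res <- paired_volume_test(a, b)
  # reference: hand-computed paired t statistic and p-value
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * pt(-abs(tstat), df = length(d) - 1)
  expect_equal(res$p_value, p_ref, tolerance = 1e-9)
  expect_equal(res$effect_ml, mean(d), tolerance = 1e-12)
  # signed-rank reference: normal approximation identical to the base test
  res_w <- paired_volume_test(a, b, method = "wilcoxon")
  expect_equal(res_w$p_value,
               wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-12)
})

test_that("degenerate paired data is flagged instead of crashing", {
  x <- c(25, 26, 27, 28)
  res <- paired_volume_test(x, x)
  expect_true(res$degenerate)
  expect_equal(res$effect_ml, 0)
  expect_equal(res$p_value, 1)
  expect_error(paired_volume_test(1:5, 1:4), "length")
  expect_error(paired_volume_test(1:2, 1:2), "3")
})

test_that("the paired t-test holds its nominal level and detects a 2 ml shift", {
  set.seed(72)
  reject_null <- replicate(1000, {
    x <- rnorm(30, 26, 1)
    paired_volume_test(x + rnorm(30, 0, 1), x)$p_value < 0.05
  })
  expect_gt(mean(reject_null), 0.03)
  expect_lt(mean(reject_null), 0.07)
  reject_shift <- replicate(500, {
    x <- rnorm(30, 26, 1)
    paired_volume_test(x + 2 + rnorm(30, 0, 1), x)$p_value < 0.05
  })
  expect_gt(mean(reject_shift), 0.99)
})

test_that("modality agreement reports Bland-Altman limits and null consistency", {
  x <- c(25, 26, 27, 28, 29)
  res0 <- modality_agreement(x, x)
  expect_equal(res0$mean_difference_ml, 0)
  expect_equal(res0$loa_lower_ml, 0)
  expect_equal(res0$loa_upper_ml, 0)
  set.seed(73)
  null_p <- replicate(200, {
    ct <- rnorm(60, 26, 2.7)
    modality_agreement(ct, ct + rnorm(60, 0, 0.3))$p_value
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  bias_p <- replicate(200, {
    ct <- rnorm(60, 26, 2.7)
    modality_agreement(ct, ct + 1.0 + rnorm(60, 0, 0.3))$p_value
  })
  expect_gte(mean(bias_p < 0.05), 0.95)
})

test_that("group summaries reproduce generator parameters within sampling error", {
  rec <- generate_cohort(n = 94, seed = 5)
  gs <- group_summary(rec, "gender", volumes = "unaffected_CT")
  male <- gs[gs$gender == "male", ]
  expect_gt(male$n, 40)
  se <- 2.8 / sqrt(male$n)
  expect_lt(abs(male$mean_ml - 26.6), 3 * se)
  expect_lt(abs(male$sd_ml - 2.8), 1.2)
  # permutation invariance of the summary
  gs2 <- group_summary(rec[rev(seq_len(nrow(rec))), ], "gender",
                       volumes = "unaffected_CT")
  expect_equal(gs2$mean_ml, gs$mean_ml)
  expect_error(group_summary(rec, "age"), "unknown stratifier")
})

test_that("single-record and empty strata are reported, not fatal", {
  rec <- generate_cohort(n = 1, seed = 9)
  expect_s3_class(rec, "cohort_records")
  gs <- group_summary(rec, "gender", volumes = "unaffected_CT")
  filled <- gs[gs$n == 1, ]
  expect_equal(filled$mean_ml, rec$unaffected_CT)
  expect_equal(filled$sd_ml, 0)
  expect_true(filled$sd_flag)
  empty <- gs[gs$n == 0, ]
  expect_true(all(is.na(empty$mean_ml)))
})

test_that("cohort validation enforces the closed vocabularies", {
  rec <- generate_cohort(10, seed = 3)
  bad <- rec
  bad$group[1] <- "robot"
  expect_error(cohort_records(bad), "Navi/conv")
  bad2 <- rec
  bad2$unaffected_CT[2] <- -1
  expect_error(cohort_records(bad2), "positive")
})
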