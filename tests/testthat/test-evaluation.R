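test_that("confusion counts binarize calls direction-matched to the region", {
  gold <- tibble::tibble(
    sample_id = sprintf("S%d", 1:10),
    region = "1p",
    status = c(rep("positive", 6), rep("negative", 4))
  )
  calls <- tibble::tibble(
    sample_id = sprintf("S%d", 1:10), region = "1p", scope = "segmental",
    status = c(rep("loss", 6), rep("normal", 4))
  )
  cc <- confusion_counts(calls, gold, "1p")
  expect_identical(cc[c("tp", "fp", "tn", "fn")],
                   tibble::tibble(tp = 6L, fp = 0L, tn = 4L, fn = 0L))

  # one gold-positive called normal is a false negative
  calls$status[1] <- "normal"
  expect_identical(confusion_counts(calls, gold, "1p")$fn, 1L)

  # a gain call at a loss region is not a positive
  calls$status[1] <- "gain"
  cc2 <- confusion_counts(calls, gold, "1p")
  expect_identical(cc2$fn, 1L)
  expect_identical(cc2$tp, 5L)

  # no_data on either side excludes the pair
  calls$status[1] <- "loss"
  calls$status[10] <- "no_data"
  gold$status[2] <- "no_data"
  cc3 <- confusion_counts(calls, gold, "1p")
  expect_identical(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 8L)
  expect_identical(cc3$n_excluded, 2L)

  expect_error(confusion_counts(calls, gold, "5q"),
               class = "maq_config_error")
})

test_that("metric ratios follow their definitions and zero denominators give NA", {
  m <- performance_metrics(tibble::tibble(tp = 17, fp = 0, tn = 17, fn = 1))
  expect_equal(m$sensitivity, 100 * 17 / 18, tolerance = 1e-12)
  expect_equal(m$specificity, 100, tolerance = 1e-12)
  expect_equal(m$ppv, 100, tolerance = 1e-12)
  expect_equal(m$npv, 100 * 17 / 18, tolerance = 1e-12)
  expect_identical(round(m$sensitivity, 1), 94.4)

  m2 <- performance_metrics(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m2$sensitivity))
  expect_identical(m2$specificity, 100)

  m3 <- performance_metrics(tibble::tibble(tp = 1, fp = 1, tn = 0, fn = 0))
  expect_identical(m3$sensitivity, 100)
  expect_identical(m3$specificity, 0)
})

test_that("the two-point AUC is the mean of sensitivity and specificity", {
  expect_identical(binary_auc(tibble::tibble(tp = 5, fp = 0, tn = 5, fn = 0)), 100)
  expect_identical(binary_auc(tibble::tibble(tp = 5, fp = 5, tn = 0, fn = 0)), 50)
  a <- binary_auc(tibble::tibble(tp = 17, fp = 0, tn = 17, fn = 1))
  expect_equal(a, (100 * 17 / 18 + 100) / 2, tolerance = 1e-12)
  expect_true(is.na(binary_auc(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 0))))
})

test_that("the threshold-swept AUC equals the pairwise-comparison probability", {
  expect_identical(continuous_auc(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                   100)
  expect_identical(continuous_auc(rep(3, 6), rep(c(TRUE, FALSE), 3)), 50)
  withr::with_seed(31, {
    for (k in 1:25) {
      n <- sample(4:20, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      pos <- runif(n) < 0.5
      if (sum(pos) == 0 || sum(!pos) == 0) next
      expect_equal(continuous_auc(scores, pos), oracle_auc(scores, pos),
                   tolerance = 1e-12)
    }
  })
})

test_that("the threshold-swept AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    scores <- c(rnorm(15, 1.3, 0.4), rnorm(12, 1.0, 0.4))
    pos <- rep(c(TRUE, FALSE), c(15, 12))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<"))) * 100
  expect_equal(continuous_auc(scores, pos), ref, tolerance = 1e-9)
})

test_that("macro averaging and pooled error rates reduce as documented", {
  expect_equal(macro_average_auc(c(50)), 50)
  expect_equal(macro_average_auc(c(90, NA, 100)), 95)
  expect_true(is.na(macro_average_auc(numeric())))

  er <- error_rates(tibble::tibble(tp = 89, fp = 1, tn = 106, fn = 1))
  expect_equal(er$fpr, 100 * 1 / 107, tolerance = 1e-12)
  expect_equal(er$fnr, 100 * 1 / 90, tolerance = 1e-12)
  expect_identical(round(er$fpr, 1), 0.9)
  expect_identical(round(er$fnr, 1), 1.1)
  expect_identical(error_rates(tibble::tibble(tp = 5, fp = 0, tn = 9, fn = 0))$fpr, 0)
  expect_true(is.na(error_rates(tibble::tibble(tp = 0, fp = 1, tn = 0, fn = 0))$fnr))
})

test_that("Bland-Altman repeatability components follow the direct formula", {
  same <- c(1, 1.1, 0.9, 1.05)
  ba <- bland_altman_cr(same, same)
  expect_identical(ba$cr, 0)
  expect_identical(ba$loa_halfwidth, 0)

  ba2 <- bland_altman_cr(c(1.1, 0.9), c(1.0, 1.0))
  expect_equal(ba2$bias, 0, tolerance = 1e-12)
  expect_equal(ba2$loa_halfwidth, 1.96 * stats::sd(c(0.1, -0.1)),
               tolerance = 1e-12)

  # pairs with missing values drop out; a single pair is not enough
  ba3 <- bland_altman_cr(c(1, NA, 1.2), c(0.9, 1, NA))
  expect_identical(ba3$n_pairs, 1L)
  expect_true(is.na(ba3$cr))
  expect_error(bland_altman_cr(1:3, 1:2), class = "maq_validation_error")
})

test_that("permuted gold labels pull sensitivity to the calling rate", {
  # with labels permuted, sensitivity estimates the probability of a
  # positive call irrespective of truth
  withr::with_seed(33, {
    n <- 40
    call_status <- ifelse(runif(n) < 0.3, "loss", "normal")
    calls <- tibble::tibble(sample_id = sprintf("S%d", 1:n), region = "1p",
                            scope = "segmental", status = call_status)
    sens <- replicate(300, {
      gold <- tibble::tibble(sample_id = sprintf("S%d", 1:n), region = "1p",
                             status = sample(rep(c("positive", "negative"),
                                                 c(15, 25))))
      performance_metrics(confusion_counts(calls, gold, "1p"))$sensitivity
    })
  })
  expect_equal(mean(sens), 100 * mean(call_status == "loss"), tolerance = 0.05)
})

test_that("the performance object tidies, summarizes and plots", {
  gold <- tibble::tibble(sample_id = rep(sprintf("S%d", 1:8), 2),
                         region = rep(c("1p", "17q"), each = 8),
                         status = rep(c("positive", "negative"), 8))
  calls <- dplyr::mutate(gold,
                         scope = "segmental",
                         status = ifelse(status == "positive",
                                         ifelse(region == "1p", "loss", "gain"),
                                         "normal"))
  perf <- evaluate_performance(calls, gold)
  td <- tidy(perf)
  expect_identical(td$region, c("1p", "17q"))
  expect_true(all(td$auc == 100))
  gl <- glance(perf)
  expect_identical(gl$macro_auc, 100)
  expect_identical(gl$fp, 0L)
  expect_s3_class(autoplot(perf), "ggplot")
  expect_output(print(perf), "macro AUC")
})

test_that("region scores orient deviations toward the expected aberration", {
  dq <- dq_from_values(list(
    `1p` = list(chromosome = "1", arm = "p", dq = c(0.6, 0.8, 1.0)),
    `17q` = list(chromosome = "17", arm = "q", dq = c(1.3, 1.1))
  ))
  expect_equal(region_scores(dq, "1p")$score, 0.4, tolerance = 1e-12)
  expect_equal(region_scores(dq, "17q")$score, 0.3, tolerance = 1e-12)
  expect_equal(region_scores(dq, "1", chromosome = TRUE, direction = "any")$score,
               0.4, tolerance = 1e-12)
})
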