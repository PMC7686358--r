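test_that("AUC is 1 for perfect separation and ~0.5 for random scores", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  withr::with_seed(1, {
    probs <- runif(4000)
    labels <- rbinom(4000, 1, 0.5)
  })
  expect_equal(roc_auc(probs, labels), 0.5, tolerance = 0.05)
})

test_that("AUC equals the pairwise Mann-Whitney count on random inputs", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(6:15, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
      probs <- round(runif(n), 2)  # rounding forces ties
    })
    expect_equal(roc_auc(probs, labels), oracle_auc(probs, labels))
  }
})

test_that("AUC requires both classes", {
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("sensitivity, specificity and accuracy follow their defining ratios", {
  # tp=2 fn=2 tn=9 fp=1 at threshold 0.5
  probs <- c(0.9, 0.8, 0.3, 0.2,           # positives: 2 above, 2 below
             0.6, rep(0.1, 9))             # negatives: 1 above, 9 below
  labels <- c(1, 1, 1, 1, rep(0, 10))
  cm <- confusion_metrics(probs, labels, 0.5)
  expect_equal(cm$tp, 2); expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 9); expect_equal(cm$fp, 1)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$accuracy, 11 / 14)
})

test_that("a score exactly at the threshold classifies positive", {
  cm <- confusion_metrics(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(cm$tp, 1)
  expect_equal(cm$tn, 1)
})

test_that("sensitivity falls and specificity rises with the threshold", {
  withr::with_seed(3, {
    probs <- runif(60)
    labels <- rbinom(60, 1, 0.4)
  })
  th <- seq(0, 1, by = 0.05)
  cms <- lapply(th, function(t) confusion_metrics(probs, labels, t))
  sens <- vapply(cms, `[[`, numeric(1), "sensitivity")
  spec <- vapply(cms, `[[`, numeric(1), "specificity")
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(4, {
    probs <- runif(40)
    labels <- rbinom(40, 1, 0.5)
  })
  labels[1:2] <- c(0, 1)
  a <- roc_auc(probs, labels)
  expect_equal(roc_auc(plogis(5 * probs - 2), labels), a)
  expect_equal(roc_auc(probs^3, labels), a)
})

test_that("Youden threshold on separated data gives perfect operating point", {
  probs <- c(0.9, 0.85, 0.2, 0.1, 0.05)
  labels <- c(1, 1, 0, 0, 0)
  th <- youden_threshold(probs, labels)
  cm <- confusion_metrics(probs, labels, th)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
})

test_that("threshold rules change operating metrics but never the AUC", {
  d <- make_tabular_cohort(8, 12, seed = 13,
                           informative = "Mean (original)", effect = 2)
  m <- suppressWarnings(fit_subset_model(d, c("Mean (original)", "SD (LLL)"), seed = 1))
  ens <- structure(list(members = list(m), subsets = NULL, roi = "LV5",
                        k = 1L, config = list(kind = "radiomic")),
                   class = "rp_ensemble")
  r1 <- evaluate_cohort(d, ens, threshold_rule = "youden")
  r2 <- evaluate_cohort(d, ens, threshold_rule = "fixed")
  expect_equal(r1$auc, r2$auc)
  expect_named(r1, c("roi", "cohort", "auc", "sensitivity", "specificity",
                     "accuracy", "threshold", "threshold_rule"))
  expect_true(all(unlist(r1[, c("auc", "sensitivity", "specificity",
                                "accuracy")]) >= 0))
  expect_true(all(unlist(r1[, c("auc", "sensitivity", "specificity",
                                "accuracy")]) <= 1))
})

test_that("tidiers and plots expose the fitted objects", {
  d <- make_tabular_cohort(5, 10, seed = 14,
                           informative = "Correlation (original)", effect = 3)
  ens <- suppressWarnings(fit_rp_ensemble(d, k = 2, n_repeats = 5, seed = 2, roi = "LV5"))
  td <- tidy(ens)
  expect_true(all(c("member", "term", "estimate") %in% names(td)))
  gl <- glance(ens)
  expect_equal(gl$k, 2L)
  sig <- ens$members[[1]]$signature
  expect_s3_class(autoplot(sig), "ggplot")
  expect_s3_class(plot_roc(d, ens), "ggplot")
  expect_s3_class(plot_feature_by_label(d), "ggplot")
})
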