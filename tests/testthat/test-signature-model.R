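test_that("22 positives and 223 negatives split into 7x22 + 3x23 groups", {
  labels <- tibble::tibble(patient_id = sprintf("P%03d", 1:245),
                           rp_label = c(rep(1L, 22), rep(0L, 223)))
  subs <- partition_balanced_subsets(labels, k = 10, seed = 4)
  expect_length(subs, 10L)
  sizes <- sort(vapply(subs, function(s) length(s$negative_ids), integer(1)))
  expect_equal(sizes, c(rep(22L, 7), rep(23L, 3)))
  # every subset holds every positive exactly once
  for (s in subs) {
    expect_setequal(s$positive_ids, labels$patient_id[labels$rp_label == 1])
  }
  # negatives partition: disjoint with full coverage
  negs <- unlist(lapply(subs, `[[`, "negative_ids"))
  expect_equal(sort(negs), sort(labels$patient_id[labels$rp_label == 0]))
})

test_that("5 positives and 10 negatives give two 5+5 subsets", {
  labels <- tibble::tibble(patient_id = letters[1:15],
                           rp_label = c(rep(1L, 5), rep(0L, 10)))
  subs <- partition_balanced_subsets(labels, k = 2, seed = 1)
  expect_length(subs, 2L)
  expect_true(all(vapply(subs, function(s) length(s$negative_ids), 1L) == 5L))
})

test_that("infeasible subset counts error with the feasible range", {
  labels <- tibble::tibble(patient_id = letters[1:15],
                           rp_label = c(rep(1L, 5), rep(0L, 10)))
  expect_error(partition_balanced_subsets(labels, k = 5, seed = 1),
               "feasible k")
})

test_that("a planted informative feature tops the signature", {
  d <- make_tabular_cohort(10, 10, seed = 2,
                           informative = "Correlation (original)",
                           effect = 3)
  sig <- suppressWarnings(select_signature(d, n_repeats = 50, top_k = 4, seed = 3))
  expect_equal(sig$feature_names[1], "Correlation (original)")
  expect_length(sig$feature_names, 4L)
})

test_that("signature selection is deterministic under a fixed seed", {
  d <- make_tabular_cohort(8, 8, seed = 5, informative = "RLV (LHL)",
                           effect = 2)
  s1 <- suppressWarnings(select_signature(d, n_repeats = 20, seed = 11))
  s2 <- suppressWarnings(select_signature(d, n_repeats = 20, seed = 11))
  expect_identical(s1, s2)
})

test_that("subset models are valid logistic models on the signature", {
  d <- make_tabular_cohort(10, 10, seed = 6,
                           informative = "Mean (HLH)", effect = 3)
  m <- suppressWarnings(fit_subset_model(d, c("Mean (HLH)", "RLV (LHL)"), seed = 2))
  pr <- predict(m, d)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_named(m$coefficients, c("Mean (HLH)", "RLV (LHL)"))
  # degenerate class errors
  d$rp_label <- 1L
  expect_error(fit_subset_model(d, "Mean (HLH)", seed = 2), "degenerate")
})

test_that("probability ordering follows the separating direction", {
  d <- tibble::tibble(
    patient_id = sprintf("S%d", 1:8),
    rp_label = c(rep(0L, 4), rep(1L, 4)),
    f1 = c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2),
    f2 = rnorm(8, sd = 0.01)
  )
  m <- suppressWarnings(fit_subset_model(d, c("f1", "f2"), seed = 3))
  pr <- predict(m, d)
  expect_true(all(pr[5:8] > max(pr[1:4])))
})

test_that("the ensemble averages member probabilities", {
  d <- make_tabular_cohort(6, 6, seed = 7)
  m <- suppressWarnings(fit_subset_model(d, c("Mean (original)", "SD (original)"), seed = 1))
  ens <- structure(list(members = list(m, m, m), subsets = NULL,
                        roi = "LV5", k = 3L,
                        config = list(kind = "radiomic")),
                   class = "rp_ensemble")
  # identical members: ensemble equals any member
  expect_equal(predict(ens, d), predict(m, d))
  # hand-made members with fixed outputs {0.2, 0.4, 0.6} -> mean 0.4
  const_member <- function(p) {
    structure(list(features = "Mean (original)",
                   center = c("Mean (original)" = 0),
                   scale = c("Mean (original)" = 1),
                   intercept = stats::qlogis(p),
                   coefficients = c("Mean (original)" = 0)),
              class = "rp_subset_model")
  }
  ens2 <- structure(list(members = lapply(c(0.2, 0.4, 0.6), const_member),
                         subsets = NULL, roi = NULL, k = 3L,
                         config = list(kind = "radiomic")),
                    class = "rp_ensemble")
  expect_equal(predict(ens2, d), rep(0.4, nrow(d)))
  # permutation invariance and member-extremes bound
  ens3 <- ens2
  ens3$members <- rev(ens3$members)
  expect_equal(predict(ens2, d), predict(ens3, d))
  expect_true(all(predict(ens2, d) >= 0.2 & predict(ens2, d) <= 0.6))
})

test_that("missing signature features are reported by name", {
  d <- make_tabular_cohort(6, 6, seed = 8)
  m <- suppressWarnings(fit_subset_model(d, c("Mean (original)", "SD (original)"), seed = 1))
  ens <- structure(list(members = list(m), subsets = NULL, roi = NULL,
                        k = 1L, config = list(kind = "radiomic")),
                   class = "rp_ensemble")
  d2 <- d[, setdiff(names(d), "SD (original)")]
  expect_error(predict(ens, d2), "SD \\(original\\)")
})

test_that("default ensemble configuration has 10 members of 4 features", {
  expect_equal(eval(formals(fit_rp_ensemble)$k), 10L)
  expect_equal(eval(formals(fit_rp_ensemble)$top_k), 4L)
  expect_equal(eval(formals(select_signature)$top_k), 4L)
  d <- make_tabular_cohort(4, 42, seed = 9,
                           informative = "Correlation (original)", effect = 3)
  ens <- suppressWarnings(fit_rp_ensemble(d, k = 10, n_repeats = 5, seed = 2))
  expect_length(ens$members, 10L)
  expect_true(all(vapply(ens$members,
                         function(m) length(m$features) == 4L, logical(1))))
})

test_that("ensembles round-trip through JSON", {
  d <- make_tabular_cohort(5, 10, seed = 10,
                           informative = "Mean (LLL)", effect = 3)
  ens <- suppressWarnings(fit_rp_ensemble(d, k = 2, n_repeats = 5, seed = 3, roi = "LV5"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(predict(back, d), predict(ens, d), tolerance = 1e-12)
  expect_equal(back$roi, "LV5")
})

test_that("the DVH candidate pool has the four parameters", {
  d <- tibble::tibble(
    patient_id = sprintf("D%02d", 1:30),
    rp_label = c(rep(1L, 5), rep(0L, 25)),
    v5 = runif(30, 40, 90), v10 = runif(30, 20, 70),
    v20 = runif(30, 5, 40), mld = runif(30, 4, 18)
  )
  ens <- suppressWarnings(fit_dvh_model(d, k = 5, n_repeats = 10, seed = 2))
  expect_length(ens$members, 5L)
  pool <- c("v5", "v10", "v20", "mld")
  for (m in ens$members) expect_true(all(m$features %in% pool))
})

test_that("when only MLD varies, MLD is the selected parameter", {
  withr::with_seed(12, {
    n <- 30
    mld <- runif(n, 4, 18)
    d <- tibble::tibble(
      patient_id = sprintf("D%02d", 1:n),
      rp_label = as.integer(mld + rnorm(n, sd = 1) > 11),
      v5 = rep(70, n), v10 = rep(45, n), v20 = rep(20, n), mld = mld
    )
  })
  if (sum(d$rp_label) < 2) d$rp_label[1:2] <- 1L
  ens <- suppressWarnings(fit_dvh_model(d, k = 2, n_repeats = 10, seed = 3))
  for (m in ens$members) expect_equal(m$features, "mld")
})
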