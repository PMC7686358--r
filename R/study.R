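#' Run the full synthetic RP prediction study
#'
#' Drives the whole pipeline at the study's cohort structure: a training
#' cohort (default 22 RP-positive / 223 RP-negative) and an independently
#' generated test cohort (default 8 / 22), LV ROI extraction and 486-feature
#' radiomics per patient, DVH parameters, a balanced-subset
#' selection-frequency ensemble on the radiomic features, the DVH baseline
#' ensemble, and ROC evaluation of both on both cohorts (the Youden
#' threshold is optimised on training and frozen for the test cohort).
#'
#' Patients are generated and featurised one at a time, so memory stays
#' bounded by a single volume. Everything derives deterministically from
#' `seed`.
#'
#' @param seed Master seed for the whole study.
#' @param n_repeats LASSO repeats per subset (default 100; the full-scale
#'   analysis uses 1000).
#' @param k Number of balanced subsets (default 10).
#' @param train,test Length-2 integer vectors `(n_positive, n_negative)`.
#' @param threshold_gy Dose threshold of the ROI the radiomic model uses
#'   (default 5, i.e. LV5).
#' @param top_k Signature length (default 4).
#' @param ... Further arguments to [cohort_spec()] (grid shape, planted
#'   effect sizes, dose parameters).
#' @return A list with `features_train`, `features_test`, `dvh_train`,
#'   `dvh_test` (tibbles), `radiomic_model`, `dvh_model` (`rp_ensemble`s),
#'   `reports` (tibble of the four evaluations), `signature_hits` (members
#'   whose signature contains `"Correlation (original)"`), and
#'   `correlation_p` (two-sided rank-sum p-value for the planted
#'   correlation effect on the training cohort).
#' @export
run_rp_study <- function(seed = 1L, n_repeats = 100L, k = 10L,
                         train = c(22L, 223L), test = c(8L, 22L),
                         threshold_gy = 5, top_k = 4L, ...) {
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, 4L))
  spec_train <- cohort_spec(train[1], train[2], seed = seeds[1], ...)
  spec_test <- cohort_spec(test[1], test[2], seed = seeds[2], ...)
  roi_lab <- paste0("LV", threshold_gy)

  featurise <- function(spec) {
    plan <- cohort_plan(spec)
    rows <- purrr::map(seq_len(nrow(plan)), function(i) {
      p <- generate_patient(spec, plan$rp_label[i], plan$seed[i],
                            patient_id = plan$patient_id[i])
      roi <- extract_lvx(p, threshold_gy)
      fv <- extract_feature_vector(p, roi)
      list(
        features = dplyr::bind_cols(
          tibble::tibble(patient_id = p$patient_id, roi = roi_lab,
                         rp_label = p$rp_label),
          tibble::as_tibble(as.list(fv))
        ),
        dvh = tibble::tibble(patient_id = p$patient_id,
                             rp_label = p$rp_label,
                             v5 = compute_vx(p, 5), v10 = compute_vx(p, 10),
                             v20 = compute_vx(p, 20), mld = compute_mld(p))
      )
    })
    list(features = dplyr::bind_rows(purrr::map(rows, "features")),
         dvh = dplyr::bind_rows(purrr::map(rows, "dvh")))
  }

  tr <- featurise(spec_train)
  te <- featurise(spec_test)

  radiomic <- fit_rp_ensemble(tr$features, k = k, n_repeats = n_repeats,
                              top_k = top_k, seed = seeds[3], roi = roi_lab)
  dvh_model <- fit_dvh_model(tr$dvh, k = k, n_repeats = n_repeats,
                             seed = seeds[4])

  eval_pair <- function(model, dtrain, dtest) {
    rep_train <- evaluate_cohort(dtrain, model, cohort = "train")
    rep_test <- evaluate_cohort(dtest, model, cohort = "test",
                                threshold = rep_train$threshold)
    dplyr::bind_rows(rep_train, rep_test)
  }
  reports <- dplyr::bind_rows(
    eval_pair(radiomic, tr$features, te$features),
    eval_pair(dvh_model, tr$dvh, te$dvh)
  )

  planted <- "Correlation (original)"
  hits <- sum(vapply(radiomic$members,
                     function(m) planted %in% m$features, logical(1)))
  pval <- stats::wilcox.test(
    tr$features[[planted]][tr$features$rp_label == 1L],
    tr$features[[planted]][tr$features$rp_label == 0L],
    exact = FALSE
  )$p.value

  list(features_train = tr$features, features_test = te$features,
       dvh_train = tr$dvh, dvh_test = te$dvh,
       radiomic_model = radiomic, dvh_model = dvh_model,
       reports = reports, signature_hits = hits, correlation_p = pval)
}
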