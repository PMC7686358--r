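#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals the
#' trapezoidal area under the ROC curve with ties handled by midranks.
#'
#' @param probabilities Numeric scores (higher = more RP-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at a threshold
#'
#' Classifies as positive when `probability >= threshold`, then applies
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP) and
#' accuracy = (TP + TN) / (TP + FN + TN + FP).
#'
#' @inheritParams roc_auc
#' @param threshold Probability threshold (at-threshold classifies positive).
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`,
#'   `tp`, `fp`, `tn`, `fn` and `threshold`.
#' @export
confusion_metrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  pred <- probabilities >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fn + tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn,
    threshold = threshold
  )
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Tibble of `threshold`, `sensitivity`, `specificity` over all
#'   distinct score thresholds (plus the all-positive end).
#' @export
roc_points <- function(probabilities, labels) {
  th <- sort(unique(probabilities))
  purrr::map_dfr(th, function(t) {
    confusion_metrics(probabilities, labels, t)[, c("threshold",
                                                    "sensitivity",
                                                    "specificity")]
  })
}

#' Youden-optimal threshold
#'
#' The score threshold maximising Youden's J (sensitivity + specificity -
#' 1); among ties the smallest (most sensitive) threshold is returned.
#'
#' @inheritParams roc_auc
#' @return A single threshold value.
#' @export
youden_threshold <- function(probabilities, labels) {
  pts <- roc_points(probabilities, labels)
  j <- pts$sensitivity + pts$specificity - 1
  pts$threshold[which.max(j)]  # which.max takes the first (smallest) tie
}

#' Evaluate an ensemble on a cohort
#'
#' Scores a fitted ensemble on a feature (or DVH) table and reports AUC,
#' sensitivity, specificity and accuracy at an operating threshold. Under
#' `threshold_rule = "youden"` the threshold is optimised on this cohort
#' unless a frozen `threshold` (e.g. from the training cohort) is supplied;
#' `"fixed"` uses `threshold` as given (default 0.5).
#'
#' @param data Table with `rp_label` and the model's signature columns.
#' @param model A fitted `rp_ensemble`.
#' @param threshold_rule `"youden"` or `"fixed"`.
#' @param threshold Frozen or fixed threshold (see above).
#' @param cohort Cohort label recorded in the report (e.g. `"train"`).
#' @return One-row tibble: `roi`, `cohort`, `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, `threshold_rule`.
#' @export
evaluate_cohort <- function(data, model,
                            threshold_rule = c("youden", "fixed"),
                            threshold = NULL, cohort = "train") {
  threshold_rule <- match.arg(threshold_rule)
  probs <- predict(model, data)
  labels <- as.integer(data$rp_label)
  th <- if (threshold_rule == "youden") {
    if (is.null(threshold)) youden_threshold(probs, labels) else threshold
  } else {
    if (is.null(threshold)) 0.5 else threshold
  }
  cm <- confusion_metrics(probs, labels, th)
  tibble::tibble(
    roi = if (is.null(model$roi)) NA_character_ else model$roi,
    cohort = cohort,
    auc = roc_auc(probs, labels),
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    accuracy = cm$accuracy,
    threshold = th,
    threshold_rule = threshold_rule
  )
}
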