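#' Plot a signature's selection frequencies
#'
#' Bar chart of how often each signature feature was selected across the
#' LASSO repeats.
#'
#' @param object An `rp_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_signature <- function(object, ...) {
  d <- tidy.rp_signature(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$frequency),
    y = .data$frequency / .data$n_repeats
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "selection frequency",
                  title = "LASSO selection-frequency signature") +
    ggplot2::theme_minimal()
}

#' ROC curve for ensemble predictions
#'
#' @param data Table with `rp_label` and the model's feature columns.
#' @param model A fitted `rp_ensemble`.
#' @return A ggplot object showing sensitivity against 1 - specificity,
#'   annotated with the AUC.
#' @export
plot_roc <- function(data, model) {
  probs <- predict(model, data)
  labels <- as.integer(data$rp_label)
  pts <- roc_points(probs, labels)
  pts <- dplyr::arrange(pts, 1 - .data$specificity, .data$sensitivity)
  auc <- roc_auc(probs, labels)
  ggplot2::ggplot(pts, ggplot2::aes(1 - .data$specificity,
                                    .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh", colour = "firebrick") +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (%s), AUC = %.3f",
                                  model$roi %||% "ensemble", auc)) +
    ggplot2::theme_minimal()
}

#' Plot a feature's distribution by RP status
#'
#' Mirrors the usual biomarker bar/box comparison (e.g. GLCM correlation in
#' RP vs non-RP lungs).
#'
#' @param data Feature table with `rp_label` and the feature column.
#' @param feature Feature column name (string).
#' @return A ggplot object.
#' @export
plot_feature_by_label <- function(data, feature = "Correlation (original)") {
  stopifnot(feature %in% names(data))
  d <- tibble::tibble(
    value = data[[feature]],
    group = factor(ifelse(data$rp_label == 1, "RP", "non-RP"),
                   levels = c("non-RP", "RP"))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}
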