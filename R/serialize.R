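#' Serialize a fitted ensemble to JSON
#'
#' Stores, for every member, the signature (names and selection
#' frequencies), the logistic coefficients and the standardization
#' constants, plus the ensemble configuration, in a plain-text JSON file.
#'
#' @param model A fitted `rp_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "rp_ensemble"))
  members <- purrr::map(model$members, function(m) {
    sig <- m$signature
    list(
      features = m$features,
      frequencies = if (inherits(sig, "rp_signature")) sig$frequencies,
      intercept = m$intercept,
      coefficients = as.list(m$coefficients),
      center = as.list(m$center),
      scale = as.list(m$scale)
    )
  })
  jsonlite::write_json(
    list(roi = model$roi, k = model$k, config = model$config,
         members = members),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param path JSON file path.
#' @return An `rp_ensemble` usable with [predict()] / [ensemble_predict()].
#' @export
read_ensemble <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- purrr::map(j$members, function(m) {
    feats <- unlist(m$features)
    structure(list(
      signature = feats,
      features = feats,
      center = stats::setNames(unlist(m$center), names(m$center)),
      scale = stats::setNames(unlist(m$scale), names(m$scale)),
      intercept = m$intercept,
      coefficients = stats::setNames(unlist(m$coefficients),
                                     names(m$coefficients))
    ), class = "rp_subset_model")
  })
  structure(list(members = members, subsets = NULL, roi = j$roi,
                 k = as.integer(j$k), config = j$config),
            class = "rp_ensemble")
}
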