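#' Tidy a signature
#'
#' @param x An `rp_signature`.
#' @param ... Unused.
#' @return Tibble with one row per signature feature: `rank`, `feature`,
#'   `frequency`, `n_repeats`, `mean_abs_coef`.
#' @export
tidy.rp_signature <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$feature_names),
    feature = x$feature_names,
    frequency = x$frequencies,
    n_repeats = x$n_repeats,
    mean_abs_coef = x$mean_abs_coef
  )
}

#' Tidy an ensemble model
#'
#' @param x An `rp_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per (member, term): `member`, `term`
#'   (`"(Intercept)"` or a feature name) and `estimate` (coefficient on the
#'   member's standardized scale).
#' @export
tidy.rp_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble::tibble(
      member = i,
      term = c("(Intercept)", names(m$coefficients)),
      estimate = c(m$intercept, unname(m$coefficients))
    )
  })
}

#' One-line summary of an ensemble model
#'
#' @param x An `rp_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: `roi`, `k`, `n_features` (distinct features used
#'   across members), `kind`.
#' @export
glance.rp_ensemble <- function(x, ...) {
  feats <- unique(unlist(purrr::map(x$members, "features")))
  tibble::tibble(
    roi = if (is.null(x$roi)) NA_character_ else x$roi,
    k = x$k,
    n_features = length(feats),
    kind = x$config$kind
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
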