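#' Partition a cohort into balanced subsets
#'
#' Implements the imbalance-adjustment strategy behind the ensemble model:
#' every subset contains *all* positive cases, while the negatives are
#' randomly permuted (seeded) and split into `k` disjoint groups of size
#' `n_pos` or `n_pos + 1`. With 22 positives and 223 negatives, `k = 10`
#' gives 7 groups of 22 and 3 of 23.
#'
#' @param data A data frame with columns `patient_id` and `rp_label`
#'   (1 = grade >= 2 RP).
#' @param k Number of subsets (default 10).
#' @param seed Integer seed for the negative permutation.
#' @return A list of `k` objects of class `balanced_subset`, each a list
#'   with `positive_ids`, `negative_ids` and `index`.
#' @export
partition_balanced_subsets <- function(data, k = 10L, seed = 1L) {
  stopifnot(all(c("patient_id", "rp_label") %in% names(data)))
  pos <- data$patient_id[data$rp_label == 1L]
  neg <- data$patient_id[data$rp_label == 0L]
  n_pos <- length(pos)
  n_neg <- length(neg)
  if (n_pos < 2L) stop("need at least 2 positive cases", call. = FALSE)
  if (n_neg < n_pos) stop("need at least as many negatives as positives",
                          call. = FALSE)
  b <- n_neg - k * n_pos  # number of groups of size n_pos + 1
  if (b < 0L || b > k) {
    lo <- ceiling(n_neg / (n_pos + 1))
    hi <- floor(n_neg / n_pos)
    stop("no ", k, "-way split of ", n_neg, " negatives into groups of ",
         n_pos, " or ", n_pos + 1, "; feasible k: ",
         if (lo <= hi) paste(lo, "to", hi) else "none", call. = FALSE)
  }
  sizes <- c(rep(n_pos, k - b), rep(n_pos + 1L, b))
  perm <- withr::with_seed(as.integer(seed), sample(neg))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map(seq_len(k), function(i) {
    structure(list(positive_ids = pos,
                   negative_ids = perm[starts[i]:ends[i]],
                   index = i),
              class = "balanced_subset")
  })
}

# split a feature table into X (matrix) and y, dropping id columns
.design <- function(data, feature_cols = NULL) {
  stopifnot("rp_label" %in% names(data))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data), c("patient_id", "roi", "rp_label"))
  }
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as.integer(data$rp_label))
}

# stratified fold ids (no fold ever single-class)
.strat_folds <- function(y, nfolds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    w <- which(y == cls)
    id[w] <- rep_len(seq_len(nfolds), length(w))[sample.int(length(w))]
  }
  id
}

#' Select a selection-frequency signature by repeated LASSO
#'
#' For each of `n_repeats` repeats, draws a stratified bootstrap resample of
#' the rows, fits an L1-penalised logistic regression with the penalty
#' chosen by internal cross-validation, and records which features have
#' nonzero coefficients. Features are ranked by selection count (ties broken
#' by mean absolute coefficient, then by name) and the `top_k` are returned
#' as the signature.
#'
#' Features are z-standardised over `data` before fitting; all-constant
#' columns are dropped with a message.
#'
#' @param data Feature table restricted to one subset (and one ROI):
#'   `rp_label` plus feature columns (`patient_id`/`roi` ignored).
#' @param n_repeats Number of LASSO repeats (default 1000).
#' @param top_k Signature length (default 4).
#' @param seed Integer seed.
#' @param nfolds Cross-validation folds per repeat (default 3; the subsets
#'   are small).
#' @param feature_cols Optional explicit feature column names.
#' @return An object of class `rp_signature`: list with `feature_names`
#'   (length `top_k`, selection-count order), `frequencies`, `mean_abs_coef`,
#'   `n_repeats`, `counts` (full named count vector) and `short` (`TRUE` if
#'   fewer than `top_k` features were ever selected).
#' @export
select_signature <- function(data, n_repeats = 1000L, top_k = 4L, seed = 1L,
                             nfolds = 3L, feature_cols = NULL) {
  d <- .design(data, feature_cols)
  if (min(table(d$y)) < 2L) stop("need >= 2 patients per class", call. = FALSE)
  sds <- apply(d$x, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " all-constant feature column(s)")
  }
  keep <- sds > 0
  x <- scale(d$x[, keep, drop = FALSE])
  y <- d$y
  counts <- numeric(ncol(x))
  coefsum <- numeric(ncol(x))
  names(counts) <- names(coefsum) <- colnames(x)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_repeats)) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      foldid <- .strat_folds(y[idx], nfolds)
      cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                              family = "binomial", alpha = 1,
                              foldid = foldid, standardize = FALSE,
                              nlambda = 50)
      beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
      nz <- beta != 0
      counts[nz] <- counts[nz] + 1
      coefsum[nz] <- coefsum[nz] + abs(beta[nz])
    }
  })
  mean_abs <- ifelse(counts > 0, coefsum / pmax(counts, 1), 0)
  ord <- order(-counts, -mean_abs, names(counts))
  ever <- sum(counts > 0)
  short <- ever < top_k
  if (short) {
    warning("only ", ever, " feature(s) were ever selected; signature is ",
            "shorter than top_k = ", top_k, call. = FALSE)
  }
  take <- ord[seq_len(min(top_k, ever))]
  structure(list(
    feature_names = names(counts)[take],
    frequencies = unname(counts[take]),
    mean_abs_coef = unname(mean_abs[take]),
    n_repeats = as.integer(n_repeats),
    counts = counts,
    short = short
  ), class = "rp_signature")
}

#' @export
print.rp_signature <- function(x, ...) {
  cat("<rp_signature> top-", length(x$feature_names), " of ", x$n_repeats,
      " LASSO repeats\n", sep = "")
  for (i in seq_along(x$feature_names)) {
    cat(sprintf("  #%d %s (%d/%d)\n", i, x$feature_names[i],
                x$frequencies[i], x$n_repeats))
  }
  invisible(x)
}

# penalised (or, for a single predictor, plain) logistic fit returning
# intercept + coefficients on standardized columns
.fit_logistic <- function(x, y, seed, nfolds = 3L) {
  if (ncol(x) >= 2L) {
    cv <- withr::with_seed(as.integer(seed), {
      foldid <- .strat_folds(y, nfolds)
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                        foldid = foldid, standardize = FALSE, nlambda = 50)
    })
    b <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial())
    )
    if (any(abs(stats::coef(fit)) > 20)) {
      warning("near-separation in single-feature logistic fit", call. = FALSE)
    }
    b <- unname(stats::coef(fit))
  }
  list(intercept = b[1], coefficients = stats::setNames(b[-1], colnames(x)))
}

#' Fit one subset model on a signature
#'
#' L1-penalised logistic regression of the RP label (1 for grade >= 2, else
#' 0) on the signature features, with per-feature centring/scaling learned
#' from the subset. Perfect separation is kept finite by the penalty.
#'
#' @param data Feature table for one subset.
#' @param signature An [select_signature()] result, or a character vector of
#'   feature names.
#' @param seed Seed for the internal cross-validation folds.
#' @return An object of class `rp_subset_model` with elements `signature`,
#'   `center`, `scale`, `intercept`, `coefficients`.
#' @export
fit_subset_model <- function(data, signature, seed = 1L) {
  feats <- if (inherits(signature, "rp_signature")) signature$feature_names
           else as.character(signature)
  if (length(feats) == 0L) stop("empty signature", call. = FALSE)
  missing <- setdiff(feats, names(data))
  if (length(missing)) {
    stop("missing signature feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- .design(data, feats)
  if (length(unique(d$y)) < 2L) {
    stop("degenerate class: all labels equal", call. = FALSE)
  }
  ctr <- colMeans(d$x)
  scl <- apply(d$x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(d$x, center = ctr, scale = scl)
  fit <- .fit_logistic(xs, d$y, seed)
  structure(list(signature = signature, features = feats,
                 center = ctr, scale = scl,
                 intercept = fit$intercept,
                 coefficients = fit$coefficients),
            class = "rp_subset_model")
}

#' @export
predict.rp_subset_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata lacks signature feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  eta <- object$intercept + as.numeric(xs %*% object$coefficients)
  stats::plogis(eta)
}

#' Fit the balanced-subset ensemble-averaging RP model
#'
#' Partitions the cohort into `k` balanced subsets, selects a
#' selection-frequency signature and fits an L1-penalised logistic model on
#' each, and predicts by averaging the `k` member probabilities.
#'
#' @param data Feature table for one ROI: columns `patient_id`, `rp_label`
#'   and the radiomic feature columns (a `roi` column, if present, must be
#'   constant).
#' @param k Number of balanced subsets (default 10).
#' @param n_repeats LASSO repeats per subset (default 1000).
#' @param top_k Signature length (default 4).
#' @param seed Master seed; per-subset seeds derive from it.
#' @param roi Optional ROI label stored in the model.
#' @return An object of class `rp_ensemble`: list with `members` (length
#'   `k`, each an `rp_subset_model`), `subsets`, `roi`, `k` and the
#'   configuration used.
#' @export
fit_rp_ensemble <- function(data, k = 10L, n_repeats = 1000L, top_k = 4L,
                            seed = 1L, roi = NULL) {
  if ("roi" %in% names(data)) {
    stopifnot(length(unique(data$roi)) == 1L)
    if (is.null(roi)) roi <- data$roi[1]
  }
  subsets <- partition_balanced_subsets(data, k = k, seed = seed)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, 2L * k))
  members <- purrr::map(seq_len(k), function(i) {
    ids <- c(subsets[[i]]$positive_ids, subsets[[i]]$negative_ids)
    sub <- data[data$patient_id %in% ids, , drop = FALSE]
    sig <- select_signature(sub, n_repeats = n_repeats, top_k = top_k,
                            seed = seeds[i])
    fit_subset_model(sub, sig, seed = seeds[k + i])
  })
  structure(list(members = members, subsets = subsets, roi = roi,
                 k = as.integer(k),
                 config = list(n_repeats = n_repeats, top_k = top_k,
                               seed = seed, kind = "radiomic")),
            class = "rp_ensemble")
}

#' @export
predict.rp_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$members, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' Ensemble-averaged RP probabilities
#'
#' @param data Feature table with the signature columns of every member.
#' @param model An `rp_ensemble`.
#' @return `data`'s `patient_id`/`rp_label` columns (when present) with an
#'   `rp_prob` column appended: the arithmetic mean of the member model
#'   probabilities.
#' @export
ensemble_predict <- function(data, model) {
  stopifnot(inherits(model, "rp_ensemble"))
  keep <- intersect(c("patient_id", "rp_label"), names(data))
  dplyr::bind_cols(data[, keep, drop = FALSE],
                   tibble::tibble(rp_prob = predict(model, data)))
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat("<rp_ensemble> ", x$k, " member models",
      if (!is.null(x$roi)) paste0(" (", x$roi, ")"), "\n", sep = "")
  invisible(x)
}

#' Fit the DVH baseline ensemble
#'
#' The dose-volume histogram baseline: per balanced subset, the same
#' repeated-LASSO machinery runs over the four candidate parameters (V5,
#' V10, V20, MLD), but instead of a top-k cap the most frequently selected
#' nonzero parameter *combination* is kept and a logistic model is fitted on
#' it; the `k` models are ensemble-averaged exactly like the radiomic ones.
#'
#' @param data DVH table: columns `patient_id`, `rp_label`, `v5`, `v10`,
#'   `v20`, `mld` (see [dvh_table()]).
#' @param k Number of balanced subsets (default 10).
#' @param n_repeats LASSO repeats per subset (default 1000).
#' @param seed Master seed.
#' @return An `rp_ensemble` whose members carry the selected DVH parameter
#'   combination as their signature.
#' @export
fit_dvh_model <- function(data, k = 10L, n_repeats = 1000L, seed = 1L) {
  pool <- c("v5", "v10", "v20", "mld")
  stopifnot(all(pool %in% names(data)))
  subsets <- partition_balanced_subsets(data, k = k, seed = seed)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, 2L * k))
  members <- purrr::map(seq_len(k), function(i) {
    ids <- c(subsets[[i]]$positive_ids, subsets[[i]]$negative_ids)
    sub <- data[data$patient_id %in% ids, , drop = FALSE]
    combo <- .select_dvh_combo(sub, pool, n_repeats, seeds[i])
    fit_subset_model(sub, combo, seed = seeds[k + i])
  })
  structure(list(members = members, subsets = subsets, roi = "DVH",
                 k = as.integer(k),
                 config = list(n_repeats = n_repeats, seed = seed,
                               kind = "dvh")),
            class = "rp_ensemble")
}

# most frequent nonzero parameter combination over repeated LASSO
.select_dvh_combo <- function(data, pool, n_repeats, seed, nfolds = 3L) {
  d <- .design(data, pool)
  sds <- apply(d$x, 2, stats::sd)
  keep <- pool[sds > 0]
  if (length(keep) == 0L) stop("all DVH parameters are constant", call. = FALSE)
  x <- scale(d$x[, keep, drop = FALSE])
  y <- d$y
  pos <- which(y == 1L); neg <- which(y == 0L)
  combos <- character(n_repeats)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_repeats)) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      if (length(keep) >= 2L) {
        foldid <- .strat_folds(y[idx], nfolds)
        cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                                family = "binomial", alpha = 1,
                                foldid = foldid, standardize = FALSE,
                                nlambda = 50)
        beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
        combos[r] <- paste(keep[beta != 0], collapse = "+")
      } else {
        combos[r] <- keep
      }
    }
  })
  tab <- sort(table(combos), decreasing = TRUE)
  pick <- names(tab)[1]
  if (pick == "") {
    nonempty <- tab[names(tab) != ""]
    if (length(nonempty) == 0L) {
      stop("LASSO never selected any DVH parameter", call. = FALSE)
    }
    warning("most frequent DVH combination was empty; using the most ",
            "frequent non-empty one", call. = FALSE)
    pick <- names(nonempty)[1]
  }
  strsplit(pick, "+", fixed = TRUE)[[1]]
}
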