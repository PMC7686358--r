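# The 54-feature set computed per (ROI, domain): 14 histogram features plus
# 40 texture features (9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM). Feature
# names that would collide across families carry a family suffix
# (Entropy_GLCM, GLN_GLRLM, GLV_GLSZM, Contrast_NGTDM, ...); names of
# single-family features stay plain (Correlation, RLV, SZLGE, LZHGE, ...).

.hist_names <- c("Mean", "Variance", "SD", "Skewness", "Kurtosis", "Entropy",
                 "Uniformity", "Energy", "Minimum", "Maximum", "Median",
                 "Range", "MAD", "RMS")
.glcm_names <- c("Energy_GLCM", "Contrast", "Correlation", "Homogeneity",
                 "Variance_GLCM", "SumAverage", "Entropy_GLCM",
                 "Dissimilarity", "Autocorrelation")
.glrlm_names <- c("SRE", "LRE", "GLN_GLRLM", "RLN", "RP_runs", "LGRE",
                  "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV_GLRLM",
                  "RLV")
.glszm_names <- c("SZE", "LZE", "GLN_GLSZM", "ZSN", "ZP", "LGZE", "HGZE",
                  "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV_GLSZM", "ZSV")
.ngtdm_names <- c("Coarseness", "Contrast_NGTDM", "Busyness", "Complexity",
                  "Strength")

#' Names of the 54 per-domain radiomic features
#'
#' @return Character vector of length 54 (14 histogram + 40 texture).
#' @export
feature_basenames <- function() {
  c(.hist_names, .glcm_names, .glrlm_names, .glszm_names, .ngtdm_names)
}

#' Full 486-feature namespace
#'
#' The 54 per-domain features crossed with the 9 domains (original + 8
#' wavelet subbands), named `"<feature> (<domain>)"` as in
#' `"Correlation (original)"` or `"RLV (LHL)"`.
#' @return Character vector of length 486.
#' @export
feature_names <- function() {
  as.vector(vapply(
    feature_domains(),
    function(d) paste0(feature_basenames(), " (", d, ")"),
    character(54)
  ))
}

#' Histogram (first-order) features
#'
#' Fourteen first-order statistics of the in-mask intensities. Entropy
#' (bits) and uniformity are computed on the quantized gray-level histogram;
#' all others on the raw intensities. Variance and the higher moments use
#' the population (1/n) normalisation; kurtosis is the non-excess (Pearson)
#' form. Degenerate rule: skewness and kurtosis of zero-variance data are 0.
#'
#' @param q A [quantize()] result.
#' @param raw 3-D array of raw intensities the quantization came from.
#' @return Named numeric vector of length 14.
#' @export
histogram_features <- function(q, raw) {
  v <- raw[q$mask]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sk <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  p <- tabulate(q$levels[q$mask], nbins = q$n_levels) / n
  p1 <- p[p > 0]
  out <- c(
    mu, m2, sqrt(m2), sk, ku,
    -sum(p1 * log2(p1)), sum(p^2), sum(v^2),
    min(v), max(v), stats::median(v), max(v) - min(v),
    mean(abs(v - mu)), sqrt(mean(v^2))
  )
  names(out) <- .hist_names
  out
}

#' GLCM features
#'
#' Nine features of the probability-normalised symmetric co-occurrence
#' matrix. Correlation uses the marginal mean/variance of the symmetric
#' matrix and is defined as 0 when the marginal variance is 0.
#'
#' @param q A [quantize()] result.
#' @return Named numeric vector of length 9.
#' @export
glcm_features <- function(q) {
  m <- glcm_matrix(q)
  tot <- sum(m)
  if (tot == 0) stop("no in-mask voxel pairs at distance 1", call. = FALSE)
  p <- m / tot
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_marg <- rowSums(p)
  mu <- sum(seq_len(ng) * pi_marg)
  sig2 <- sum((seq_len(ng) - mu)^2 * pi_marg)
  corr <- if (sig2 > 0) sum(p * (i - mu) * (j - mu)) / sig2 else 0
  pp <- p[p > 0]
  out <- c(
    sum(p^2),
    sum(p * (i - j)^2),
    corr,
    sum(p / (1 + abs(i - j))),
    sum(p * (i - mu)^2),
    sum(p * (i + j)),
    -sum(pp * log2(pp)),
    sum(p * abs(i - j)),
    sum(p * i * j)
  )
  names(out) <- .glcm_names
  out
}

# shared emphasis features for run-length and size-zone matrices; m has
# rows = gray level, cols = run length / zone size; np = in-mask voxel count
.rl_sz_features <- function(m, np) {
  nr <- sum(m)
  if (nr == 0) stop("no runs/zones in mask", call. = FALSE)
  ng <- nrow(m); nl <- ncol(m)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  p <- m / nr
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  c(
    sum(m / j^2) / nr,              # short emphasis
    sum(m * j^2) / nr,              # long emphasis
    sum(rowSums(m)^2) / nr,         # gray-level non-uniformity
    sum(colSums(m)^2) / nr,         # length non-uniformity
    nr / np,                        # percentage (runs or zones per voxel)
    sum(m / i^2) / nr,              # low gray-level emphasis
    sum(m * i^2) / nr,              # high gray-level emphasis
    sum(m / (i^2 * j^2)) / nr,      # short + low
    sum(m * i^2 / j^2) / nr,        # short + high
    sum(m * j^2 / i^2) / nr,        # long + low
    sum(m * i^2 * j^2) / nr,        # long + high
    sum(p * (i - mu_i)^2),          # gray-level variance
    sum(p * (j - mu_j)^2)           # length variance
  )
}

#' GLRLM features
#'
#' Thirteen run-length features (SRE, LRE, GLN, RLN, run percentage, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV) of the direction-merged
#' run-length matrix. Run percentage divides the total run count by
#' `13 x` the in-mask voxel count, the maximum possible number of runs over
#' the 13 merged directions, so it stays in (0, 1].
#'
#' @param q A [quantize()] result.
#' @return Named numeric vector of length 13.
#' @export
glrlm_features <- function(q) {
  np <- sum(q$mask) * nrow(.offsets13())
  out <- .rl_sz_features(glrlm_matrix(q), np)
  names(out) <- .glrlm_names
  out
}

#' GLSZM features
#'
#' Thirteen size-zone features (SZE, LZE, GLN, ZSN, zone percentage, LGZE,
#' HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV) of the 26-connected
#' size-zone matrix. Zone percentage = zones / in-mask voxels.
#'
#' @param q A [quantize()] result.
#' @return Named numeric vector of length 13.
#' @export
glszm_features <- function(q) {
  out <- .rl_sz_features(glszm_matrix(q), sum(q$mask))
  names(out) <- .glszm_names
  out
}

#' NGTDM features
#'
#' The five neighbourhood gray-tone difference features (coarseness,
#' contrast, busyness, complexity, strength) restricted to in-mask
#' 26-neighbourhoods. Degenerate rules: coarseness is capped at `1e6` when
#' `sum(p * s) == 0`; contrast and busyness are 0 when only one gray level
#' is present; strength is 0 when `sum(s) == 0`.
#'
#' @param q A [quantize()] result.
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(q) {
  ng <- ngtdm_matrix(q)
  p <- ng$p; s <- ng$s
  nv <- ng$n_valid
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    ii <- rep(act, times = ngp)
    jj <- rep(act, each = ngp)
    contrast <- sum(p[ii] * p[jj] * (ii - jj)^2) / (ngp * (ngp - 1)) *
      sum(s) / nv
    busy_den <- sum(abs(ii * p[ii] - jj * p[jj]))
    busy <- if (busy_den > 0) ps / busy_den else 0
    cplx <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                  (p[ii] + p[jj])) / nv
    strength <- if (sum(s) > 0) {
      sum((p[ii] + p[jj]) * (ii - jj)^2) / sum(s)
    } else 0
  } else {
    contrast <- 0; busy <- 0; cplx <- 0; strength <- 0
  }
  out <- c(coarse, contrast, busy, cplx, strength)
  names(out) <- .ngtdm_names
  out
}

# all 54 features of one quantized domain
.domain_features <- function(q, raw) {
  c(histogram_features(q, raw), glcm_features(q), glrlm_features(q),
    glszm_features(q), ngtdm_features(q))
}

#' Extract the 486-feature radiomic vector for one (patient, ROI) pair
#'
#' Computes the 54 per-domain features on the masked original CT volume and
#' on each of its eight single-level wavelet subbands (the subbands are
#' computed on the full CT grid, then the ROI mask is applied unchanged).
#' Any non-finite value arising from a degenerate domain is mapped to 0 and
#' reported via a warning.
#'
#' @param patient A [generate_patient()]-style patient volume (list with at
#'   least a `ct` array), or a bare 3-D array.
#' @param roi An ROI mask from [extract_lvx()], or a bare logical array.
#' @param n_levels Gray levels for quantization (default 32).
#' @param basis Wavelet basis (default Coiflet-1).
#' @param boundary Wavelet boundary rule (default symmetric).
#' @return Named numeric vector of length 486.
#' @export
extract_feature_vector <- function(patient, roi, n_levels = 32L,
                                   basis = "coif1", boundary = "symmetric") {
  ct <- if (is.list(patient)) patient$ct else patient
  mask <- if (is.list(roi)) roi$mask else roi
  stopifnot(length(dim(ct)) == 3L, all(dim(ct) == dim(mask)))
  if (!any(mask)) stop("empty ROI: refusing to extract features", call. = FALSE)
  # crop to the mask bounding box (padded for the wavelet support) to keep
  # the texture passes cheap; features depend only on in-mask voxels
  pad <- length(wavelet_filters(basis)$lo)
  bb <- .bbox(mask, pad = pad, dims = dim(ct))
  ct <- ct[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  mask <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  domains <- c(list(original = ct),
               wavelet_subbands(ct, basis = basis, boundary = boundary))
  out <- unlist(lapply(names(domains), function(dn) {
    vol <- domains[[dn]]
    q <- quantize(vol, mask, n_levels = n_levels)
    f <- .domain_features(q, vol)
    names(f) <- paste0(names(f), " (", dn, ")")
    f
  }))
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("mapped ", sum(bad), " non-finite feature value(s) to 0: ",
            paste(utils::head(names(out)[bad], 5), collapse = ", "),
            call. = FALSE)
    out[bad] <- 0
  }
  out[feature_names()]
}

.bbox <- function(mask, pad, dims) {
  w <- which(mask, arr.ind = TRUE)
  lapply(1:3, function(ax) {
    seq.int(max(1L, min(w[, ax]) - pad), min(dims[ax], max(w[, ax]) + pad))
  })
}

#' Radiomic feature table for a cohort
#'
#' Runs ROI extraction and the 486-feature extractor for every patient and
#' every requested dose threshold, returning one row per (patient, ROI).
#'
#' @param cohort A list of patient volumes from [generate_cohort()].
#' @param thresholds_gy Dose thresholds defining the LVx ROIs
#'   (default `c(0, 5, 10, 20)`).
#' @param ... Passed on to [extract_feature_vector()].
#' @return A tibble with columns `patient_id`, `roi`, `rp_label` and the 486
#'   feature columns.
#' @export
extract_feature_table <- function(cohort, thresholds_gy = c(0, 5, 10, 20),
                                  ...) {
  rows <- purrr::map(cohort, function(p) {
    purrr::map(thresholds_gy, function(th) {
      roi <- extract_lvx(p, th)
      if (roi$n_voxels == 0L) {
        warning("empty LV", th, " for ", p$patient_id, "; row skipped",
                call. = FALSE)
        return(NULL)
      }
      fv <- extract_feature_vector(p, roi, ...)
      dplyr::bind_cols(
        tibble::tibble(patient_id = p$patient_id, roi = paste0("LV", th),
                       rp_label = p$rp_label),
        tibble::as_tibble(as.list(fv))
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
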