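#' Wavelet analysis filters
#'
#' Returns the decomposition (analysis) low-pass and high-pass filter pair
#' used for the single-level 3-D wavelet decomposition. The default basis is
#' Coiflet-1 (6-tap, orthonormal); Haar is available mainly for hand-checked
#' tests. Filters are returned in the usual orthonormal normalisation
#' (`sum(lo) == sqrt(2)`, `sum(lo^2) == 1`).
#'
#' @param basis One of `"coif1"` or `"haar"`.
#' @return A list with numeric vectors `lo` and `hi`.
#' @export
#' @examples
#' f <- wavelet_filters("haar")
#' sum(f$lo^2)
wavelet_filters <- function(basis = c("coif1", "haar")) {
  basis <- match.arg(basis)
  lo <- switch(basis,
    coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    haar  = c(0.7071067811865476, 0.7071067811865476)
  )
  n <- length(lo)
  # quadrature mirror: hi[k] = (-1)^k lo[n - 1 - k]  (0-based)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi, basis = basis)
}

# index vector of length n for a shift by `s` under the given boundary rule
.shift_index <- function(n, s, boundary) {
  i <- seq_len(n) + s
  if (boundary == "periodic") {
    ((i - 1) %% n) + 1
  } else {
    # half-sample symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
    j <- (i - 1) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
}

# filter a 3-D array along one axis (1 = z, 2 = y, 3 = x in this package's
# (z, y, x) storage order) with taps w; y[i] = sum_k w[k] x[i + k - c]
.filter_axis <- function(x, w, axis, boundary) {
  d <- dim(x)
  n <- d[axis]
  cc <- length(w) %/% 2L
  out <- array(0, dim = d)
  for (k in seq_along(w)) {
    idx <- .shift_index(n, k - cc, boundary)
    shifted <- switch(axis,
      x[idx, , , drop = FALSE],
      x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE]
    )
    out <- out + w[k] * shifted
  }
  out
}

#' Single-level 3-D wavelet subbands
#'
#' Decomposes a 3-D volume into its eight single-level separable wavelet
#' subbands by applying either the low-pass (L) or the high-pass (H) analysis
#' filter along each of the x, y and z axes. The transform is undecimated
#' (stationary), so every subband lives on the original voxel grid and any
#' ROI mask defined on the input applies to the subbands unchanged. Filters
#' are rescaled by `1/sqrt(2)` per axis so the transform is a tight frame:
#' with an orthonormal basis and periodic boundary handling the summed energy
#' of the eight subbands equals the energy of the input exactly.
#'
#' Subband labels are written filter-per-axis in x, y, z reading order:
#' `"LHH"` means low-pass along x, high-pass along y and high-pass along z.
#' Arrays are stored `(z, y, x)`.
#'
#' @param ct 3-D numeric array `(z, y, x)`.
#' @param basis Wavelet basis passed to [wavelet_filters()].
#' @param boundary `"symmetric"` (default, for feature extraction) or
#'   `"periodic"` (exact energy preservation).
#' @return Named list of eight 3-D arrays (`LLL`, `HLL`, `LHL`, `HHL`,
#'   `LLH`, `HLH`, `LHH`, `HHH`), each the shape of `ct`.
#' @export
#' @examples
#' v <- array(rnorm(8^3), dim = c(8, 8, 8))
#' sb <- wavelet_subbands(v, basis = "haar", boundary = "periodic")
#' sum(vapply(sb, function(s) sum(s^2), numeric(1))) - sum(v^2)  # ~ 0
wavelet_subbands <- function(ct, basis = "coif1",
                             boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.array(ct), length(dim(ct)) == 3L)
  f <- wavelet_filters(basis)
  if (any(dim(ct) < length(f$lo))) {
    stop("volume smaller than the wavelet filter support (",
         length(f$lo), ") along at least one axis", call. = FALSE)
  }
  lo <- f$lo / sqrt(2)
  hi <- f$hi / sqrt(2)
  taps <- list(L = lo, H = hi)
  out <- list()
  # axis 1 = z, 2 = y, 3 = x; label is x-major (x filter letter first)
  for (fz in c("L", "H")) {
    z1 <- .filter_axis(ct, taps[[fz]], 1L, boundary)
    for (fy in c("L", "H")) {
      z2 <- .filter_axis(z1, taps[[fy]], 2L, boundary)
      for (fx in c("L", "H")) {
        lab <- paste0(fx, fy, fz)
        out[[lab]] <- .filter_axis(z2, taps[[fx]], 3L, boundary)
      }
    }
  }
  order <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out[order]
}

#' Names of the nine feature domains
#'
#' The original CT volume plus the eight wavelet subbands.
#' @return Character vector of length 9.
#' @export
feature_domains <- function() {
  c("original", "LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}
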