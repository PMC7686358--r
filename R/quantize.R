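#' Quantize in-mask intensities to gray levels
#'
#' Uniform (equal-width) binning of the intensities inside a mask into
#' `n_levels` gray levels. The in-mask minimum maps to level 1 and the
#' maximum to level `n_levels`; quantization is monotone in intensity and
#' invariant under any affine rescaling with positive slope. Voxels outside
#' the mask are set to level 0 and carry no meaning downstream.
#'
#' @param x 3-D numeric array of intensities.
#' @param mask 3-D logical (or 0/1) array, same shape as `x`.
#' @param n_levels Number of gray levels `Ng >= 2`.
#' @return An object of class `quantized_roi`: list with `levels` (3-D
#'   integer array, 0 outside the mask), `n_levels`, `mask` (logical array)
#'   and `degenerate` (`TRUE` when the in-mask intensity was constant, in
#'   which case every in-mask voxel has level 1).
#' @export
quantize <- function(x, mask, n_levels = 32L) {
  stopifnot(is.array(x), length(dim(x)) == 3L, all(dim(x) == dim(mask)))
  if (n_levels < 2L) stop("n_levels must be at least 2", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(x))
  vals <- x[mask]
  if (length(vals) == 0L) stop("empty mask: nothing to quantize", call. = FALSE)
  lev <- array(0L, dim = dim(x))
  rng <- range(vals)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    lev[mask] <- 1L
  } else {
    width <- (rng[2] - rng[1]) / n_levels
    l <- floor((vals - rng[1]) / width) + 1
    l[l > n_levels] <- n_levels  # the maximum lands in the top bin
    lev[mask] <- as.integer(l)
  }
  structure(
    list(levels = lev, n_levels = as.integer(n_levels), mask = mask,
         degenerate = degenerate),
    class = "quantized_roi"
  )
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat("<quantized_roi> ", sum(x$mask), " voxels, Ng = ", x$n_levels,
      if (x$degenerate) " (degenerate: constant intensity)", "\n", sep = "")
  invisible(x)
}
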