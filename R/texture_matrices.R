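# Gray-level texture matrices on quantized 3-D ROIs.
#
# All four matrices follow the 3-D conventions of the classical radiomics
# literature: GLCM and GLRLM aggregate the 13 unique distance-1 direction
# offsets into a single matrix; GLSZM zones and NGTDM neighbourhoods use
# 26-connectivity. Out-of-mask voxels (level 0) never contribute: they are
# excluded from pairs, they break runs, and they are not counted as
# neighbours. The counting kernels live in src/texture.cpp; the test suite
# checks them entry-by-entry against naive enumeration oracles.

# the 13 unique 3-D direction offsets at distance 1 (antipodes removed),
# rows (dz, dy, dx)
.offsets13 <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  keep <- g[, "dx"] > 0 |
    (g[, "dx"] == 0 & g[, "dy"] > 0) |
    (g[, "dx"] == 0 & g[, "dy"] == 0 & g[, "dz"] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Gray level co-occurrence matrix (3-D, merged directions)
#'
#' Counts co-occurring gray-level pairs at voxel distance 1 over the 13
#' unique 3-D direction offsets, merged into one matrix and symmetrized
#' (each pair is counted in both orders). Only pairs with both voxels in
#' the mask contribute.
#'
#' @param q A [quantize()] result.
#' @return `Ng x Ng` symmetric matrix of raw counts.
#' @export
glcm_matrix <- function(q) {
  .glcm_counts_cpp(q$levels, as.integer(dim(q$levels)), .offsets13(),
                   q$n_levels)
}

#' Gray level run-length matrix (3-D, merged directions)
#'
#' Runs are maximal collinear segments of in-mask voxels sharing a gray
#' level; out-of-mask voxels break runs. Runs along the 13 unique 3-D
#' directions are accumulated into one matrix.
#'
#' @param q A [quantize()] result.
#' @param directions Optional integer matrix of `(dz, dy, dx)` offsets to
#'   accumulate over (rows); default all 13 unique distance-1 directions.
#' @return `Ng x Lmax` matrix of run counts (row = gray level,
#'   column = run length).
#' @export
glrlm_matrix <- function(q, directions = NULL) {
  if (is.null(directions)) directions <- .offsets13()
  storage.mode(directions) <- "integer"
  .glrlm_counts_cpp(q$levels, as.integer(dim(q$levels)), directions,
                    q$n_levels, max(dim(q$levels)))
}

#' Gray level size-zone matrix (3-D, 26-connected zones)
#'
#' Zones are 26-connected components of in-mask voxels sharing a gray level.
#'
#' @param q A [quantize()] result.
#' @return `Ng x Smax` matrix of zone counts (row = gray level,
#'   column = zone size).
#' @export
glszm_matrix <- function(q) {
  zs <- zone_table(q)
  m <- matrix(0, q$n_levels, max(zs$size))
  for (i in seq_len(nrow(zs))) {
    m[zs$level[i], zs$size[i]] <- m[zs$level[i], zs$size[i]] + 1
  }
  m
}

#' Connected same-level zones of a quantized ROI
#'
#' @param q A [quantize()] result.
#' @return A tibble with one row per 26-connected zone: `zone` id, gray
#'   `level` and `size` in voxels.
#' @export
zone_table <- function(q) {
  zone <- .label_zones_cpp(q$levels, as.integer(dim(q$levels)))
  ids <- zone[zone > 0L]
  levs <- q$levels[zone > 0L]
  size <- tabulate(ids)
  level <- levs[match(seq_along(size), ids)]
  tibble::tibble(zone = seq_along(size), level = as.integer(level), size = size)
}

#' Neighbourhood gray-tone difference matrix (3-D, 26-neighbourhood)
#'
#' For each gray level `i`, sums the absolute difference between the level
#' of each in-mask voxel of level `i` and the mean level of its in-mask
#' 26-neighbours; voxels with no in-mask neighbour are dropped.
#'
#' @param q A [quantize()] result.
#' @return A list with `s` (per-level difference sums), `n` (per-level voxel
#'   counts), `p` (`n` normalised over valid voxels) and `n_valid`.
#' @export
ngtdm_matrix <- function(q) {
  res <- .ngtdm_counts_cpp(q$levels, as.integer(dim(q$levels)), q$n_levels)
  nv <- sum(res$n)
  if (nv == 0L) stop("no voxel has an in-mask neighbour", call. = FALSE)
  list(s = res$s, n = res$n, p = res$n / nv, n_valid = nv)
}
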