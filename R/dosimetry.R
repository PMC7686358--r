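#' Dose-threshold lung ROI (LVx)
#'
#' Builds the binary ROI of lung voxels (GTV excluded) receiving strictly
#' more than `threshold_gy` Gy. The four default thresholds 0, 5, 10 and
#' 20 Gy define the LV0/LV5/LV10/LV20 regions used for feature extraction;
#' because dose thresholds only remove voxels, the masks are nested
#' (LV20 within LV10 within LV5 within LV0).
#'
#' @param patient A patient volume: list with 3-D arrays `dose`,
#'   `lung_mask`, `gtv_mask` of a common shape.
#' @param threshold_gy Dose threshold in Gy (`>= 0`); voxels with dose
#'   exactly at the threshold are excluded.
#' @return An object of class `roi_mask`: list with logical `mask`,
#'   `threshold_gy` and `n_voxels`. An empty result is returned with a
#'   warning (downstream feature extraction refuses empty ROIs).
#' @export
extract_lvx <- function(patient, threshold_gy) {
  stopifnot(threshold_gy >= 0,
            all(dim(patient$dose) == dim(patient$lung_mask)),
            all(dim(patient$dose) == dim(patient$gtv_mask)))
  m <- patient$lung_mask & !patient$gtv_mask & (patient$dose > threshold_gy)
  n <- sum(m)
  if (n == 0L) {
    warning("LV", threshold_gy, " is empty: no lung voxel exceeds ",
            threshold_gy, " Gy", call. = FALSE)
  }
  structure(list(mask = m, threshold_gy = threshold_gy, n_voxels = n),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> LV", x$threshold_gy, ": ", x$n_voxels, " voxels\n", sep = "")
  invisible(x)
}

.lung_dose <- function(patient) {
  keep <- patient$lung_mask & !patient$gtv_mask
  if (!any(keep)) stop("lung minus GTV is empty", call. = FALSE)
  patient$dose[keep]
}

#' Vx dose-volume parameter
#'
#' Percentage of the lung volume (GTV excluded) receiving strictly more
#' than `threshold_gy` Gy.
#'
#' @inheritParams extract_lvx
#' @return Percentage in `[0, 100]`.
#' @export
compute_vx <- function(patient, threshold_gy) {
  d <- .lung_dose(patient)
  100 * sum(d > threshold_gy) / length(d)
}

#' Mean lung dose
#'
#' Arithmetic mean dose over the lung volume with the GTV excluded.
#'
#' @inheritParams extract_lvx
#' @return Mean lung dose in Gy.
#' @export
compute_mld <- function(patient) {
  mean(.lung_dose(patient))
}

#' Dose-volume histogram parameter table for a cohort
#'
#' @param cohort List of patient volumes from [generate_cohort()].
#' @return A tibble with one row per patient: `patient_id`, `rp_label`,
#'   `v5`, `v10`, `v20` (percent) and `mld` (Gy).
#' @export
dvh_table <- function(cohort) {
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(
      patient_id = p$patient_id,
      rp_label = p$rp_label,
      v5 = compute_vx(p, 5),
      v10 = compute_vx(p, 10),
      v20 = compute_vx(p, 20),
      mld = compute_mld(p)
    )
  })
}
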