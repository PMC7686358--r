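#' Specification for a synthetic SBRT cohort
#'
#' Bundles the parameters of the synthetic cohort generator. Each patient is
#' an ellipsoidal lung region with an embedded spherical gross tumor volume
#' (GTV), a Gaussian dose field peaked at the GTV falling off with distance
#' (so LV20, LV10, LV5, LV0 are nested and V5/V10/V20/MLD vary with the GTV
#' position), and a lung texture made of Gaussian-smoothed noise. The
#' planted class effect acts through the smoothing kernel length: RP-positive
#' lungs use a longer kernel than RP-negative lungs, so their voxel-neighbor
#' spatial correlation is higher while the marginal intensity distribution
#' is matched (the smoothed field is renormalised to unit variance).
#'
#' @param n_positive,n_negative Patients per class (each `>= 1`).
#' @param grid_shape Integer length-3 `(z, y, x)` voxel counts, each `>= 16`.
#' @param spacing Voxel size in mm `(z, y, x)`; default `(2.0, 1.0, 1.0)`
#'   mimicking a 2-mm slice, ~1-mm in-plane planning CT.
#' @param correlation_length_pos,correlation_length_neg Gaussian smoothing
#'   kernel standard deviation (voxels) for the lung texture of RP-positive
#'   and RP-negative patients; the planted effect requires `pos > neg`.
#' @param dose_peak Peak dose in Gy at the GTV centroid (default 48, a
#'   typical SBRT prescription).
#' @param dose_falloff Distance scale (voxels) of the Gaussian dose falloff.
#' @param noise_sd Texture amplitude in intensity units.
#' @param lung_intensity Baseline lung intensity (HU-like).
#' @param seed Master seed; all per-patient seeds derive from it.
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_positive, n_negative,
                        grid_shape = c(48L, 48L, 48L),
                        spacing = c(2.0, 1.0, 1.0),
                        correlation_length_pos = 2.0,
                        correlation_length_neg = 1.0,
                        dose_peak = 48,
                        dose_falloff = 10,
                        noise_sd = 50,
                        lung_intensity = -800,
                        seed = 1L) {
  if (n_positive < 1L || n_negative < 1L) {
    stop("both classes must have at least one patient", call. = FALSE)
  }
  if (any(grid_shape < 16L)) stop("grid_shape must be >= 16 per axis", call. = FALSE)
  if (correlation_length_pos <= 0 || correlation_length_neg <= 0) {
    stop("smoothing kernel lengths must be positive", call. = FALSE)
  }
  if (correlation_length_pos <= correlation_length_neg) {
    stop("correlation_length_pos must exceed correlation_length_neg ",
         "(the planted effect's direction)", call. = FALSE)
  }
  if (dose_peak <= 0 || dose_falloff <= 0) {
    stop("dose_peak and dose_falloff must be positive", call. = FALSE)
  }
  structure(list(
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    grid_shape = as.integer(grid_shape), spacing = spacing,
    correlation_length_pos = correlation_length_pos,
    correlation_length_neg = correlation_length_neg,
    dose_peak = dose_peak, dose_falloff = dose_falloff,
    noise_sd = noise_sd, lung_intensity = lung_intensity,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# coordinate arrays (voxel index units) for a (z, y, x) grid
.coord_grids <- function(d) {
  list(
    z = array(rep_len(seq_len(d[1]), prod(d)), d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), d[3]), d),
    x = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}

# separable Gaussian smoothing of a 3-D field, renormalised so white-noise
# input keeps unit marginal variance
.smooth_noise <- function(noise, sigma) {
  r <- ceiling(3 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- noise
  for (ax in 1:3) out <- .filter_axis(out, w, ax, "symmetric")
  out / sum(w^2)^(3 / 2)  # variance of smoothed white noise = (sum w^2)^3
}

#' Generate one synthetic patient volume
#'
#' Deterministic in `(spec, rp_status, seed)`: two calls with identical
#' arguments return bit-identical grids.
#'
#' @param spec A [cohort_spec()].
#' @param rp_status 1 for a grade >= 2 RP case, 0 otherwise.
#' @param seed Integer seed for this patient.
#' @param patient_id Optional id string stored in the result.
#' @return A patient volume: list with 3-D arrays `ct`, `dose` (Gy),
#'   `lung_mask`, `gtv_mask` (all shaped `spec$grid_shape`, `(z, y, x)`),
#'   plus `spacing`, `rp_label`, `patient_id` and `gtv_center` (the exact
#'   continuous centre the dose field is peaked on, voxel units).
#' @export
generate_patient <- function(spec, rp_status, seed, patient_id = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"), rp_status %in% c(0L, 1L))
  d <- spec$grid_shape
  withr::with_seed(as.integer(seed), {
    co <- .coord_grids(d)
    ctr <- (d + 1) / 2
    semi <- 0.38 * d * stats::runif(3, 0.88, 1.0)
    lung <- ((co$z - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
      ((co$x - ctr[3]) / semi[3])^2 <= 1
    gtv_r <- stats::runif(1, 3, 5)
    if (gtv_r >= min(semi)) {
      stop("GTV radius exceeds the lung semi-axes", call. = FALSE)
    }
    # GTV centre uniform in a shrunken copy of the lung ellipsoid so the
    # sphere stays inside the lung
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    gctr <- ctr + u * (semi - gtv_r) * 0.92
    gtv <- sqrt((co$z - gctr[1])^2 + (co$y - gctr[2])^2 +
                  (co$x - gctr[3])^2) <= gtv_r
    sigma <- if (rp_status == 1L) spec$correlation_length_pos else
      spec$correlation_length_neg
    field <- .smooth_noise(array(stats::rnorm(prod(d)), d), sigma)
    ct <- spec$lung_intensity + spec$noise_sd * field
    ct[gtv] <- ct[gtv] + 830  # soft-tissue-like tumor, excluded downstream
    dist2 <- (co$z - gctr[1])^2 + (co$y - gctr[2])^2 + (co$x - gctr[3])^2
    dose <- spec$dose_peak * exp(-dist2 / (2 * spec$dose_falloff^2))
    if (!any(lung & !gtv)) stop("lung minus GTV is empty", call. = FALSE)
    list(ct = ct, dose = dose, lung_mask = lung, gtv_mask = gtv,
         spacing = spec$spacing, rp_label = as.integer(rp_status),
         patient_id = patient_id, gtv_center = gctr)
  })
}

#' Generate a synthetic cohort
#'
#' Per-patient seeds are derived deterministically from `spec$seed`; labels
#' are laid out positives-first and then shuffled by a seeded permutation so
#' cohort order carries no label information.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `n_positive + n_negative` patient volumes with ids
#'   `"P001"`, `"P002"`, ...
#' @export
generate_cohort <- function(spec) {
  plan <- cohort_plan(spec)
  purrr::map(seq_len(nrow(plan)), function(i) {
    generate_patient(spec, plan$rp_label[i], plan$seed[i],
                     patient_id = plan$patient_id[i])
  })
}

#' Deterministic per-patient plan for a cohort
#'
#' The ids, shuffled labels and per-patient seeds that [generate_cohort()]
#' realises; useful for generating patients one at a time without holding
#' the whole cohort in memory.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `patient_id`, `rp_label` and `seed`.
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_positive + spec$n_negative
  withr::with_seed(spec$seed, {
    labels <- c(rep(1L, spec$n_positive),
                rep(0L, spec$n_negative))[sample.int(n)]
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    tibble::tibble(patient_id = sprintf("P%03d", seq_len(n)),
                   rp_label = labels, seed = seeds)
  })
}

#' Cohort manifest
#'
#' @param cohort List of patient volumes.
#' @return Tibble with `patient_id` and `rp_label`.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(patient_id = p$patient_id, rp_label = p$rp_label)
  })
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Each patient gets `<id>_ct.nii.gz`, `<id>_dose.nii.gz`,
#' `<id>_lung.nii.gz` and `<id>_gtv.nii.gz`; `manifest.csv` lists ids,
#' paths and RP labels.
#'
#' @param cohort List of patient volumes.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- purrr::map_dfr(cohort, function(p) {
    paths <- file.path(dir, paste0(p$patient_id, "_",
                                   c("ct", "dose", "lung", "gtv"), ".nii.gz"))
    vols <- list(p$ct, p$dose, p$lung_mask * 1L, p$gtv_mask * 1L)
    for (i in 1:4) {
      RNifti::writeNifti(RNifti::asNifti(vols[[i]], pixdim = p$spacing),
                         paths[i])
    }
    tibble::tibble(patient_id = p$patient_id, rp_label = p$rp_label,
                   ct = paths[1], dose = paths[2], lung = paths[3],
                   gtv = paths[4])
  })
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A list of patient volumes.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(man)), function(i) {
    rd <- function(path) {
      v <- RNifti::readNifti(path)
      array(as.numeric(v), dim = dim(v))
    }
    ct_img <- RNifti::readNifti(man$ct[i])
    list(ct = array(as.numeric(ct_img), dim = dim(ct_img)),
         dose = rd(man$dose[i]),
         lung_mask = rd(man$lung[i]) > 0.5,
         gtv_mask = rd(man$gtv[i]) > 0.5,
         spacing = RNifti::pixdim(ct_img),
         rp_label = man$rp_label[i], patient_id = man$patient_id[i])
  })
}
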