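# Shared fixtures, all generated in code.

# quantized_roi built directly from a level array (0 = out of mask)
qroi_from_levels <- function(lev, ng = max(lev)) {
  structure(list(levels = array(as.integer(lev), dim = dim(lev)),
                 n_levels = as.integer(ng),
                 mask = array(lev > 0, dim = dim(lev)),
                 degenerate = FALSE),
            class = "quantized_roi")
}

# random masked level grid of side <= 5
rand_qroi <- function(seed, side = sample(2:5, 1), ng = 4L,
                      p_mask = 0.8) {
  withr::with_seed(seed, {
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(2:5, 1))
    lev <- array(sample.int(ng, prod(d), replace = TRUE), d)
    lev[array(runif(prod(d)) > p_mask, d)] <- 0L
    if (all(lev == 0L)) lev[1] <- 1L
    qroi_from_levels(lev, ng)
  })
}

# toy patient with explicit voxel doses, full lung, empty GTV
toy_patient <- function(doses, dims = c(2, 2, 1)) {
  list(ct = array(0, dims),
       dose = array(doses, dims),
       lung_mask = array(TRUE, dims),
       gtv_mask = array(FALSE, dims),
       spacing = c(2, 1, 1), rp_label = 0L, patient_id = "TOY")
}

# tabular cohort: rp_label plus the full 486-column namespace of noise
# features, with one optional informative column shifted by `effect`
make_tabular_cohort <- function(n_pos, n_neg, seed = 1,
                                informative = NULL, effect = 0) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    y <- sample(c(rep(1L, n_pos), rep(0L, n_neg)))
    x <- matrix(rnorm(n * 486), n, 486,
                dimnames = list(NULL, feature_names()))
    if (!is.null(informative)) {
      x[, informative] <- x[, informative] + effect * y
    }
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("T%03d", seq_len(n)), rp_label = y),
      tibble::as_tibble(x)
    )
  })
}

# one small default-physics patient, cached across tests
cached_patient <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- cohort_spec(2, 2, grid_shape = c(32L, 32L, 32L), seed = 5L)
      val <<- generate_patient(spec, 1L, 99L, patient_id = "FIX")
    }
    val
  }
})
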