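# Shared phantom fixtures, built once per test run. Everything is generated
# in code from fixed seeds; no binary fixtures.

phantom_anatomy <- make_phantom_anatomy()

# Five-band integer-TR lag field (symmetric about zero) on the default grid:
# bands along y at -4, -2, 0, +2, +4 s.
integer_lag_field <- local({
  dims <- phantom_anatomy$shape
  iy <- slice.index(array(0, dims), 2)
  f <- array(0, dims)
  f[iy <= 4] <- -4
  f[iy > 4 & iy <= 8] <- -2
  f[iy > 12 & iy <= 16] <- 2
  f[iy > 16] <- 4
  f
})

noisefree_truth <- make_ground_truth(phantom_anatomy,
                                     lag_field = integer_lag_field,
                                     noise_sd = 0, seed = 7)
noisefree_rest <- simulate_rest_bold(phantom_anatomy, noisefree_truth)

default_truth <- make_ground_truth(phantom_anatomy, seed = 11)
default_rest <- simulate_rest_bold(phantom_anatomy, default_truth)

bh_paradigm <- make_paradigm()
bh_n_frames <- floor(bh_paradigm$duration_s / 2) + 1
noisefree_co2 <- simulate_co2_trace(bh_paradigm, noise_sd = 0, seed = 1)

# Reference Spearman-free ROI set on the default anatomy
default_rois <- build_roi_set(phantom_anatomy$lesion_mask,
                              phantom_anatomy$gm_mask,
                              phantom_anatomy$left_hemi_mask,
                              phantom_anatomy$right_hemi_mask,
                              phantom_anatomy$voxel_size_mm,
                              phantom_anatomy$midline_index)

# Build a lag_map object directly from a field (for statistics tests that
# do not need the estimation path).
synthetic_lag_map <- function(field, mask, valid = NULL) {
  if (is.null(valid)) valid <- mask
  vals <- array(NA_real_, dim(mask))
  vals[valid] <- field[valid]
  structure(list(lag_s = vals, peak_r = array(0.9, dim(mask)),
                 valid = valid & mask, at_boundary = array(FALSE, dim(mask)),
                 TR = 2, mask = mask, reference_id = "synthetic",
                 shifts_s = seq(-8, 8, by = 2)),
            class = "lag_map")
}

synthetic_cvr_map <- function(field, mask, valid = NULL) {
  if (is.null(valid)) valid <- mask
  vals <- array(NA_real_, dim(mask))
  vals[valid] <- field[valid]
  structure(list(cvr = vals, delay_s = array(0, dim(mask)),
                 fit_r = array(0.9, dim(mask)), valid = valid & mask,
                 mask = mask, delays_s = seq(-15, 15, by = 0.1), r_min = 0.1),
            class = "cvr_map")
}
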