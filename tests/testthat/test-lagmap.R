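# Lag mapping: reference construction, correlogram, parabolic peak,
# map-level recovery.

test_that("reference timeseries is the masked mean and validates its mask", {
  b <- noisefree_rest
  an <- phantom_anatomy
  gm <- an$gm_mask
  ref <- reference_timeseries(b, gm, an$lesion_mask)
  eff <- gm & !an$lesion_mask
  expect_equal(ref, rowMeans(lagcvr:::bold_matrix(b, eff)))
  expect_error(reference_timeseries(b, gm, gm), "empty")

  # two voxels u and -u average to zero
  arr <- array(0, dim = c(2, 1, 1, 20))
  u <- sin(1:20)
  arr[1, 1, 1, ] <- u
  arr[2, 1, 1, ] <- -u
  bb <- bold_series(arr, TR = 2, brain_mask = array(TRUE, c(2, 1, 1)))
  expect_equal(reference_timeseries(bb, array(TRUE, c(2, 1, 1))), rep(0, 20))
})

test_that("correlogram enumerates 9 positions and respects the sign convention", {
  set.seed(3)
  s <- lagcvr:::band_limited_signal(400, 2)
  ref <- s[51:250]
  cg <- cross_correlogram(ref, ref, TR = 2)
  expect_length(cg$shifts_s, 9) # +/-4 frames at 2 s steps
  expect_equal(cg$shifts_s, seq(-8, 8, by = 2))
  expect_equal(cg$r[5], 1) # zero shift, perfect correlation
  expect_equal(which.max(cg$r), 5)

  # a voxel equal to the reference two frames earlier in index trails it:
  # voxel(t) = reference(t - 2 frames) -> argmax at +4 s
  vox <- s[49:248]
  cg2 <- cross_correlogram(vox, ref, TR = 2)
  expect_equal(cg$shifts_s[which.max(cg2$r)], 4)

  # antisymmetry: swapping voxel and reference negates the argmax
  cg3 <- cross_correlogram(ref, vox, TR = 2)
  expect_equal(cg3$shifts_s[which.max(cg3$r)], -4)

  # insufficient overlap is flagged, not computed
  fv <- rep(c(TRUE, FALSE), length.out = 200)
  fv[1:180] <- FALSE
  cg4 <- cross_correlogram(vox, ref, frame_valid = fv, TR = 2)
  expect_true(any(is.na(cg4$r)))
  expect_true(all(cg4$n_pairs[is.na(cg4$r)] < 10))
})

test_that("parabolic peak matches closed-form examples and boundary policy", {
  mk <- function(r) structure(list(shifts_s = seq(-8, 8, 2), r = r,
                                   n_pairs = rep(100, 9)), class = "correlogram")
  # symmetric triple -> vertex at the centre
  r <- c(0, 0, 0, .2, .8, .2, 0, 0, 0)
  expect_equal(parabolic_peak(mk(r))$lag_s, 0)
  # hand-derived asymmetric triple: offset = 0.5(.3-.5)/(.3-1.6+.5) = 0.125
  r <- c(0, 0, 0, .3, .8, .5, .1, 0, 0)
  pk <- parabolic_peak(mk(r))
  expect_equal(pk$lag_s, 0.25)
  expect_gt(pk$peak_r, 0.8)
  # boundary maximum is clamped, not extrapolated
  r <- c(.9, .8, .2, .1, 0, 0, 0, 0, 0)
  pk <- parabolic_peak(mk(r))
  expect_equal(pk$lag_s, -8)
  expect_true(pk$at_boundary)
  # an all-tied correlogram clamps at its first grid point (a boundary)
  r <- rep(0.5, 9)
  pk <- parabolic_peak(mk(r))
  expect_true(pk$at_boundary)
  expect_equal(pk$lag_s, -8)
  # zero-curvature interior triple returns the grid shift, flagged degenerate
  r <- c(0, 0, 0, .5, .5 + 1e-15, .5, 0, 0, 0)
  pk <- parabolic_peak(mk(r))
  expect_true(pk$degenerate)
  expect_equal(pk$lag_s, 0)
})

test_that("parabolic vertex equals a dense-grid quadratic oracle", {
  set.seed(12)
  mk <- function(r3) structure(list(shifts_s = c(-2, 0, 2), r = r3,
                                    n_pairs = rep(100, 3)), class = "correlogram")
  for (i in 1:100) {
    r0 <- runif(1, 0.5, 0.99)
    rm1 <- runif(1, 0, r0 - 0.05)
    rp1 <- runif(1, 0, r0 - 0.05)
    pk <- parabolic_peak(mk(c(rm1, r0, rp1)))
    # oracle: least-squares quadratic through the three points, vertex found
    # by two-stage dense-grid search
    fit <- lm(y ~ x + I(x^2), data = data.frame(x = c(-1, 0, 1), y = c(rm1, r0, rp1)))
    g1 <- seq(-1, 1, by = 1e-3)
    v1 <- g1[which.max(predict(fit, data.frame(x = g1)))]
    g2 <- seq(v1 - 2e-3, v1 + 2e-3, by = 1e-7)
    v2 <- g2[which.max(predict(fit, data.frame(x = g2)))]
    expect_lt(abs(pk$lag_s - v2 * 2), 1e-6)
  }
})

test_that("integer-TR lags are recovered exactly against a zero-lag reference", {
  an <- phantom_anatomy
  b <- noisefree_rest
  zero_band <- an$gm_mask & (integer_lag_field == 0)
  ref <- reference_timeseries(b, zero_band)
  lm0 <- compute_lag_map(b, ref, mask = an$gm_mask)
  sel <- lm0$valid & !an$lesion_mask
  expect_gt(sum(sel), 1000)
  expect_identical(max(abs(lm0$lag_s[sel] - integer_lag_field[sel])), 0)
})

test_that("integer-TR lags are recovered closely against the mixed GM reference", {
  an <- phantom_anatomy
  b <- noisefree_rest
  ref <- reference_timeseries(b, an$gm_mask, an$lesion_mask)
  lmm <- compute_lag_map(b, ref, mask = an$gm_mask)
  sel <- lmm$valid & !an$lesion_mask
  # the reference is a mixture of shifted copies, so the empirical
  # correlogram is not exactly symmetric; the vertex error stays small
  expect_lt(max(abs(lmm$lag_s[sel] - integer_lag_field[sel])), 0.1)
})

test_that("fractional lags are recovered within interpolation error", {
  an <- phantom_anatomy
  dims <- an$shape
  iy <- slice.index(array(0, dims), 2)
  f <- array(0, dims)
  f[iy > 14] <- 1.0
  tr <- make_ground_truth(an, lag_field = f, noise_sd = 0, seed = 19)
  b <- simulate_rest_bold(an, tr)
  ref <- reference_timeseries(b, an$gm_mask, an$lesion_mask)
  lmf <- compute_lag_map(b, ref, mask = an$gm_mask)
  sel <- lmf$valid & !an$lesion_mask & f == 1
  expect_gt(sum(sel), 100)
  expect_lt(max(abs(lmf$lag_s[sel] - 1.0)), 0.25)
})

test_that("delaying a voxel by one extra TR raises its recovered lag by TR", {
  set.seed(21)
  sfine <- lagcvr:::band_limited_signal(5000, 0.1)
  ft <- (0:149) * 2
  samp <- function(shift) lagcvr:::lin_interp(sfine, -20, 0.1, ft - shift)
  ref <- samp(0)
  lag_of <- function(shift) {
    parabolic_peak(cross_correlogram(samp(shift), ref, TR = 2))$lag_s
  }
  for (tau in c(-1.4, 0.3, 1.7)) {
    expect_equal(lag_of(tau + 2) - lag_of(tau), 2, tolerance = 0.15)
  }
})

test_that("white-noise voxels are excluded by the r threshold on long series", {
  set.seed(31)
  nt <- 600
  ref <- lagcvr:::band_limited_signal(nt, 2)
  nv <- 200
  arr <- array(rnorm(nv * nt), dim = c(nv, 1, 1, nt))
  b <- bold_series(arr, TR = 2, brain_mask = array(TRUE, c(nv, 1, 1)))
  lmn <- compute_lag_map(b, ref)
  expect_lt(mean(lmn$valid), 0.2)
})

test_that("censored frames and physically absent frames give identical results", {
  an <- phantom_anatomy
  tr <- make_ground_truth(an, lag_field = integer_lag_field, noise_sd = 0, seed = 7)
  b_long <- simulate_rest_bold(an, tr, n_frames = 160)
  # flag the trailing 10 frames invalid
  b_flag <- b_long
  b_flag$frame_valid[151:160] <- FALSE
  b_cut <- bold_series(b_long$data[, , , 1:150, drop = FALSE], TR = 2,
                       brain_mask = an$brain)
  ref_flag <- reference_timeseries(b_flag, an$gm_mask)
  ref_cut <- reference_timeseries(b_cut, an$gm_mask)
  vox <- which(an$gm_mask, arr.ind = TRUE)[40, ]
  cg_flag <- cross_correlogram(b_flag$data[vox[1], vox[2], vox[3], ],
                               ref_flag, b_flag$frame_valid, TR = 2)
  cg_cut <- cross_correlogram(b_cut$data[vox[1], vox[2], vox[3], ],
                              ref_cut[1:150], TR = 2)
  expect_equal(cg_flag$r, cg_cut$r)
  expect_equal(cg_flag$n_pairs, cg_cut$n_pairs)
})

test_that("map-level recovery at SNR 3 stays under 0.3 s RMSE", {
  an <- phantom_anatomy
  b <- default_rest
  ref <- reference_timeseries(b, an$gm_mask, an$lesion_mask)
  lmr <- compute_lag_map(b, ref, mask = an$gm_mask)
  sel <- lmr$valid & an$gm_mask & !an$lesion_mask
  rmse <- sqrt(mean((lmr$lag_s[sel] - default_truth$lag_field[sel])^2))
  expect_lt(rmse, 0.3)
  expect_gt(mean(lmr$valid[an$gm_mask & !an$lesion_mask]), 0.95)
})

test_that("hemisphere mean lag averages only valid voxels", {
  an <- phantom_anatomy
  f <- array(0.5, an$shape)
  m <- synthetic_lag_map(f, an$gm_mask)
  expect_equal(hemisphere_mean_lag(m, an$left_hemi_mask), 0.5)

  # half +1, half -1 averages to zero
  f2 <- array(1, an$shape)
  f2[slice.index(array(0, an$shape), 3) %% 2 == 0] <- -1
  counts <- table(f2[an$gm_mask & an$left_hemi_mask])
  m2 <- synthetic_lag_map(f2, an$gm_mask)
  expect_equal(hemisphere_mean_lag(m2, an$left_hemi_mask),
               weighted.mean(c(-1, 1), counts))

  # invalid voxels are excluded from the mean
  valid <- an$gm_mask & (f2 == 1)
  m3 <- synthetic_lag_map(f2, an$gm_mask, valid = valid)
  expect_equal(hemisphere_mean_lag(m3, an$left_hemi_mask), 1)
  expect_error(hemisphere_mean_lag(m3, an$csf_mask), "valid")
})
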