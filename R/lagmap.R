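# Voxelwise haemodynamic lag mapping: discrete shift cross-correlation
# against a reference timeseries, with parabolic sub-sample peak
# interpolation. Sign convention: positive lag means the voxel trails
# (is delayed relative to) the reference; negative means it leads.

#' Grey-matter reference timeseries
#'
#' Frame-wise mean BOLD signal over grey-matter voxels, after removing an
#' exclusion mask (typically the lesion). This is the reference against
#' which voxel lags are measured.
#'
#' @param bold a [bold_series()].
#' @param gm_mask logical grey-matter volume.
#' @param exclude_mask optional logical volume removed from the average.
#' @return Numeric vector, one value per frame.
#' @export
reference_timeseries <- function(bold, gm_mask, exclude_mask = NULL) {
  dims <- dim(bold$data)[1:3]
  gm_mask <- as_mask(gm_mask, dims, "gm_mask")
  eff <- gm_mask
  if (!is.null(exclude_mask)) {
    eff <- eff & !as_mask(exclude_mask, dims, "exclude_mask")
  }
  if (sum(eff) == 0L) stop("reference mask is empty after exclusion")
  rowMeans(bold_matrix(bold, eff))
}

#' Cross-correlogram of a voxel against the reference
#'
#' For each integer shift `k` in `-K..K`, the Pearson correlation of
#' `voxel(t)` with `reference(t - k * TR)` over the frame pairs where both
#' frames are valid. Positive `k` (and positive lag) means the voxel trails
#' the reference. Shifts with fewer than `min_pairs` overlapping valid
#' pairs are flagged (`NA`) rather than silently computed.
#'
#' @param voxel,reference numeric timeseries of equal length.
#' @param frame_valid logical per-frame validity flags.
#' @param TR repetition time (s).
#' @param max_shift_frames search half-width `K` in frames (default 4, i.e.
#'   +/-8 s at TR 2 s: 9 shift positions).
#' @param min_pairs minimum valid overlap per shift (default 10).
#' @return A `correlogram`: list with `shifts_s`, `r` and `n_pairs`.
#' @export
cross_correlogram <- function(voxel, reference, frame_valid = NULL, TR,
                              max_shift_frames = 4, min_pairs = 10) {
  nt <- length(voxel)
  if (length(reference) != nt) stop("voxel and reference lengths differ")
  if (is.null(frame_valid)) frame_valid <- rep(TRUE, nt)
  K <- as.integer(max_shift_frames)
  shifts <- (-K):K
  r <- rep(NA_real_, length(shifts))
  n_pairs <- integer(length(shifts))
  for (j in seq_along(shifts)) {
    k <- shifts[j]
    t_idx <- seq(max(1, 1 + k), min(nt, nt + k))
    r_idx <- t_idx - k
    ok <- frame_valid[t_idx] & frame_valid[r_idx]
    n_pairs[j] <- sum(ok)
    if (n_pairs[j] >= min_pairs) {
      x <- voxel[t_idx[ok]]
      y <- reference[r_idx[ok]]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        r[j] <- stats::cor(x, y)
      }
    }
  }
  structure(list(shifts_s = shifts * TR, r = r, n_pairs = n_pairs),
            class = "correlogram")
}

#' Parabolic interpolation of the correlogram peak
#'
#' Fits the unique parabola through the maximum of the correlogram and its
#' two neighbouring shift positions and returns the vertex abscissa (the
#' sub-sample lag, seconds) and ordinate (the interpolated peak
#' correlation). A maximum at the edge of the shift grid is clamped to that
#' boundary shift (`at_boundary = TRUE`) rather than extrapolated beyond
#' the search window. Two degenerate cases return the grid shift itself
#' with `degenerate = TRUE`: a flat triple (zero curvature), and a perfect
#' peak correlation (within machine tolerance of 1), where any interpolated
#' vertex would assert a correlation above 1.
#'
#' @param cg a [cross_correlogram()] result.
#' @return List with `lag_s`, `peak_r`, `at_boundary`, `degenerate`.
#' @export
parabolic_peak <- function(cg) {
  r <- cg$r
  if (all(is.na(r))) {
    return(list(lag_s = NA_real_, peak_r = NA_real_,
                at_boundary = FALSE, degenerate = TRUE))
  }
  m <- which.max(r)
  step <- diff(cg$shifts_s[1:2])
  boundary <- m == 1L || m == length(r) ||
    is.na(r[m - 1L]) || is.na(r[m + 1L])
  if (boundary) {
    return(list(lag_s = cg$shifts_s[m], peak_r = r[m],
                at_boundary = TRUE, degenerate = FALSE))
  }
  rm1 <- r[m - 1L]; r0 <- r[m]; rp1 <- r[m + 1L]
  denom <- rm1 - 2 * r0 + rp1
  if (abs(denom) < 1e-12 || r0 >= 1 - 1e-12) {
    return(list(lag_s = cg$shifts_s[m], peak_r = r0,
                at_boundary = FALSE, degenerate = TRUE))
  }
  offset <- 0.5 * (rm1 - rp1) / denom
  a <- denom / 2
  b <- (rp1 - rm1) / 2
  list(lag_s = cg$shifts_s[m] + offset * step,
       peak_r = r0 + b * offset + a * offset^2,
       at_boundary = FALSE, degenerate = FALSE)
}

#' Compute a voxelwise haemodynamic lag map
#'
#' Per masked voxel: cross-correlogram against the reference, validity test
#' (the maximum correlation over the integer shifts must reach `r_min`;
#' voxels below it are excluded, as are zero-variance voxels), then
#' parabolic peak interpolation. Per-voxel failures yield invalid voxels,
#' never aborts.
#'
#' @param bold a [bold_series()].
#' @param reference reference timeseries from [reference_timeseries()].
#' @param mask analysis mask (default the brain mask).
#' @param r_min minimum peak correlation for a voxel to be mapped
#'   (default 0.1; voxels with `r < 0.1` are excluded).
#' @param max_shift_frames shift search half-width in frames (default 4).
#' @param min_pairs minimum valid overlap per shift (default 10).
#' @param reference_id label recorded on the map.
#'
#' @return A `lag_map`: 3D arrays `lag_s` (NA where invalid), `peak_r`,
#'   logical `valid`, `at_boundary`, plus `TR`, `mask` and `reference_id`.
#' @export
compute_lag_map <- function(bold, reference, mask = bold$brain_mask,
                            r_min = 0.1, max_shift_frames = 4,
                            min_pairs = 10, reference_id = "gm_mean") {
  dims <- dim(bold$data)[1:3]
  mask <- as_mask(mask, dims, "mask")
  nt <- n_frames(bold)
  valid <- bold$frame_valid
  K <- as.integer(max_shift_frames)
  shifts <- (-K):K
  Y <- bold_matrix(bold, mask)
  nv <- ncol(Y)

  R <- matrix(NA_real_, nrow = nv, ncol = length(shifts))
  for (j in seq_along(shifts)) {
    k <- shifts[j]
    t_idx <- seq(max(1, 1 + k), min(nt, nt + k))
    r_idx <- t_idx - k
    ok <- valid[t_idx] & valid[r_idx]
    if (sum(ok) < min_pairs) next
    t_idx <- t_idx[ok]; r_idx <- r_idx[ok]
    yv <- Y[t_idx, , drop = FALSE]
    rv <- reference[r_idx]
    yc <- sweep(yv, 2, colMeans(yv))
    rc <- rv - mean(rv)
    denom <- sqrt(colSums(yc^2) * sum(rc^2))
    rj <- as.vector(crossprod(yc, rc)) / denom
    rj[!is.finite(rj)] <- NA_real_
    R[, j] <- rj
  }

  Rf <- R
  Rf[is.na(Rf)] <- -Inf
  m <- max.col(Rf, ties.method = "first")
  idx <- cbind(seq_len(nv), m)
  rmax <- Rf[idx]
  vox_valid <- is.finite(rmax) & rmax >= r_min

  lag <- rep(NA_real_, nv)
  peak <- rep(NA_real_, nv)
  at_bd <- rep(FALSE, nv)

  interior <- vox_valid & m > 1L & m < length(shifts)
  rm1 <- rp1 <- rep(NA_real_, nv)
  rm1[interior] <- R[cbind(which(interior), m[interior] - 1L)]
  rp1[interior] <- R[cbind(which(interior), m[interior] + 1L)]
  interior <- interior & !is.na(rm1) & !is.na(rp1)

  bd <- vox_valid & !interior
  lag[bd] <- shifts[m[bd]] * bold$TR
  peak[bd] <- rmax[bd]
  at_bd[bd] <- m[bd] == 1L | m[bd] == length(shifts)

  r0 <- rmax
  denom2 <- rm1 - 2 * r0 + rp1
  snap <- interior & (abs(denom2) < 1e-12 | r0 >= 1 - 1e-12)
  lag[snap] <- shifts[m[snap]] * bold$TR
  peak[snap] <- r0[snap]

  fit <- interior & !snap
  off <- 0.5 * (rm1[fit] - rp1[fit]) / denom2[fit]
  a <- denom2[fit] / 2
  b <- (rp1[fit] - rm1[fit]) / 2
  lag[fit] <- (shifts[m[fit]] + off) * bold$TR
  peak[fit] <- r0[fit] + b * off + a * off^2

  structure(
    list(lag_s = vec_to_vol(lag, mask),
         peak_r = vec_to_vol(peak, mask),
         valid = vec_to_vol(vox_valid, mask, fill = FALSE) == 1,
         at_boundary = vec_to_vol(at_bd, mask, fill = FALSE) == 1,
         TR = bold$TR, mask = mask, reference_id = reference_id,
         shifts_s = shifts * bold$TR),
    class = "lag_map"
  )
}

#' @export
print.lag_map <- function(x, ...) {
  cat(sprintf("<lag_map> reference '%s', %d valid voxels (of %d in mask)\n",
              x$reference_id, sum(x$valid), sum(x$mask)))
  if (any(x$valid)) {
    cat(sprintf("  lag range: [%.2f, %.2f] s; search grid +/-%g s\n",
                min(x$lag_s[x$valid]), max(x$lag_s[x$valid]),
                max(x$shifts_s)))
  }
  invisible(x)
}

#' Mean lag over a mask
#'
#' Mean of the lag values over valid voxels inside `mask`; used for the
#' lesioned-hemisphere grey-matter summary.
#'
#' @param lagmap a [compute_lag_map()] result.
#' @param mask logical volume.
#' @return Mean lag in seconds.
#' @export
hemisphere_mean_lag <- function(lagmap, mask) {
  mask <- as_mask(mask, dim(lagmap$lag_s), "mask")
  sel <- mask & lagmap$valid
  if (sum(sel) == 0L) stop("no valid lag voxels inside the mask")
  mean(lagmap$lag_s[sel])
}
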