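# Breath-hold cerebrovascular reactivity mapping: end-tidal CO2 envelope
# construction, double-gamma HRF convolution, and exhaustive voxelwise CO2
# delay search with a single-regressor GLM. CVR is reported in units of
# %BOLD signal change per mmHg change in end-tidal CO2.

#' Detect end-tidal (expiratory peak) points of a CO2 trace
#'
#' End-tidal CO2 points are the expiratory peaks of the capnograph trace:
#' local maxima separated by at least `min_peak_separation_s`, with a
#' minimum prominence so that measurement noise on the flat breath-hold
#' segments (where no expiration occurs) does not produce spurious peaks.
#'
#' @param co2 a `co2_trace` (list with `samples`, `fs`, `t0`).
#' @param min_peak_separation_s minimum spacing between retained peaks.
#' @param min_prominence_mmHg minimum height of a peak above the lowest
#'   sample within half a separation window on either side (default 3 mmHg:
#'   well below any respiratory excursion, well above capnograph noise).
#' @return List with `time_s` and `value_mmHg` of the end-tidal points, in
#'   time order.
#' @export
end_tidal_detect <- function(co2, min_peak_separation_s = 2,
                             min_prominence_mmHg = 3) {
  x <- co2$samples
  n <- length(x)
  if (n < 3L) stop("CO2 trace too short for peak detection")
  # candidates are found on a lightly smoothed copy (0.25 s moving average,
  # edge-replicated) so sample-level measurement noise cannot masquerade as
  # expiratory peaks; reported values come from the raw samples
  w <- max(1L, round(0.25 * co2$fs))
  if (w %% 2L == 0L) w <- w + 1L # odd width: symmetric, no half-sample shift
  if (w > 1L) {
    k <- rep(1 / w, w)
    r <- w %/% 2L
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    xs <- as.numeric(stats::filter(xp, k, sides = 2))
    xs <- xs[!is.na(xs)][seq_len(n)]
  } else {
    xs <- x
  }
  cand <- which(diff(sign(diff(xs))) < 0) + 1L
  half <- max(1L, round(min_peak_separation_s * co2$fs / 2))
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      win <- max(1L, i - half):min(n, i + half)
      xs[i] - min(xs[win])
    }, numeric(1))
    cand <- cand[prom >= min_prominence_mmHg]
  }
  if (!length(cand)) {
    stop("no end-tidal peaks found; inspect the CO2 trace ",
         "(is it flat, or is the prominence threshold too high?)")
  }
  # greedy non-maximum suppression: keep the highest peaks subject to spacing
  keep <- integer(0)
  sep <- min_peak_separation_s * co2$fs
  for (i in cand[order(xs[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  list(time_s = co2$t0 + (keep - 1L) / co2$fs, value_mmHg = x[keep])
}

#' Interpolate end-tidal points to a fine uniform grid
#'
#' Piecewise-linear interpolation through the end-tidal points (in
#' particular, linearly across each breath-hold, between the last end-tidal
#' value before and the first after the hold), with constant extrapolation
#' at the ends, sampled on a `dt`-spaced grid covering `[0,
#' scan_duration_s]`.
#'
#' @param peaks result of [end_tidal_detect()].
#' @param scan_duration_s scan duration to cover (seconds).
#' @param dt grid step (default 0.1 s).
#' @return An `end_tidal_trace`: list with `time_s`, `petco2_mmHg`, `dt`.
#' @export
end_tidal_interpolate <- function(peaks, scan_duration_s, dt = 0.1) {
  if (length(peaks$time_s) < 2L) stop("need at least 2 end-tidal points to interpolate")
  grid <- seq(0, scan_duration_s, by = dt)
  y <- stats::approx(peaks$time_s, peaks$value_mmHg, xout = grid, rule = 2)$y
  structure(list(time_s = grid, petco2_mmHg = y, dt = dt),
            class = "end_tidal_trace")
}

#' Baseline end-tidal CO2
#'
#' The resting PETCO2 reference, defined as the median of the end-tidal
#' points recorded before the first breath-hold.
#'
#' @param peaks result of [end_tidal_detect()].
#' @param first_hold_start_s start time of the first breath-hold window.
#' @return Baseline PETCO2 in mmHg.
#' @export
baseline_petco2 <- function(peaks, first_hold_start_s) {
  pre <- peaks$value_mmHg[peaks$time_s < first_hold_start_s]
  if (!length(pre)) {
    warning("no end-tidal points before the first hold; using the median of all points")
    pre <- peaks$value_mmHg
  }
  stats::median(pre)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peaking at `peak_s`,
#' undershoot peaking at `undershoot_s`, undershoot-to-peak ratio `ratio`),
#' sampled at `dt` over `[0, length_s]` and normalised to unit peak
#' amplitude.
#'
#' @param dt sampling step (s).
#' @param peak_s,undershoot_s modes of the response and undershoot lobes.
#' @param ratio relative undershoot amplitude (default 1/6).
#' @param length_s kernel support (default 32 s).
#' @return Numeric kernel vector.
#' @export
double_gamma_hrf <- function(dt, peak_s = 6, undershoot_s = 16,
                             ratio = 1 / 6, length_s = 32) {
  if (dt <= 0) stop("`dt` must be positive")
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

# HRF-convolved end-tidal deviation from baseline, on the fine grid (mmHg).
co2_response_fine <- function(etco2, baseline_mmHg, hrf) {
  dev <- etco2$petco2_mmHg - baseline_mmHg
  full <- stats::convolve(dev, rev(hrf), type = "open")
  full[seq_along(dev)] * etco2$dt
}

#' Build a frame-sampled, delayed CO2 regressor
#'
#' Convolves the end-tidal deviation from baseline with the HRF on the fine
#' grid, applies a temporal delay (positive = later arrival of the CO2
#' bolus at the voxel), and samples at the BOLD frame times.
#'
#' @param etco2 an [end_tidal_interpolate()] trace.
#' @param hrf kernel from [double_gamma_hrf()] sampled at the same `dt`.
#' @param TR repetition time (s).
#' @param n_frames number of BOLD frames.
#' @param delay_s temporal shift (s), `|delay_s| <= 15`.
#' @param baseline_mmHg baseline PETCO2 subtracted before convolution.
#' @return Numeric regressor of length `n_frames` (units mmHg).
#' @export
build_regressor <- function(etco2, hrf, TR, n_frames, delay_s,
                            baseline_mmHg) {
  scan_dur <- (n_frames - 1) * TR
  if (abs(delay_s) >= scan_dur) {
    stop("`delay_s` shifts the regressor fully out of the scan window")
  }
  x <- co2_response_fine(etco2, baseline_mmHg, hrf)
  ft <- (seq_len(n_frames) - 1) * TR
  lin_interp(x, etco2$time_s[1], etco2$dt, ft - delay_s)
}

# Frame-sampled regressors for every delay on the grid: frames x delays.
regressor_bank <- function(etco2, hrf, TR, n_frames, delays, baseline_mmHg) {
  x <- co2_response_fine(etco2, baseline_mmHg, hrf)
  ft <- (seq_len(n_frames) - 1) * TR
  q <- outer(ft, delays, `-`)
  lin_interp(x, etco2$time_s[1], etco2$dt, q)
}

#' Fit CVR and CO2 delay for a single voxel
#'
#' For each candidate delay, the voxel signal is regressed (OLS, intercept
#' plus the delayed regressor, valid frames only) on the HRF-convolved
#' end-tidal trace; the delay maximising the voxel-regressor correlation is
#' selected (ties broken toward the smallest |delay|, negative first).
#' CVR is `100 * beta / intercept`: percent signal change per mmHg.
#'
#' @param voxel numeric voxel timeseries.
#' @param frame_valid logical per-frame validity flags.
#' @param regressors `n_frames x n_delays` matrix of delayed regressors
#'   (e.g. from the internal bank used by [compute_cvr_map()]).
#' @param delays_s the delay grid (seconds), one per regressor column.
#' @param min_valid_frames minimum valid frames for a fit (default 20).
#' @return List with `cvr`, `delay_s`, `fit_r`, `valid`.
#' @export
fit_cvr_voxel <- function(voxel, frame_valid, regressors, delays_s,
                          min_valid_frames = 20) {
  v <- which(frame_valid)
  if (length(v) < min_valid_frames) {
    return(list(cvr = NA_real_, delay_s = NA_real_, fit_r = NA_real_,
                valid = FALSE))
  }
  y <- voxel[v]
  if (stats::sd(y) == 0) {
    return(list(cvr = NA_real_, delay_s = NA_real_, fit_r = NA_real_,
                valid = FALSE))
  }
  ord <- order(abs(delays_s), delays_s)
  r <- suppressWarnings(stats::cor(regressors[v, ord, drop = FALSE], y))
  r[!is.finite(r)] <- -Inf
  best <- which.max(r) # first maximum in |delay| order: ties go toward 0
  j <- ord[best]
  g <- regressors[v, j]
  beta <- stats::cov(g, y) / stats::var(g)
  intercept <- mean(y) - beta * mean(g)
  fit_r <- r[best]
  list(cvr = 100 * beta / intercept, delay_s = delays_s[j],
       fit_r = fit_r, valid = is.finite(fit_r) && fit_r >= 0.1)
}

#' Compute a voxelwise CVR map with CO2 delay optimisation
#'
#' Per masked voxel, the CO2 regressor is systematically time-shifted over
#' `delay_range_s` in `delay_step_s` steps; the best-fit delay (maximum
#' voxel-regressor correlation, equivalently minimum residual sum of
#' squares) is kept and CVR computed from the GLM beta normalised by the
#' intercept baseline. Voxels whose best-fit correlation falls below
#' `r_min` display an abnormal breath-hold response and are flagged
#' invalid, as are zero-variance voxels; per-voxel failures never abort the
#' map.
#'
#' @param bold a [bold_series()] of the breath-hold run.
#' @param etco2 an [end_tidal_interpolate()] trace covering the scan.
#' @param baseline_mmHg baseline PETCO2 (see [baseline_petco2()]).
#' @param mask analysis mask (default the brain mask).
#' @param delay_range_s search window (default -15..+15 s).
#' @param delay_step_s search step (default 0.1 s).
#' @param r_min validity threshold on the model-fit correlation
#'   (default 0.1).
#' @param hrf optional HRF kernel; defaults to [double_gamma_hrf()] at the
#'   end-tidal grid step.
#' @param min_valid_frames minimum valid frames per voxel fit.
#' @param confounds optional `n_frames x K` matrix of the nuisance and
#'   drift regressors that were removed from the BOLD data during
#'   preprocessing (motion, CSF, [cosine_drift_basis()] columns). By the
#'   Frisch-Waugh theorem, projecting the same columns out of the CO2
#'   regressor makes the single-regressor fit equivalent to the joint GLM;
#'   omitting this when the data were residualised shrinks beta -- and
#'   hence CVR -- toward zero.
#'
#' @return A `cvr_map`: 3D arrays `cvr` (%BOLD/mmHg), `delay_s`, `fit_r`,
#'   logical `valid`, plus the `mask` and search parameters.
#' @export
compute_cvr_map <- function(bold, etco2, baseline_mmHg,
                            mask = bold$brain_mask,
                            delay_range_s = c(-15, 15), delay_step_s = 0.1,
                            r_min = 0.1, hrf = NULL, min_valid_frames = 20,
                            confounds = NULL) {
  dims <- dim(bold$data)[1:3]
  mask <- as_mask(mask, dims, "mask")
  if (is.null(hrf)) hrf <- double_gamma_hrf(etco2$dt)
  delays <- seq(delay_range_s[1], delay_range_s[2], by = delay_step_s)
  nt <- n_frames(bold)
  G <- regressor_bank(etco2, hrf, bold$TR, nt, delays, baseline_mmHg)

  v <- which(bold$frame_valid)
  Y <- bold_matrix(bold, mask)
  nv <- ncol(Y)
  if (length(v) < min_valid_frames) {
    stop("fewer than ", min_valid_frames, " valid frames; cannot fit CVR")
  }
  Yv <- Y[v, , drop = FALSE]
  Gv <- G[v, , drop = FALSE]
  if (!is.null(confounds) && ncol(confounds) > 0) {
    if (nrow(confounds) != nt) stop("`confounds` rows must match the frames")
    Gv <- qr.resid(qr(cbind(1, confounds[v, , drop = FALSE])), Gv)
  }

  # correlations of every voxel with every delayed regressor: delays x voxels
  gs <- scale(Gv)
  ys <- scale(Yv)
  R <- crossprod(gs, ys) / (length(v) - 1)
  R[!is.finite(R)] <- -Inf

  # argmax with ties broken toward the smallest |delay| (negative first)
  ord <- order(abs(delays), delays)
  best_ord <- max.col(t(R[ord, , drop = FALSE]), ties.method = "first")
  j <- ord[best_ord]
  fit_r <- R[cbind(j, seq_len(nv))]

  cvr <- rep(NA_real_, nv)
  delay <- rep(NA_real_, nv)
  ymean <- colMeans(Yv)
  ysd <- apply(Yv, 2, stats::sd)
  fittable <- is.finite(fit_r) & ysd > 0
  for (jj in unique(j[fittable])) {
    sel <- which(fittable & j == jj)
    g <- Gv[, jj]
    gc <- g - mean(g)
    beta <- as.vector(crossprod(gc, Yv[, sel, drop = FALSE])) / sum(gc^2)
    intercept <- ymean[sel] - beta * mean(g)
    cvr[sel] <- 100 * beta / intercept
    delay[sel] <- delays[jj]
  }
  vox_valid <- fittable & fit_r >= r_min
  fit_r[!is.finite(fit_r)] <- NA_real_

  structure(
    list(cvr = vec_to_vol(ifelse(vox_valid, cvr, NA_real_), mask),
         delay_s = vec_to_vol(ifelse(vox_valid, delay, NA_real_), mask),
         fit_r = vec_to_vol(fit_r, mask),
         valid = vec_to_vol(vox_valid, mask, fill = FALSE) == 1,
         mask = mask, delays_s = delays, r_min = r_min),
    class = "cvr_map"
  )
}

#' @export
print.cvr_map <- function(x, ...) {
  cat(sprintf("<cvr_map> %d valid voxels (of %d in mask); delay grid %g..%g s\n",
              sum(x$valid), sum(x$mask), min(x$delays_s), max(x$delays_s)))
  if (any(x$valid)) {
    cat(sprintf("  CVR median %.3f %%BOLD/mmHg; delay median %.1f s\n",
                stats::median(x$cvr[x$valid]), stats::median(x$delay_s[x$valid])))
  }
  invisible(x)
}

#' End-to-end CVR map from a raw CO2 trace
#'
#' Convenience wrapper: detects end-tidal points, interpolates them,
#' derives the baseline PETCO2 from the pre-first-hold points, and runs
#' [compute_cvr_map()].
#'
#' @param bold breath-hold [bold_series()].
#' @param co2 raw `co2_trace`.
#' @param paradigm the breath-hold [make_paradigm()] timing.
#' @param ... passed on to [compute_cvr_map()].
#' @return A `cvr_map`.
#' @export
cvr_from_co2 <- function(bold, co2, paradigm, ...) {
  dur <- (n_frames(bold) - 1) * bold$TR
  peaks <- end_tidal_detect(co2)
  etco2 <- end_tidal_interpolate(peaks, scan_duration_s = dur)
  base <- baseline_petco2(peaks, paradigm$hold_windows[1, "start"])
  compute_cvr_map(bold, etco2, baseline_mmHg = base, ...)
}
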