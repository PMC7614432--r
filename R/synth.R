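# Synthetic phantom generation: anatomy, ground truth, CO2 traces, motion
# traces, and resting-state / breath-hold BOLD series with known parameters.
# Every downstream stage of the pipeline is validated against these phantoms.

#' Breath-hold paradigm timing
#'
#' Defines the cyclic breath-hold task: each cycle is a period of normal
#' breathing, a period of paced breathing, and an end-expiration breath-hold,
#' optionally preceded by a lead-in of free breathing. The default protocol
#' (six cycles of 14 s normal + 16 s paced + 15 s hold) produces transient
#' hypercapnia after every hold, the stimulus used for CVR mapping.
#'
#' @param n_cycles number of breath-hold cycles (>= 1).
#' @param normal_s,paced_s,hold_s durations (seconds, > 0) of the normal
#'   breathing, paced breathing and breath-hold phases of each cycle.
#' @param lead_in_s free-breathing lead-in before the first cycle (seconds,
#'   >= 0).
#' @param tail_s return-to-normal-breathing period after the last hold
#'   (seconds, >= 0); the post-hold hypercapnic peak falls in this window.
#'
#' @return A `bh_paradigm` object with the cycle period, total duration and a
#'   `n_cycles x 2` matrix `hold_windows` of `[start, end)` hold times.
#' @export
#' @examples
#' p <- make_paradigm()
#' p$hold_windows
make_paradigm <- function(n_cycles = 6, normal_s = 14, paced_s = 16,
                          hold_s = 15, lead_in_s = 10, tail_s = 20) {
  if (any(c(normal_s, paced_s, hold_s) <= 0)) {
    stop("phase durations must all be positive")
  }
  if (lead_in_s < 0 || tail_s < 0) stop("lead-in and tail must be non-negative")
  if (n_cycles < 1) stop("`n_cycles` must be at least 1")
  period <- normal_s + paced_s + hold_s
  starts <- lead_in_s + (seq_len(n_cycles) - 1) * period + normal_s + paced_s
  structure(
    list(n_cycles = as.integer(n_cycles), normal_s = normal_s,
         paced_s = paced_s, hold_s = hold_s, lead_in_s = lead_in_s,
         tail_s = tail_s, cycle_period_s = period,
         duration_s = lead_in_s + n_cycles * period + tail_s,
         hold_windows = cbind(start = starts, end = starts + hold_s)),
    class = "bh_paradigm"
  )
}

#' Simulate a capnograph (CO2) trace for a breath-hold session
#'
#' Produces a raw CO2 trace oscillating at the respiratory rate between a
#' trough and an end-tidal envelope. The envelope sits at `baseline_mmHg`
#' during free breathing; in the first expiration after each breath-hold it
#' rises by `hold_rise_mmHg` (the hypercapnic stimulus) and then relaxes back
#' to baseline with a 10 s time constant. During the hold itself the trace is
#' flat (no expiration, hence no end-tidal peaks).
#'
#' @param paradigm a [make_paradigm()] object.
#' @param fs sampling rate in Hz; must exceed twice the respiratory rate.
#' @param baseline_mmHg resting end-tidal CO2 (mmHg).
#' @param hold_rise_mmHg end-tidal rise in the first post-hold expiration.
#' @param resp_rate_hz respiratory rate (breaths per second).
#' @param trough_mmHg inspiratory trough of the oscillation.
#' @param noise_sd additive Gaussian measurement noise (mmHg).
#' @param seed integer RNG seed; identical seeds give identical traces.
#'
#' @return A `co2_trace`: list with `samples` (mmHg), `fs` (Hz) and `t0`
#'   (offset of the first sample relative to the first BOLD frame, seconds).
#' @export
simulate_co2_trace <- function(paradigm, fs = 200, baseline_mmHg = 40,
                               hold_rise_mmHg = 8, resp_rate_hz = 0.25,
                               trough_mmHg = baseline_mmHg - 8,
                               noise_sd = 0.3, seed = 1) {
  if (fs <= 2 * resp_rate_hz) {
    stop("`fs` must exceed twice the respiratory rate (aliasing)")
  }
  dur <- paradigm$duration_s
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  hw <- paradigm$hold_windows
  # breathing restarts from end-expiration after each hold, so the
  # oscillation phase is referenced to the start of each breathing segment;
  # the first expiratory peak of a segment falls half a period after it
  seg_start <- c(0, hw[, "end"])
  seg_end <- c(hw[, "start"], dur)
  osc <- numeric(n)
  for (j in seq_along(seg_start)) {
    in_seg <- t >= seg_start[j] & t < seg_end[j]
    osc[in_seg] <- 0.5 * (1 - cos(2 * pi * resp_rate_hz * (t[in_seg] - seg_start[j])))
  }

  env <- rep(baseline_mmHg, n)
  tau <- 10 # post-hold relaxation time constant (s)
  for (j in seq_len(nrow(hw))) {
    hold_end <- hw[j, "end"]
    this_end <- if (j < nrow(hw)) hw[j + 1, "start"] else dur
    p <- hold_end + 0.5 / resp_rate_hz # first expiration after the hold
    in_seg <- t >= hold_end & t < this_end
    env[in_seg & t <= p] <- baseline_mmHg + hold_rise_mmHg
    decay <- in_seg & t > p
    env[decay] <- baseline_mmHg + hold_rise_mmHg * exp(-(t[decay] - p) / tau)
  }

  x <- trough_mmHg + (env - trough_mmHg) * osc
  in_hold <- rep(FALSE, n)
  for (j in seq_len(nrow(hw))) {
    in_hold <- in_hold | (t >= hw[j, "start"] & t < hw[j, "end"])
  }
  x[in_hold] <- trough_mmHg # end-expiration hold: flat trace
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  structure(list(samples = x, fs = fs, t0 = 0), class = "co2_trace")
}

#' Construct phantom anatomy masks
#'
#' Builds a left/right-symmetric ellipsoidal "brain" on a voxel grid, with a
#' central CSF compartment (disjoint from grey matter), hemisphere masks that
#' partition the brain about the central sagittal plane (first axis), and a
#' spherical lesion confined to the left hemisphere.
#'
#' @param shape integer length-3 voxel counts per axis.
#' @param voxel_size_mm voxel edge lengths (mm) per axis.
#' @param lesion_centre voxel index (length-3) of the lesion centre.
#' @param lesion_radius_mm lesion radius in mm; voxels whose centre lies
#'   within this distance of the lesion centre (and inside the brain) are
#'   lesioned. Radius 0 gives a single-voxel lesion.
#'
#' @return A `phantom_anatomy` with logical volumes `brain`, `gm_mask`,
#'   `csf_mask`, `lesion_mask`, `left_hemi_mask`, `right_hemi_mask`, plus
#'   `voxel_size_mm` and the sagittal `midline_index` (may be half-integer).
#' @export
make_phantom_anatomy <- function(shape = c(20, 20, 10), voxel_size_mm = c(2, 2, 2),
                                 lesion_centre = c(5, 10, 5),
                                 lesion_radius_mm = 6) {
  stopifnot(length(shape) == 3L, all(shape >= 4), length(voxel_size_mm) == 3L)
  nx <- shape[1]
  ctr <- (shape + 1) / 2
  ix <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  iz <- slice.index(array(0, shape), 3)

  ell <- function(semi) {
    ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
      ((iz - ctr[3]) / semi[3])^2 <= 1
  }
  brain <- ell(0.48 * shape)
  csf <- ell(0.15 * shape)
  gm <- brain & !csf

  midline <- (nx + 1) / 2
  left <- brain & (ix < midline)
  right <- brain & (ix > midline)

  d2 <- ((ix - lesion_centre[1]) * voxel_size_mm[1])^2 +
    ((iy - lesion_centre[2]) * voxel_size_mm[2])^2 +
    ((iz - lesion_centre[3]) * voxel_size_mm[3])^2
  lesion <- brain & (d2 <= lesion_radius_mm^2 + 1e-9)
  if (!brain[lesion_centre[1], lesion_centre[2], lesion_centre[3]]) {
    stop("lesion centre lies outside the brain")
  }
  lesion[lesion_centre[1], lesion_centre[2], lesion_centre[3]] <- TRUE
  if (any(lesion & !left)) {
    stop("lesion crosses the sagittal midline; it must fit inside the left hemisphere")
  }
  structure(
    list(brain = brain, gm_mask = gm, csf_mask = csf, lesion_mask = lesion,
         left_hemi_mask = left, right_hemi_mask = right,
         voxel_size_mm = as.numeric(voxel_size_mm), midline_index = midline,
         shape = as.integer(shape)),
    class = "phantom_anatomy"
  )
}

#' Ground-truth parameter fields for phantom simulation
#'
#' Generates the latent voxelwise fields whose estimates the pipeline
#' produces: haemodynamic lag `lag_field` (s), CVR `cvr_field` (%BOLD/mmHg),
#' CO2 arrival delay `delay_field` (s), fluctuation coupling
#' `amplitude_field`, and baseline signal `baseline_field`. Default fields
#' are spatially smooth Gaussian random fields at physiologically plausible
#' scales (lags of order 1 s, CVR ~0.25 %BOLD/mmHg, delays of a few
#' seconds). Lesioned voxels are, by default, a signal void: zero coupling
#' and zero CVR.
#'
#' @param anatomy a [make_phantom_anatomy()] object.
#' @param lag_field,cvr_field,delay_field,amplitude_field,baseline_field
#'   optional explicit 3D fields overriding the generated defaults; scalars
#'   are recycled over the grid.
#' @param lag_sd_s,lag_max_s spread (SD) and clamp of the default lag field.
#' @param cvr_mean,cvr_sd mean and spread of the default CVR field.
#' @param delay_sd_s,delay_max_s spread and clamp of the default delay field.
#' @param amplitude fractional BOLD fluctuation amplitude (unitless).
#' @param baseline raw-unit baseline signal (> 0).
#' @param target_snr per-voxel temporal SNR (fluctuation SD / noise SD) used
#'   to derive `noise_sd` when the latter is not given.
#' @param noise_sd white-noise SD in raw units; overrides `target_snr`.
#' @param lesion_void if `TRUE`, lesion voxels get amplitude 0 and CVR 0.
#' @param seed integer RNG seed.
#'
#' @return A `ground_truth` object holding the five fields, `noise_sd` and
#'   `seed`.
#' @export
make_ground_truth <- function(anatomy,
                              lag_field = NULL, cvr_field = NULL,
                              delay_field = NULL, amplitude_field = NULL,
                              baseline_field = NULL,
                              lag_sd_s = 1.2, lag_max_s = 4,
                              cvr_mean = 0.25, cvr_sd = 0.08,
                              delay_sd_s = 2, delay_max_s = 6,
                              amplitude = 0.01, baseline = 1000,
                              target_snr = 3, noise_sd = NULL,
                              lesion_void = TRUE, seed = 1) {
  dims <- anatomy$shape
  expand <- function(x, default) {
    if (is.null(x)) return(default())
    if (length(x) == 1L) return(array(x, dim = dims))
    as_mask_dims <- dim(x)
    if (is.null(as_mask_dims) || !all(as_mask_dims == dims)) {
      stop("explicit fields must be scalars or arrays on the anatomy grid")
    }
    x
  }
  fields <- with_seed(seed, {
    rf <- function() {
      f <- smooth3d(array(stats::rnorm(prod(dims)), dim = dims), sigma_vox = 1.5)
      f / stats::sd(f)
    }
    list(
      # lag is a latency relative to the grey-matter mean signal, so the
      # generated field is centred on zero over grey matter
      lag = expand(lag_field, function() {
        f <- pmin(pmax(rf() * lag_sd_s, -lag_max_s), lag_max_s)
        pmin(pmax(f - mean(f[anatomy$gm_mask & !anatomy$lesion_mask]), -lag_max_s), lag_max_s)
      }),
      cvr = expand(cvr_field, function() pmax(cvr_mean + rf() * cvr_sd, 0.05)),
      delay = expand(delay_field, function() pmin(pmax(rf() * delay_sd_s, -delay_max_s), delay_max_s)),
      amp = expand(amplitude_field, function() array(amplitude, dim = dims)),
      base = expand(baseline_field, function() array(baseline, dim = dims))
    )
  })
  if (lesion_void) {
    fields$amp[anatomy$lesion_mask] <- 0
    fields$cvr[anatomy$lesion_mask] <- 0
  }
  if (any(abs(fields$lag) > 8)) stop("|lag_field| must not exceed 8 s")
  if (any(abs(fields$delay) > 15)) stop("delay_field must lie within [-15, 15] s")
  if (any(fields$base <= 0)) stop("baseline_field must be positive")
  if (is.null(noise_sd)) {
    mean_sig <- mean((fields$base * fields$amp)[anatomy$gm_mask & fields$amp > 0])
    noise_sd <- if (is.finite(mean_sig) && mean_sig > 0) mean_sig / target_snr else 0
  }
  structure(
    list(lag_field = fields$lag, cvr_field = fields$cvr,
         delay_field = fields$delay, amplitude_field = fields$amp,
         baseline_field = fields$base, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

# Shared fine-grid machinery: the resting-state signal (and CSF confound) are
# generated at dt = 0.1 s so fractional-second lags are representable before
# resampling to TR.
FINE_DT <- 0.1

# Sample a fine-grid signal at frame times minus a per-voxel shift.
# Returns a frames x voxels matrix. `t_fine0` is the time of fine sample 1.
sample_shifted <- function(s_fine, t_fine0, frame_t, shift_per_voxel) {
  q <- outer(frame_t, shift_per_voxel, `-`)
  lin_interp(s_fine, t_fine0, FINE_DT, q)
}

#' Simulate a resting-state BOLD phantom
#'
#' Forward model: every brain voxel carries a shared, band-limited
#' (0.01-0.1 Hz) zero-mean unit-variance signal `s`, time-shifted by its
#' ground-truth lag, scaled by its coupling amplitude and baseline, plus
#' white noise: `S_v(t) = B_v (1 + a_v s(t - lag_v)) + noise`. The shared
#' signal is generated on a 0.1 s grid so fractional lags are honoured before
#' resampling to TR. CSF voxels carry an independent band-limited confound
#' instead of `s`.
#'
#' @param anatomy a [make_phantom_anatomy()] object.
#' @param truth a [make_ground_truth()] object on the same grid.
#' @param TR repetition time (s).
#' @param n_frames number of frames; must be at least `2 * max_shift + 1`
#'   frames so the downstream lag search is feasible.
#' @param max_shift_frames search half-width used for the feasibility check.
#'
#' @return A [bold_series()] with all frames valid.
#' @export
simulate_rest_bold <- function(anatomy, truth, TR = 2, n_frames = 150,
                               max_shift_frames = 4) {
  if (n_frames < 2 * max_shift_frames + 1) {
    stop("`n_frames` must be at least ", 2 * max_shift_frames + 1,
         " for a +/-", max_shift_frames, "-frame lag search")
  }
  dur <- (n_frames - 1) * TR
  pad <- 10 # covers |lag| <= 8 s plus interpolation margin
  t0 <- -pad
  nf <- ceiling((dur + 2 * pad) / FINE_DT) + 1

  with_seed(truth$seed, {
    s <- band_limited_signal(nf, FINE_DT)
    csf_sig <- band_limited_signal(nf, FINE_DT)
    ft <- (seq_len(n_frames) - 1) * TR

    dims <- anatomy$shape
    data <- array(0, dim = c(dims, n_frames))
    flat <- matrix(0, nrow = prod(dims), ncol = n_frames)

    tissue <- anatomy$brain & !anatomy$csf_mask
    lagv <- truth$lag_field[tissue]
    ampv <- truth$amplitude_field[tissue]
    basev <- truth$baseline_field[tissue]
    sv <- sample_shifted(s, t0, ft, lagv) # frames x voxels
    flat[as.vector(tissue), ] <- basev * (1 + t(sv) * ampv)

    if (any(anatomy$csf_mask)) {
      csfv <- which(as.vector(anatomy$csf_mask))
      cb <- truth$baseline_field[anatomy$csf_mask]
      ca <- truth$amplitude_field[anatomy$csf_mask]
      ct <- lin_interp(csf_sig, t0, FINE_DT, ft)
      flat[csfv, ] <- cb * (1 + outer(ca, ct))
    }

    if (truth$noise_sd > 0) {
      bvox <- as.vector(anatomy$brain)
      flat[bvox, ] <- flat[bvox, ] +
        stats::rnorm(sum(bvox) * n_frames, 0, truth$noise_sd)
    }
    data[] <- array(flat, dim = c(dims, n_frames))
    bold_series(data, TR, brain_mask = anatomy$brain,
                voxel_size_mm = anatomy$voxel_size_mm)
  })
}

#' Simulate a breath-hold BOLD phantom
#'
#' Forward model: on top of the resting-state model of
#' [simulate_rest_bold()], each voxel carries a CVR response to the
#' HRF-convolved end-tidal CO2 deviation `x(t)` (mmHg), delayed by its CO2
#' arrival delay: `S_v(t) = B_v (1 + (CVR_v/100) x(t - delay_v) +
#' a_v s(t - lag_v)) + noise`. The regressor `x` is built with the same
#' operators the CVR estimator uses (end-tidal peak detection, linear
#' interpolation, double-gamma convolution) on the 0.1 s grid.
#'
#' @inheritParams simulate_rest_bold
#' @param co2 a `co2_trace` covering the full scan duration.
#' @param paradigm the [make_paradigm()] object that produced `co2`.
#' @return A [bold_series()] with all frames valid.
#' @export
simulate_bh_bold <- function(anatomy, truth, co2, paradigm, TR = 2,
                             n_frames = 150, max_shift_frames = 4) {
  if (n_frames < 2 * max_shift_frames + 1) {
    stop("`n_frames` must be at least ", 2 * max_shift_frames + 1,
         " for a +/-", max_shift_frames, "-frame lag search")
  }
  dur <- (n_frames - 1) * TR
  if (length(co2$samples) / co2$fs < dur) {
    stop("CO2 trace (", round(length(co2$samples) / co2$fs), " s) does not cover the scan (",
         dur, " s)")
  }
  peaks <- end_tidal_detect(co2)
  etco2 <- end_tidal_interpolate(peaks, scan_duration_s = dur)
  base_pet <- baseline_petco2(peaks, first_hold_start_s = paradigm$hold_windows[1, "start"])
  hrf <- double_gamma_hrf(FINE_DT)
  x_fine <- co2_response_fine(etco2, base_pet, hrf)

  pad <- 10
  t0 <- -pad
  nf <- ceiling((dur + 2 * pad) / FINE_DT) + 1

  with_seed(truth$seed, {
    s <- band_limited_signal(nf, FINE_DT)
    csf_sig <- band_limited_signal(nf, FINE_DT)
    ft <- (seq_len(n_frames) - 1) * TR

    dims <- anatomy$shape
    flat <- matrix(0, nrow = prod(dims), ncol = n_frames)

    tissue <- anatomy$brain & !anatomy$csf_mask
    lagv <- truth$lag_field[tissue]
    ampv <- truth$amplitude_field[tissue]
    basev <- truth$baseline_field[tissue]
    cvrv <- truth$cvr_field[tissue]
    delv <- truth$delay_field[tissue]
    sv <- sample_shifted(s, t0, ft, lagv)
    # x is defined on [0, dur]; earlier times carry the (zero) baseline deviation
    xv <- sample_shifted(x_fine, etco2$time_s[1], ft, delv)
    flat[as.vector(tissue), ] <-
      basev * (1 + t(xv) * (cvrv / 100) + t(sv) * ampv)

    if (any(anatomy$csf_mask)) {
      csfv <- which(as.vector(anatomy$csf_mask))
      cb <- truth$baseline_field[anatomy$csf_mask]
      ca <- truth$amplitude_field[anatomy$csf_mask]
      ct <- lin_interp(csf_sig, t0, FINE_DT, ft)
      flat[csfv, ] <- cb * (1 + outer(ca, ct))
    }
    if (truth$noise_sd > 0) {
      bvox <- as.vector(anatomy$brain)
      flat[bvox, ] <- flat[bvox, ] +
        stats::rnorm(sum(bvox) * n_frames, 0, truth$noise_sd)
    }
    data <- array(flat, dim = c(dims, n_frames))
    bold_series(data, TR, brain_mask = anatomy$brain,
                voxel_size_mm = anatomy$voxel_size_mm)
  })
}

#' Simulate rigid-body motion parameters
#'
#' Smooth, small-amplitude head motion (cubic-spline interpolated Gaussian
#' knots every 10 frames) in six rigid-body parameters, with an optional
#' translation step of `outlier_magnitude_mm` injected at listed frames so
#' framewise displacement spikes there.
#'
#' @param n_frames number of frames.
#' @param outlier_frames integer frame indices (> 1) receiving a step.
#' @param outlier_magnitude_mm size of the injected translation step (mm).
#' @param amplitude_mm,amplitude_rad SD of the smooth translation (mm) and
#'   rotation (radians) components; 0 gives identically zero motion.
#' @param seed integer RNG seed.
#'
#' @return An `n_frames x 6` matrix with columns `tx, ty, tz` (mm) and
#'   `rx, ry, rz` (radians).
#' @export
simulate_motion_params <- function(n_frames, outlier_frames = integer(0),
                                   outlier_magnitude_mm = 1.5,
                                   amplitude_mm = 0.05, amplitude_rad = 5e-4,
                                   seed = 1) {
  if (length(outlier_frames) && any(outlier_frames > n_frames)) {
    stop("`outlier_frames` must be <= n_frames")
  }
  m <- with_seed(seed, {
    knots <- unique(c(seq(1, n_frames, by = 10), n_frames))
    smooth_col <- function(amp) {
      if (amp == 0 || length(knots) < 2) return(rep(0, n_frames))
      stats::spline(knots, stats::rnorm(length(knots), 0, amp),
                    xout = seq_len(n_frames))$y
    }
    cbind(tx = smooth_col(amplitude_mm), ty = smooth_col(amplitude_mm),
          tz = smooth_col(amplitude_mm), rx = smooth_col(amplitude_rad),
          ry = smooth_col(amplitude_rad), rz = smooth_col(amplitude_rad))
  })
  for (f in outlier_frames) {
    m[f:n_frames, "tx"] <- m[f:n_frames, "tx"] + outlier_magnitude_mm
  }
  m
}
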