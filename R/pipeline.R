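# End-to-end orchestration: a run configuration carrying the protocol
# constants, single-subject processing (QC -> nuisance removal -> lag map /
# CVR map -> ROIs -> subject statistics) and group-level analysis.

#' Run configuration with protocol defaults
#'
#' Collects every tunable constant of the pipeline. The defaults are the
#' protocol values used throughout: 1 mm FD threshold, 50% scan-exclusion
#' rule, r >= 0.1 validity for both lag and CVR, a +/-4-frame (+/-8 s at TR
#' 2 s) lag search, a -15..+15 s by 0.1 s CO2 delay search, a 10 mm
#' perilesional radius, FDR q = 0.1 and a 0.05 family alpha Bonferroni-split
#' over 6 ROIs.
#'
#' @param TR repetition time (s).
#' @param fd_threshold_mm framewise-displacement exclusion threshold.
#' @param max_invalid_fraction scan-level exclusion fraction.
#' @param r_min_lag,r_min_cvr voxel validity thresholds.
#' @param max_shift_frames lag search half-width (frames).
#' @param delay_range_s,delay_step_s CO2 delay search grid.
#' @param roi_radius_mm perilesional shell radius.
#' @param fdr_q FDR level for voxelwise group maps.
#' @param family_alpha,n_rois family-wise alpha and ROI count for the
#'   Bonferroni-corrected Wilcoxon tests.
#' @param highpass_hz high-pass cutoff.
#' @param seed integer seed recorded for provenance.
#' @return A `run_config` list.
#' @export
run_config <- function(TR = 2, fd_threshold_mm = 1, max_invalid_fraction = 0.5,
                       r_min_lag = 0.1, r_min_cvr = 0.1, max_shift_frames = 4,
                       delay_range_s = c(-15, 15), delay_step_s = 0.1,
                       roi_radius_mm = 10, fdr_q = 0.1, family_alpha = 0.05,
                       n_rois = 6L, highpass_hz = 0.01, seed = 1L) {
  cfg <- list(TR = TR, fd_threshold_mm = fd_threshold_mm,
              max_invalid_fraction = max_invalid_fraction,
              r_min_lag = r_min_lag, r_min_cvr = r_min_cvr,
              max_shift_frames = max_shift_frames,
              delay_range_s = delay_range_s, delay_step_s = delay_step_s,
              roi_radius_mm = roi_radius_mm, fdr_q = fdr_q,
              family_alpha = family_alpha, n_rois = as.integer(n_rois),
              highpass_hz = highpass_hz, seed = as.integer(seed))
  stopifnot(cfg$TR > 0, cfg$fd_threshold_mm > 0, cfg$delay_step_s > 0,
            cfg$delay_range_s[1] < cfg$delay_range_s[2])
  structure(cfg, class = "run_config")
}

#' Simulate one complete phantom subject
#'
#' Builds the anatomy, ground-truth fields, motion traces, breath-hold CO2
#' trace, and the resting-state and breath-hold BOLD runs for one subject,
#' with all randomness governed by `seed`.
#'
#' @param seed integer seed for this subject.
#' @param anatomy optional [make_phantom_anatomy()]; built with defaults if
#'   missing.
#' @param paradigm optional [make_paradigm()].
#' @param TR,n_frames acquisition parameters.
#' @param ... passed to [make_ground_truth()] (e.g. `noise_sd = 0`).
#' @return List with `anatomy`, `truth`, `paradigm`, `co2`, `rest`, `bh`,
#'   `motion_rest`, `motion_bh`.
#' @export
simulate_subject <- function(seed = 1, anatomy = NULL, paradigm = NULL,
                             TR = 2, n_frames = 150, ...) {
  if (is.null(anatomy)) anatomy <- make_phantom_anatomy()
  dur <- n_frames * TR
  if (is.null(paradigm)) {
    # fit as many standard cycles as the scan allows
    cyc <- max(1, floor((dur - 10) / 45))
    paradigm <- make_paradigm(n_cycles = cyc)
  }
  truth <- make_ground_truth(anatomy, seed = seed, ...)
  co2 <- simulate_co2_trace(paradigm, seed = seed + 1003L)
  rest <- simulate_rest_bold(anatomy, truth, TR = TR, n_frames = n_frames)
  truth_bh <- truth
  truth_bh$seed <- truth$seed + 211L
  # the breath-hold run can only be as long as the task it records
  n_frames_bh <- min(n_frames, floor(paradigm$duration_s / TR) + 1)
  bh <- simulate_bh_bold(anatomy, truth_bh, co2, paradigm, TR = TR,
                         n_frames = n_frames_bh)
  motion_rest <- simulate_motion_params(n_frames, seed = seed + 17L)
  motion_bh <- simulate_motion_params(n_frames_bh, seed = seed + 31L)
  list(anatomy = anatomy, truth = truth, paradigm = paradigm, co2 = co2,
       rest = rest, bh = bh, motion_rest = motion_rest, motion_bh = motion_bh)
}

# QC + nuisance removal for one run; returns the cleaned bold, QC info and
# the full confound matrix removed from the data (needed so model
# regressors can be residualised against the identical space).
clean_run <- function(bold, motion, csf_mask, config) {
  fd <- framewise_displacement(motion)
  fv <- flag_motion_outliers(fd, config$fd_threshold_mm)
  decision <- scan_exclusion_check(fv, config$max_invalid_fraction)
  bold$frame_valid <- bold$frame_valid & fv
  csf_tc <- mask_mean_timecourse(bold, csf_mask)
  nuisance <- cbind(motion, csf = csf_tc)
  bold <- regress_nuisance(bold, nuisance)
  bold <- highpass_filter(bold, config$highpass_hz)
  drift <- cosine_drift_basis(n_frames(bold), bold$TR, config$highpass_hz)
  list(bold = bold, fd = fd, decision = decision,
       confounds = cbind(nuisance, drift))
}

#' Process one subject end to end
#'
#' Runs frame-level QC and nuisance removal on both runs, computes the
#' resting-state and breath-hold lag maps against the grey-matter reference
#' (lesion excluded), the CVR map from the breath-hold run and CO2 trace,
#' builds the six-compartment ROI set, and derives the subject-level
#' statistics: per-ROI Spearman correlation of lag and CVR, hemisphere mean
#' lags, and the cross-condition spatial correlation of the two lag maps.
#'
#' @param subject list as returned by [simulate_subject()] (fields
#'   `rest`, `bh`, `co2`, `paradigm`, `motion_rest`, `motion_bh`,
#'   `anatomy`).
#' @param config a [run_config()].
#' @param out_dir optional directory; maps, masks and a JSON sidecar of the
#'   configuration are written there.
#' @return A result bundle (lag maps, CVR map, ROI set, QC, statistics).
#' @export
run_subject <- function(subject, config = run_config(), out_dir = NULL) {
  an <- subject$anatomy
  qc_rest <- clean_run(subject$rest, subject$motion_rest, an$csf_mask, config)
  qc_bh <- clean_run(subject$bh, subject$motion_bh, an$csf_mask, config)
  if (!qc_rest$decision$keep || !qc_bh$decision$keep) {
    warning("scan fails the motion exclusion rule (>",
            100 * config$max_invalid_fraction, "% invalid frames)")
  }

  gm <- an$gm_mask
  lag_of <- function(qc) {
    ref <- reference_timeseries(qc$bold, gm, an$lesion_mask)
    compute_lag_map(qc$bold, ref, mask = gm, r_min = config$r_min_lag,
                    max_shift_frames = config$max_shift_frames)
  }
  lag_rest <- lag_of(qc_rest)
  lag_bh <- lag_of(qc_bh)

  # the breath-hold run was residualised against motion, CSF and drift, so
  # the CO2 regressor must have the identical space projected out
  cvr <- cvr_from_co2(qc_bh$bold, subject$co2, subject$paradigm, mask = gm,
                      delay_range_s = config$delay_range_s,
                      delay_step_s = config$delay_step_s,
                      r_min = config$r_min_cvr, confounds = qc_bh$confounds)

  rois <- build_roi_set(an$lesion_mask, gm, an$left_hemi_mask,
                        an$right_hemi_mask, an$voxel_size_mm,
                        an$midline_index, config$roi_radius_mm)

  roi_corr <- lapply(roi_labels, function(l) {
    res <- roi_spearman(lag_bh, cvr, rois[[l]])
    c(list(roi = l), res)
  })
  names(roi_corr) <- roi_labels

  result <- list(
    lag_rest = lag_rest, lag_bh = lag_bh, cvr = cvr, rois = rois,
    qc = list(rest = qc_rest[c("fd", "decision")],
              bh = qc_bh[c("fd", "decision")]),
    roi_spearman = roi_corr,
    mean_lag_left_rest = hemisphere_mean_lag(lag_rest, an$left_hemi_mask),
    mean_lag_left_bh = hemisphere_mean_lag(lag_bh, an$left_hemi_mask),
    cross_condition_r = spatial_pearson(lag_rest, lag_bh),
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_map(lag_rest, file.path(out_dir, "lag_rest"), an$voxel_size_mm)
    write_map(lag_bh, file.path(out_dir, "lag_bh"), an$voxel_size_mm)
    write_map(cvr, file.path(out_dir, "cvr"), an$voxel_size_mm)
    for (l in roi_labels) {
      write_nifti_vol(rois[[l]], file.path(out_dir, paste0("roi_", l, ".nii.gz")),
                      an$voxel_size_mm)
    }
    jsonlite::write_json(
      list(config = unclass(config), package_version = as.character(utils::packageVersion("lagcvr"))),
      file.path(out_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Group-level analysis over subject bundles
#'
#' Runs the voxelwise two-factor (group x timepoint) OLS ANOVA with FDR
#' control on the chosen condition's lag maps, the per-ROI group Wilcoxon
#' signed-rank tests of the subject-level lag-CVR Spearman coefficients
#' against zero (Bonferroni-corrected alpha), and summarises the
#' cross-condition spatial correlations.
#'
#' @param results list of [run_subject()] bundles.
#' @param group,timepoint design labels, one per bundle (>= 2 subjects per
#'   cell).
#' @param condition which lag maps enter the ANOVA (`"rest"` or `"bh"`).
#' @param config a [run_config()].
#' @return List with `anova`, `roi_tests` (per-ROI r values, Wilcoxon p,
#'   significance), and `cross_condition` (per-subject r, one-sample t).
#' @export
run_group <- function(results, group, timepoint, condition = c("rest", "bh"),
                      config = run_config()) {
  condition <- match.arg(condition)
  maps <- lapply(results, function(r) if (condition == "rest") r$lag_rest else r$lag_bh)
  anova <- voxelwise_group_anova(maps, group, timepoint, q = config$fdr_q)

  alpha <- bonferroni_alpha(config$family_alpha, config$n_rois)
  roi_tests <- lapply(roi_labels, function(l) {
    r <- vapply(results, function(x) {
      v <- x$roi_spearman[[l]]
      if (isTRUE(v$ok)) v$r else NA_real_
    }, numeric(1))
    wt <- group_wilcoxon_vs_zero(r[!is.na(r)], alpha = alpha)
    list(roi = l, r = r, mean_r = mean(r, na.rm = TRUE),
         p = wt$p, significant = wt$significant, n = wt$n)
  })
  names(roi_tests) <- roi_labels

  cc_r <- vapply(results, function(x) x$cross_condition_r$r, numeric(1))
  cc <- cc_r[!is.na(cc_r)]
  cc_test <- if (length(cc) >= 3 && stats::sd(cc) > 0) {
    ht <- stats::t.test(cc, mu = 0)
    list(mean_r = mean(cc), t = unname(ht$statistic), p = ht$p.value)
  } else {
    list(mean_r = mean(cc), t = NA_real_, p = NA_real_)
  }
  list(anova = anova, roi_tests = roi_tests,
       cross_condition = c(list(r = cc_r), cc_test),
       alpha = alpha, config = config)
}
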