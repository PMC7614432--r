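# Frame-level quality control and nuisance removal, applied identically
# before lag and CVR estimation.

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the three rotations converted to arc length on a
#' sphere of radius `sphere_radius_mm`. The first frame has FD 0 by
#' definition.
#'
#' @param motion `n_frames x 6` matrix: translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @param sphere_radius_mm radius used to convert rotations to mm (default
#'   50 mm, the community convention).
#'
#' @return Numeric vector of per-frame FD values (mm), first element 0.
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) < 2L) stop("need at least 2 frames to compute FD")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rowSums(d[, 4:6, drop = FALSE]) * sphere_radius_mm)
}

#' Flag motion-outlier frames
#'
#' A frame is invalid iff its framewise displacement strictly exceeds the
#' threshold (the boundary value is kept).
#'
#' @param fd per-frame FD (mm), e.g. from [framewise_displacement()].
#' @param threshold_mm exclusion threshold (default 1 mm).
#' @return Logical vector: `TRUE` for valid frames.
#' @export
flag_motion_outliers <- function(fd, threshold_mm = 1.0) {
  fd <= threshold_mm
}

#' Whole-scan motion exclusion decision
#'
#' A scan is discarded iff the fraction of invalid frames strictly exceeds
#' `max_invalid_fraction` (default one half).
#'
#' @param frame_valid logical per-frame validity flags.
#' @param max_invalid_fraction maximum tolerated invalid fraction.
#' @return List with `keep` (logical), `n_invalid` and `invalid_fraction`.
#' @export
scan_exclusion_check <- function(frame_valid, max_invalid_fraction = 0.5) {
  n_invalid <- sum(!frame_valid)
  frac <- n_invalid / length(frame_valid)
  list(keep = frac <= max_invalid_fraction,
       n_invalid = n_invalid, invalid_fraction = frac)
}

# Shared engine: regress a column basis out of every masked voxel over the
# valid frames, add the valid-frame mean back, and leave invalid frames
# untouched. `label` names the basis in error messages.
regress_basis <- function(bold, basis, label) {
  valid <- bold$frame_valid
  if (nrow(basis) != n_frames(bold)) {
    stop(label, " rows (", nrow(basis), ") must match the number of frames (",
         n_frames(bold), ")")
  }
  Xv <- basis[valid, , drop = FALSE]
  # columns constant over the valid frames are absorbed by the intercept
  keep <- apply(Xv, 2, function(col) stats::sd(col) > 0)
  Xv <- Xv[, keep, drop = FALSE]
  if (ncol(Xv) == 0L) return(bold)
  X <- cbind(1, Xv)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    cols <- colnames(Xv)
    if (is.null(cols)) cols <- paste0("column ", seq_len(ncol(Xv)))
    dropped <- setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)]) - 1L
    stop("rank-deficient ", label, ": collinear columns: ",
         paste(cols[dropped], collapse = ", "))
  }
  Y <- bold_matrix(bold)
  Yv <- Y[valid, , drop = FALSE]
  resid <- qr.resid(qrx, Yv)
  Y[valid, ] <- sweep(resid, 2, colMeans(Yv), `+`)
  set_bold_matrix(bold, Y)
}

#' Regress nuisance signals from a BOLD series
#'
#' Per voxel, ordinary least squares of the valid-frame signal on an
#' intercept plus the supplied regressors (typically the six motion
#' parameters and a CSF timecourse); the voxel's valid-frame mean is added
#' back to the residuals so baseline units are preserved. Invalid frames
#' pass through unchanged and remain flagged invalid. Regressor columns that
#' are constant over the valid frames (including all-zero columns) carry no
#' information beyond the intercept and are ignored; genuinely collinear
#' columns raise an error naming them.
#'
#' @param bold a [bold_series()].
#' @param regressors `n_frames x k` numeric matrix.
#' @return A cleaned [bold_series()].
#' @export
regress_nuisance <- function(bold, regressors) {
  regressors <- as.matrix(regressors)
  regress_basis(bold, regressors, "nuisance design")
}

#' Discrete-cosine drift basis below a cutoff
#'
#' The DCT-II components spanning frequencies strictly below `cutoff_hz`
#' for a run of `n_frames` frames at repetition time `TR`; the basis the
#' high-pass filter regresses out. Exposed so model regressors can be
#' residualised against the identical drift space.
#'
#' @param n_frames number of frames.
#' @param TR repetition time (s).
#' @param cutoff_hz high-pass cutoff (Hz).
#' @return `n_frames x K` matrix (zero columns if nothing falls below the
#'   cutoff).
#' @export
cosine_drift_basis <- function(n_frames, TR, cutoff_hz) {
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be positive")
  dur <- n_frames * TR
  K <- max(0L, ceiling(2 * dur * cutoff_hz) - 1L)
  i <- seq_len(n_frames)
  if (K < 1L) return(matrix(numeric(0), nrow = n_frames, ncol = 0))
  sapply(seq_len(K), function(k) cos(pi * k * (i - 0.5) / n_frames))
}

#' High-pass filter a BOLD series by cosine-basis regression
#'
#' Removes drifts below `cutoff_hz` by regressing out (over valid frames
#' only) a discrete-cosine basis spanning all frequencies strictly below the
#' cutoff; the voxel mean is re-added. Realised as a regression rather than
#' a recursive filter so censored frames are handled exactly.
#'
#' @param bold a [bold_series()].
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz); the scan must be
#'   longer than one cutoff period.
#' @return A filtered [bold_series()].
#' @export
highpass_filter <- function(bold, cutoff_hz = 0.01) {
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be positive")
  nt <- n_frames(bold)
  dur <- nt * bold$TR
  if (dur <= 1 / cutoff_hz) {
    stop("scan duration (", dur, " s) must exceed one cutoff period (",
         1 / cutoff_hz, " s)")
  }
  basis <- cosine_drift_basis(nt, bold$TR, cutoff_hz)
  if (ncol(basis) == 0L) return(bold)
  regress_basis(bold, basis, "cosine drift basis")
}
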