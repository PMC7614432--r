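#' BOLD time-series container
#'
#' A `bold_series` bundles a 4D voxel-by-time BOLD array with its repetition
#' time, a per-frame validity flag (used for motion scrubbing), a brain mask
#' and the voxel geometry. All estimation functions in the package operate on
#' this container; frames flagged invalid are excluded from every fit but are
#' never deleted, so temporal shift alignment stays index-true.
#'
#' @param data 4D numeric array `(x, y, z, time)` in raw signal units.
#' @param TR repetition time in seconds (> 0).
#' @param brain_mask logical 3D volume on the same grid; defaults to voxels
#'   with non-zero temporal standard deviation.
#' @param frame_valid logical vector, one entry per frame; defaults to all
#'   `TRUE`.
#' @param voxel_size_mm numeric length-3, voxel edge length per axis in mm.
#'
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, TR, brain_mask = NULL, frame_valid = NULL,
                        voxel_size_mm = c(2, 2, 2)) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D (x, y, z, time) array")
  nt <- dim(data)[4]
  if (nt < 2L) stop("time dimension must have at least 2 frames")
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0) stop("`TR` must be a positive scalar")
  if (is.null(frame_valid)) frame_valid <- rep(TRUE, nt)
  if (length(frame_valid) != nt) {
    stop("`frame_valid` length (", length(frame_valid),
         ") must equal the number of frames (", nt, ")")
  }
  if (is.null(brain_mask)) {
    v <- matrix(data, ncol = nt)
    sds <- sqrt(pmax(rowMeans(v^2) - rowMeans(v)^2, 0))
    brain_mask <- array(sds > 0, dim = dim(data)[1:3])
  }
  brain_mask <- as_mask(brain_mask, dim(data)[1:3], "brain_mask")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  structure(
    list(data = data, TR = TR, brain_mask = brain_mask,
         frame_valid = as.logical(frame_valid),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d voxels x %d frames, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$TR))
  cat(sprintf("  brain voxels: %d; valid frames: %d/%d\n",
              sum(x$brain_mask), sum(x$frame_valid), d[4]))
  invisible(x)
}

n_frames <- function(bold) dim(bold$data)[4]

frame_times <- function(bold) (seq_len(n_frames(bold)) - 1) * bold$TR

# Extract masked voxel timecourses as a frames x voxels matrix.
bold_matrix <- function(bold, mask = bold$brain_mask) {
  mask <- as_mask(mask, dim(bold$data)[1:3], "mask")
  nt <- n_frames(bold)
  m <- matrix(bold$data, ncol = nt)[as.vector(mask), , drop = FALSE]
  t(m)
}

# Write a frames x voxels matrix back into the 4D array over `mask`.
set_bold_matrix <- function(bold, mat, mask = bold$brain_mask) {
  mask <- as_mask(mask, dim(bold$data)[1:3], "mask")
  nt <- n_frames(bold)
  flat <- matrix(bold$data, ncol = nt)
  flat[as.vector(mask), ] <- t(mat)
  bold$data <- array(flat, dim = dim(bold$data))
  bold
}

# Mean timecourse over a mask (all frames; validity is handled downstream).
mask_mean_timecourse <- function(bold, mask) {
  if (sum(mask) == 0L) stop("mask is empty")
  rowMeans(bold_matrix(bold, mask))
}
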