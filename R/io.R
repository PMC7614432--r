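# File-format interfaces: NIfTI volumes via RNifti, motion parameters as
# 6-column TSV, CO2 traces as single-column text with a header line, JSON
# sidecars via jsonlite.

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param vol numeric or logical array (masks are written as 8-bit).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge lengths (mm); encoded in the pixdim.
#' @param TR for 4D data, the repetition time stored in the 4th pixdim.
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(vol, path, voxel_size_mm = c(2, 2, 2), TR = NULL) {
  is_mask <- is.logical(vol)
  arr <- if (is_mask) array(as.integer(vol), dim = dim(vol)) else vol
  pd <- voxel_size_mm
  if (length(dim(arr)) == 4L) pd <- c(pd, if (is.null(TR)) 1 else TR)
  attr(arr, "pixdim") <- pd
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(arr, path, datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List with `data` (array), `voxel_size_mm`, and `TR` (4D only).
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  nd <- length(dim(img))
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = pd[1:3],
       TR = if (nd >= 4L) pd[4] else NULL)
}

#' Write / read motion parameters as TSV
#'
#' Six columns: translations `tx, ty, tz` in mm, rotations `rx, ry, rz` in
#' radians; one row per frame.
#'
#' @param motion `n_frames x 6` matrix.
#' @param path TSV path.
#' @return `write_motion_tsv`: the path, invisibly. `read_motion_tsv`: the
#'   motion matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  m <- as.matrix(motion)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Write / read a CO2 trace as single-column text
#'
#' Plain text, one sample (mmHg) per line, preceded by a single header line
#' `# fs=<Hz> t0=<s>` stating the sampling rate and the offset of the first
#' sample relative to the first BOLD frame.
#'
#' @param co2 a `co2_trace`.
#' @param path output path.
#' @return `write_co2_trace`: the path, invisibly. `read_co2_trace`: a
#'   `co2_trace`.
#' @export
write_co2_trace <- function(co2, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g t0=%g", co2$fs, co2$t0), con)
  writeLines(format(co2$samples, digits = 10, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_co2_trace
#' @export
read_co2_trace <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("fs=([0-9.eE+-]+)(\\s+t0=([0-9.eE+-]+))?", header))[[1]]
  if (length(m) < 2L || m[2] == "") stop("CO2 file header must state `# fs=<Hz>`")
  fs <- as.numeric(m[2])
  t0 <- if (length(m) >= 4L && nzchar(m[4])) as.numeric(m[4]) else 0
  samples <- scan(path, skip = 1, quiet = TRUE)
  structure(list(samples = samples, fs = fs, t0 = t0), class = "co2_trace")
}

#' Write a lag or CVR map (plus QC sidecar) to a directory
#'
#' Lag maps produce `lag_s`, `peak_r` and `lag_valid` NIfTIs; CVR maps
#' produce `cvr`, `cvr_delay_s`, `cvr_fit_r` and `cvr_valid`. A JSON
#' summary sidecar is written alongside.
#'
#' @param map a `lag_map` or `cvr_map`.
#' @param dir output directory (created if needed).
#' @param voxel_size_mm voxel geometry for the NIfTI headers.
#' @return The directory, invisibly.
#' @export
write_map <- function(map, dir, voxel_size_mm = c(2, 2, 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wv <- function(vol, name) {
    write_nifti_vol(vol, file.path(dir, paste0(name, ".nii.gz")), voxel_size_mm)
  }
  if (inherits(map, "lag_map")) {
    wv(map$lag_s, "lag_s"); wv(map$peak_r, "peak_r"); wv(map$valid, "lag_valid")
    summary <- list(reference_id = map$reference_id,
                    valid_fraction = mean(map$valid[map$mask]),
                    mean_lag_s = mean(map$lag_s[map$valid]))
    jsonlite::write_json(summary, file.path(dir, "lag_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (inherits(map, "cvr_map")) {
    wv(map$cvr, "cvr"); wv(map$delay_s, "cvr_delay_s")
    wv(map$fit_r, "cvr_fit_r"); wv(map$valid, "cvr_valid")
    summary <- list(valid_fraction = mean(map$valid[map$mask]),
                    median_cvr = stats::median(map$cvr[map$valid]),
                    median_delay_s = stats::median(map$delay_s[map$valid]))
    jsonlite::write_json(summary, file.path(dir, "cvr_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    stop("`map` must be a lag_map or cvr_map")
  }
  invisible(dir)
}
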