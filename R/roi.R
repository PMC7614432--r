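# Lesion-anchored region-of-interest geometry: lesion, perilesional shell,
# remote tissue, and their hemispheric homologues by sagittal reflection.

#' Perilesional shell mask
#'
#' Brain voxels whose centre lies within `radius_mm` (centre-to-centre
#' Euclidean distance in millimetres, inclusive) of any lesion voxel
#' centre, excluding the lesion itself. Distances are computed in mm so
#' anisotropic voxels are handled correctly.
#'
#' @param lesion logical lesion volume (non-empty).
#' @param brain logical brain (or tissue) volume on the same grid.
#' @param voxel_size_mm voxel edge lengths (mm) per axis.
#' @param radius_mm shell radius (default 10 mm, i.e. within 1 cm).
#' @return Logical volume.
#' @export
perilesional_mask <- function(lesion, brain, voxel_size_mm, radius_mm = 10) {
  lesion <- as_mask(lesion, arg = "lesion")
  brain <- as_mask(brain, dim(lesion), "brain")
  if (sum(lesion) == 0L) stop("lesion mask is empty")
  out <- array(FALSE, dim = dim(lesion))
  if (radius_mm <= 0) return(out)
  les <- which(lesion, arr.ind = TRUE)
  cand <- which(brain & !lesion, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  d2 <- matrix(0, nrow(cand), nrow(les))
  for (ax in 1:3) {
    d2 <- d2 + outer(cand[, ax], les[, ax], `-`)^2 * voxel_size_mm[ax]^2
  }
  hit <- apply(d2, 1, min) <= radius_mm^2 + 1e-9
  out[cand[hit, , drop = FALSE]] <- TRUE
  out
}

#' Reflect a mask about the sagittal midline
#'
#' Maps each voxel at distance d left of the midline plane (first axis) to
#' distance d right of it. Voxels lying exactly on the plane (odd grids)
#' map to themselves, with a warning. Reflecting twice returns the
#' original mask.
#'
#' @param mask logical volume.
#' @param midline_index midline coordinate along the first axis (may be a
#'   half-integer for even grids).
#' @return Reflected logical volume.
#' @export
homologue_mask <- function(mask, midline_index) {
  mask <- as_mask(mask, arg = "mask")
  out <- array(FALSE, dim = dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  xr <- round(2 * midline_index - idx[, 1])
  if (any(xr < 1 | xr > dim(mask)[1])) {
    stop("reflection falls outside the grid; check `midline_index`")
  }
  if (any(xr == idx[, 1])) {
    warning("mask overlaps the midline plane; on-plane voxels map to themselves")
  }
  out[cbind(xr, idx[, 2], idx[, 3])] <- TRUE
  out
}

#' Build the six tissue-compartment ROIs
#'
#' Constructs the three left-hemisphere compartments used for the lag-CVR
#' statistics -- lesion, perilesional shell (within `radius_mm` of the
#' lesion boundary) and remote healthy tissue -- and their homologues in
#' the right hemisphere by sagittal reflection. All ROIs are restricted to
#' grey matter and to their hemisphere, so {lesion, perilesional, remote}
#' partitions left-hemisphere grey matter.
#'
#' @param lesion logical lesion volume (within the left hemisphere).
#' @param gm logical grey-matter volume.
#' @param left_hemi,right_hemi hemisphere masks partitioning the brain.
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param midline_index sagittal midline coordinate (first axis).
#' @param radius_mm perilesional shell radius (default 10 mm).
#' @return A `roi_set`: named list of six logical volumes (`lesion`,
#'   `perilesional`, `remote_left`, `lesion_homologue`,
#'   `perilesional_homologue`, `remote_right`) plus `radius_mm`.
#' @export
build_roi_set <- function(lesion, gm, left_hemi, right_hemi, voxel_size_mm,
                          midline_index, radius_mm = 10) {
  dims <- dim(as_mask(lesion, arg = "lesion"))
  lesion <- as_mask(lesion, dims, "lesion")
  gm <- as_mask(gm, dims, "gm")
  left_hemi <- as_mask(left_hemi, dims, "left_hemi")
  right_hemi <- as_mask(right_hemi, dims, "right_hemi")
  if (any(lesion & right_hemi)) {
    warning("lesion extends into the right hemisphere; homologues will overlap it")
  }
  brain <- left_hemi | right_hemi
  peri_raw <- perilesional_mask(lesion, brain, voxel_size_mm, radius_mm)

  lesion_roi <- lesion & gm
  peri <- peri_raw & gm & left_hemi
  remote_left <- left_hemi & gm & !lesion & !peri_raw
  refl <- function(m) homologue_mask(m, midline_index) & gm & right_hemi
  structure(
    list(lesion = lesion_roi, perilesional = peri, remote_left = remote_left,
         lesion_homologue = refl(lesion_roi),
         perilesional_homologue = refl(peri),
         remote_right = refl(remote_left),
         radius_mm = radius_mm),
    class = "roi_set"
  )
}

roi_labels <- c("lesion", "perilesional", "remote_left",
                "lesion_homologue", "perilesional_homologue", "remote_right")

#' @export
print.roi_set <- function(x, ...) {
  counts <- vapply(roi_labels, function(l) sum(x[[l]]), integer(1))
  cat("<roi_set> voxel counts:\n")
  print(counts)
  invisible(x)
}
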