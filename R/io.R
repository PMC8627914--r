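# User-facing mask I/O and the two data-preparation operations applied to
# automatic segmentations before analysis: probability thresholding and
# merging an initial segmentation with manual corrections.

#' Read a binary mask
#'
#' Reads a segmentation mask from a NIfTI file (`.nii` / `.nii.gz`) or a
#' directory of DICOM slices. DICOM slices are reassembled in spatial order
#' (by position along the slice normal), not by filename. Voxel values must
#' be binary: exactly `{0, 1}`, or any two distinct values, which are mapped
#' low to background and high to foreground with a warning (as with
#' `{0, 255}` exports).
#'
#' @param path File (NIfTI) or directory (DICOM series).
#' @param format `"auto"` (default, by path type/extension), `"nifti"` or
#'   `"dicom_series"`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
    read_nifti_mask(path)
  } else {
    if (!dir.exists(path)) stop(sprintf("directory not found: '%s'", path))
    read_dicom_series(path)
  }
}

#' Write a binary mask
#'
#' Writes either a single NIfTI volume or one DICOM file per axial slice
#' (minimal secondary-capture-style files with correct PixelSpacing,
#' ImagePositionPatient and SliceThickness). Foreground is stored as 1;
#' both formats read back voxel-exactly through [read_mask()].
#'
#' @param mask A [binary_mask()].
#' @param path Output file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("nifti", "dicom_series")) {
  stopifnot(inherits(mask, "binary_mask"))
  format <- match.arg(format)
  res <- try(switch(format,
                    nifti = write_nifti_mask(mask, path),
                    dicom_series = write_dicom_series(mask, path)),
             silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("failed to write mask to '%s': %s", path,
                 attr(res, "condition")$message))
  invisible(path)
}

#' Read a probability map from NIfTI
#'
#' @param path NIfTI file with voxel values in \[0, 1\].
#' @return A [probability_map()].
#' @export
read_probability_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  read_nifti_pmap(path)
}

#' Threshold a probability map to a binary mask
#'
#' A voxel becomes foreground iff its probability is greater than or equal
#' to the threshold (so a voxel at exactly the 0.5 cut-off is foreground).
#' The default threshold of 0.5 is the standard operating point for
#' voxel-classification airway models.
#'
#' @param pmap A [probability_map()].
#' @param threshold Real in \[0, 1\].
#' @return A [binary_mask()] with the map's geometry.
#' @export
threshold_probability <- function(pmap, threshold = 0.5) {
  stopifnot(inherits(pmap, "probability_map"))
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]")
  binary_mask(array(pmap$values >= threshold, dim(pmap$values)),
              pmap$spacing_mm, pmap$origin_mm, pmap$orientation)
}

#' Merge an initial segmentation with corrections
#'
#' Voxelwise union of two masks on the same grid, as when manual correction
#' strokes are combined with an automatic initial segmentation. The two
#' masks must agree in grid shape, spacing (within 1e-3 mm) and orientation;
#' geometry metadata is taken from `initial`.
#'
#' @param initial,correction [binary_mask()] objects on identical grids.
#' @return A [binary_mask()] containing the union.
#' @export
merge_correction <- function(initial, correction) {
  stopifnot(inherits(initial, "binary_mask"), inherits(correction, "binary_mask"))
  if (!identical(dim(initial$voxels), dim(correction$voxels)))
    stop(sprintf("geometry mismatch: grid dimensions differ (%s vs %s)",
                 paste(dim(initial$voxels), collapse = "x"),
                 paste(dim(correction$voxels), collapse = "x")))
  if (any(abs(initial$spacing_mm - correction$spacing_mm) > 1e-3))
    stop("geometry mismatch: spacing_mm differs by more than 1e-3 mm")
  if (!identical(initial$orientation, correction$orientation))
    stop("geometry mismatch: orientation differs")
  binary_mask(initial$voxels | correction$voxels,
              initial$spacing_mm, initial$origin_mm, initial$orientation)
}
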