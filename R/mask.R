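# Binary masks and probability maps: the in-memory representation of a
# segmentation.  All geometry is physical millimetres; voxel (i,j,k)
# (1-based) has its center at origin_mm + (c(i,j,k) - 1) * spacing_mm.
# The orientation codes give the anatomical direction of increasing index
# along each array axis ("R"/"L", "A"/"P", "S"/"I"); the default "RAS"
# frame puts superior at high third-axis index, so the trachea of a chest
# scan is at the top of the volume.

#' Construct a binary segmentation mask
#'
#' A `binary_mask` is a 3-D logical voxel grid with physical geometry:
#' voxel spacing in mm per axis, the physical coordinate of the first voxel
#' center, and orientation codes identifying the anatomical direction of each
#' array axis (needed to know which way is superior, where the trachea lies).
#'
#' @param voxels 3-D `logical` (or coercible numeric 0/1) array.
#' @param spacing_mm Numeric length-3, strictly positive voxel spacing (mm).
#' @param origin_mm Numeric length-3 physical coordinate of voxel (1,1,1) (mm).
#' @param orientation Character length-3; direction of increasing index per
#'   axis, one axis of which must be `"S"` or `"I"`. Default `c("R","A","S")`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                        orientation = c("R", "A", "S")) {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("'voxels' must be a non-empty 3-D array")
  if (!is.logical(voxels)) {
    vals <- unique(as.vector(voxels))
    if (!all(vals %in% c(0, 1)))
      stop("numeric 'voxels' must contain only 0 and 1")
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite numbers")
  orientation <- as.character(orientation)
  if (length(orientation) != 3L ||
      !any(orientation %in% c("S", "I")))
    stop("'orientation' must contain a superior/inferior axis ('S' or 'I')")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm, origin_mm = origin_mm,
         orientation = orientation),
    class = "binary_mask")
}

#' Construct a probability map
#'
#' A 3-D grid of voxelwise foreground probabilities in \[0, 1\] with the same
#' geometry metadata as [binary_mask()]. Typically the raw output of a
#' voxel-classification model before thresholding.
#'
#' @param values 3-D numeric array with values in \[0, 1\] (tolerance 1e-6).
#' @inheritParams binary_mask
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                            orientation = c("R", "A", "S")) {
  if (length(dim(values)) != 3L || any(dim(values) < 1L))
    stop("'values' must be a non-empty 3-D array")
  rng <- range(values)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    stop("probability values must lie in [0, 1]")
  m <- binary_mask(array(TRUE, dim(values)), spacing_mm, origin_mm, orientation)
  structure(
    list(values = values, spacing_mm = m$spacing_mm, origin_mm = m$origin_mm,
         orientation = m$orientation),
    class = "probability_map")
}

# Index of the array axis pointing superior/inferior, with sign +1 if
# increasing index moves superior.
superior_axis <- function(mask) {
  ax <- which(mask$orientation %in% c("S", "I"))[1]
  sign <- if (mask$orientation[ax] == "S") 1 else -1
  list(axis = ax, sign = sign)
}

# Physical coordinates (n x 3 matrix, mm) of 1-based voxel indices.
voxel_to_mm <- function(mask, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, mask$spacing_mm, "*"), 2, mask$origin_mm, "+")
}

n_foreground <- function(mask) sum(mask$voxels)

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_mask: %d x %d x %d voxels, spacing %s mm, %d foreground (%s)\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 3), collapse = " x "),
              sum(x$voxels), paste(x$orientation, collapse = "")))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("probability_map: %d x %d x %d voxels, spacing %s mm, range [%.3f, %.3f]\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}
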