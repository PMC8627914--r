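# NIfTI reading/writing through RNifti.  Internal geometry is physical mm
# in an RAS-style frame: the sform is a diagonal spacing matrix plus the
# origin translation, which round-trips voxels, spacing and origin exactly.

nifti_xform <- function(spacing_mm, origin_mm) {
  m <- diag(c(spacing_mm, 1))
  m[1:3, 4] <- origin_mm
  m
}

write_nifti_mask <- function(mask, path) {
  arr <- array(as.integer(mask$voxels), dim(mask$voxels))
  attr(arr, "pixdim") <- mask$spacing_mm   # must precede asNifti()
  img <- RNifti::asNifti(arr, datatype = "uint8")
  m <- nifti_xform(mask$spacing_mm, mask$origin_mm)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

write_nifti_pmap <- function(pmap, path) {
  vals <- pmap$values
  attr(vals, "pixdim") <- pmap$spacing_mm
  img <- RNifti::asNifti(vals, datatype = "double")
  m <- nifti_xform(pmap$spacing_mm, pmap$origin_mm)
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_geometry <- function(img) {
  x <- RNifti::xform(img)
  spacing <- sqrt(colSums(x[1:3, 1:3]^2))
  origin <- x[1:3, 4]
  orient <- strsplit(RNifti::orientation(img), "")[[1]]
  # RNifti reports the nearest-axis orientation string, e.g. "RAS"
  list(spacing_mm = as.numeric(spacing), origin_mm = as.numeric(origin),
       orientation = orient)
}

read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  geo <- read_nifti_geometry(img)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop(sprintf("'%s' is not a 3-D volume", path))
  vox <- coerce_binary_values(vals, path)
  binary_mask(vox, geo$spacing_mm, geo$origin_mm, geo$orientation)
}

read_nifti_pmap <- function(path) {
  img <- RNifti::readNifti(path)
  geo <- read_nifti_geometry(img)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop(sprintf("'%s' is not a 3-D volume", path))
  probability_map(vals, geo$spacing_mm, geo$origin_mm, geo$orientation)
}

# Map stored voxel values to logical foreground.  Exactly {0,1} passes
# silently; any other two-valued coding (e.g. DICOM-style {0,255}) is
# mapped low -> background, high -> foreground with a warning; more than
# two distinct values is an error.
coerce_binary_values <- function(vals, path) {
  u <- sort(unique(as.vector(vals)))
  if (length(u) > 2L)
    stop(sprintf("'%s' is not a binary mask: %d distinct voxel values", path, length(u)))
  if (length(u) == 1L) {
    fg <- u[1] != 0
    if (fg && u[1] != 1)
      warning(sprintf("mask '%s' stores foreground as %g; mapped to TRUE", path, u[1]))
    return(array(rep(fg, length(vals)), dim(vals)))
  }
  if (!identical(u, c(0, 1)) && !identical(as.numeric(u), c(0, 1))) {
    warning(sprintf("mask '%s' stores values {%g, %g}; mapped low->0, high->1",
                    path, u[1], u[2]))
  }
  array(as.vector(vals) == u[2], dim(vals))
}
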