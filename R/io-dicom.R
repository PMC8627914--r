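# Minimal DICOM slice-series support for binary masks.  One 8-bit
# secondary-capture-style file per axial slice, Explicit VR Little Endian,
# with the geometry tags (PixelSpacing, ImagePositionPatient,
# ImageOrientationPatient, SliceThickness) filled correctly so that a
# series round-trips voxels and spacing exactly.  This is a transport
# format for segmentation volumes, not a conformant clinical archive; only
# Explicit VR Little Endian files written in this style are read back.
# No DICOM package ships with the R distribution used here, so the byte
# format is implemented directly.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.9999"

dcm_pad <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

# One data element in Explicit VR Little Endian.
dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(paste(value, collapse = "\\"))
    v <- dcm_pad(v, pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  } else if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    v <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    v <- as.raw(value)
    v <- dcm_pad(v, pad = as.raw(0))
  } else {
    stop("unsupported VR ", vr)
  }
  long_form <- vr %in% c("OB", "OW", "SQ", "UN", "UT")
  header <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (long_form) {
    header <- c(header, as.raw(c(0, 0)),
                writeBin(length(v), raw(), size = 4, endian = "little"))
  } else {
    if (length(v) > 65534L) stop("value too long for short-form VR")
    header <- c(header, dcm_uint16(length(v)))
  }
  c(header, v)
}

dcm_ds <- function(x) paste(formatC(x, format = "fg", digits = 10), collapse = "\\")

# Write one axial slice (matrix nx x ny of logical) as a DICOM file.
write_dicom_slice <- function(slice, path, spacing_mm, position_mm,
                              instance, series_uid, study_uid) {
  nx <- nrow(slice)
  ny <- ncol(slice)
  sop_uid <- paste0(series_uid, ".", instance)
  # PixelData: DICOM is row-major with Rows = ny (our y axis), Columns = nx,
  # the column index (x) varying fastest -- which is R's column-major order
  # for an nx x ny matrix.  Foreground is stored as 1.
  pix <- as.raw(as.integer(slice))
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_SECONDARY_CAPTURE),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "OT"),
    dcm_element(0x0020, 0x000D, "UI", study_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", dcm_ds(position_mm)),
    dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0018, 0x0050, "DS", dcm_ds(spacing_mm[3])),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", ny),          # Rows
    dcm_element(0x0028, 0x0011, "US", nx),          # Columns
    dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(spacing_mm[2], spacing_mm[1]))),
    dcm_element(0x0028, 0x0100, "US", 8L),
    dcm_element(0x0028, 0x0101, "US", 8L),
    dcm_element(0x0028, 0x0102, "US", 7L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OB", pix))
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", UID_SECONDARY_CAPTURE),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# DS and IS are decimal strings; short string VRs share one decoder.
dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path))
  pos <- 133L
  elements <- list()
  string_vrs <- c("UI", "CS", "DS", "IS", "LO", "SH", "PN", "DA", "TM", "AE", "ST")
  while (pos + 8L <= length(bytes) + 1L) {
    group <- readBin(bytes[pos:(pos + 1)], "integer", size = 2, endian = "little", signed = FALSE)
    element <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2, endian = "little", signed = FALSE)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("'%s': unsupported transfer syntax (implicit VR?)", path))
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4, endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2, endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    if (len < 0L) stop(sprintf("'%s': undefined element lengths are not supported", path))
    vraw <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    value <- if (vr %in% string_vrs) {
      v <- vraw
      while (length(v) > 0L && (v[length(v)] == as.raw(0) || v[length(v)] == as.raw(0x20)))
        v <- v[-length(v)]
      strsplit(rawToChar(v), "\\\\")[[1]]
    } else if (vr == "US") {
      readBin(vraw, "integer", n = len / 2, size = 2, endian = "little", signed = FALSE)
    } else if (vr == "UL") {
      readBin(vraw, "integer", n = len / 4, size = 4, endian = "little")
    } else {
      vraw
    }
    elements[[key]] <- value
    pos <- vstart + len
  }
  elements
}

write_dicom_series <- function(mask, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  d <- dim(mask$voxels)
  series_uid <- paste0(UID_ROOT, ".", Sys.getpid(), ".",
                       format(as.integer(Sys.time()) %% 1e7))
  study_uid <- paste0(series_uid, ".0")
  for (k in seq_len(d[3])) {
    pos <- mask$origin_mm + c(0, 0, (k - 1) * mask$spacing_mm[3])
    write_dicom_slice(mask$voxels[, , k],
                      file.path(dir_path, sprintf("slice_%04d.dcm", k)),
                      mask$spacing_mm, pos, k, series_uid, study_uid)
  }
  invisible(dir_path)
}

read_dicom_series <- function(dir_path) {
  files <- list.files(dir_path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no .dcm files found in '%s'", dir_path))
  slices <- lapply(files, dcm_parse_file)
  get1 <- function(el, key, what) {
    v <- el[[key]]
    if (is.null(v)) stop(sprintf("DICOM slice is missing %s (%s)", what, key))
    v
  }
  positions <- t(vapply(slices, function(el)
    as.numeric(get1(el, "0020,0032", "ImagePositionPatient")), numeric(3)))
  orient <- as.numeric(get1(slices[[1]], "0020,0037", "ImageOrientationPatient"))
  normal <- cross3(orient[1:3], orient[4:6])
  along <- as.numeric(positions %*% normal)
  ord <- order(along)            # spatial order, independent of filenames
  slices <- slices[ord]
  along <- along[ord]
  positions <- positions[ord, , drop = FALSE]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(along)
    if (any(abs(dz - dz[1]) > 1e-3))
      stop(sprintf("inconsistent slice spacing in '%s': increments range %.6g-%.6g mm",
                   dir_path, min(dz), max(dz)))
    dz <- dz[1]
  } else {
    dz <- as.numeric(get1(slices[[1]], "0018,0050", "SliceThickness"))
  }
  rows <- get1(slices[[1]], "0028,0010", "Rows")
  cols <- get1(slices[[1]], "0028,0011", "Columns")
  ps <- as.numeric(get1(slices[[1]], "0028,0030", "PixelSpacing"))  # row, col
  vox <- array(0L, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    pix <- slices[[k]][["7FE0,0010"]]
    if (is.null(pix)) stop("DICOM slice has no PixelData")
    vox[, , k] <- array(as.integer(pix[seq_len(cols * rows)]), c(cols, rows))
  }
  vals <- coerce_binary_values(vox, dir_path)
  binary_mask(vals, spacing_mm = c(ps[2], ps[1], dz),
              origin_mm = positions[1, ])
}
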