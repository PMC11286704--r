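# Minimal DICOM Part-10 reader/writer for single-frame, uncompressed,
# Explicit VR Little Endian series -- the only encoding this engine consumes
# and the one its fixture writer emits. Tags outside the set needed for
# geometry, ordering and pixel data are parsed generically and ignored.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

.str_val <- function(s, pad = as.raw(0x20)) .pad_even(charToRaw(s), pad)

# One explicit-VR element as raw bytes.
.dcm_element <- function(group, elem, vr, value) {
  stopifnot(is.raw(value))
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(hdr, as.raw(c(0, 0)), .u32(length(value)), value)
  } else {
    c(hdr, .u16(length(value)), value)
  }
}

.uid <- function(...) paste(c("1.2.826.0.1.3680043.9999", ...), collapse = ".")

#' Write an image series as single-frame DICOM files
#'
#' Fixture/export writer emitting one Explicit VR Little Endian Part-10 file
#' per slice, with 16-bit unsigned pixels. Intensities must already be
#' integers in \[0, 65535\]. Slice positions are encoded along the slice
#' normal of a coronal stack so that readers can restore spatial order
#' independent of file naming.
#'
#' @param series an [image_series]
#' @param dir output directory (created if needed)
#' @param series_uid DICOM series instance UID; generated when `NULL`
#' @param file_names optional file names, one per slice (used to exercise
#'   order-independence of readers)
#' @param instance_numbers optional instance numbers, one per slice
#' @return invisibly, the written file paths in slice order
#' @export
write_dicom_series <- function(series, dir, series_uid = NULL,
                               file_names = NULL, instance_numbers = NULL) {
  stopifnot(inherits(series, "image_series"))
  v <- series$voxels
  if (any(v != round(v)) || max(v) > 65535)
    stop("DICOM writer requires integer intensities in [0, 65535]")
  nz <- dim(v)[1]; ny <- dim(v)[2]; nx <- dim(v)[3]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(series_uid)) series_uid <- .uid("1", round(stats::runif(1) * 1e6))
  study_uid <- .uid("0", "1")
  if (is.null(file_names)) file_names <- sprintf("IM%04d.dcm", seq_len(nz))
  if (is.null(instance_numbers)) instance_numbers <- seq_len(nz)
  # coronal: rows run craniocaudally, columns left-right, normal A->P
  orient <- "1\\0\\0\\0\\0\\-1"
  paths <- character(nz)
  for (i in seq_len(nz)) {
    sop_uid <- .uid("2", i)
    pos <- sprintf("0\\%g\\0", (i - 1) * series$slice_thickness_mm)
    slc <- v[i, , ]
    pix <- writeBin(as.integer(t(slc)), raw(), size = 2, endian = "little")
    ds <- c(
      .dcm_element(0x0008, 0x0016, "UI", .str_val(DICOM_SOP_MR, as.raw(0))),
      .dcm_element(0x0008, 0x0018, "UI", .str_val(sop_uid, as.raw(0))),
      .dcm_element(0x0008, 0x0060, "CS", .str_val("MR")),
      .dcm_element(0x0008, 0x103E, "LO", .str_val(series$series_label)),
      if (length(series$patient_meta))
        .dcm_element(0x0010, 0x0010, "PN",
                     .str_val(series$patient_meta[[1]])) else raw(0),
      .dcm_element(0x0018, 0x0050, "DS",
                   .str_val(format(series$slice_thickness_mm))),
      .dcm_element(0x0020, 0x000D, "UI", .str_val(study_uid, as.raw(0))),
      .dcm_element(0x0020, 0x000E, "UI", .str_val(series_uid, as.raw(0))),
      .dcm_element(0x0020, 0x0013, "IS",
                   .str_val(format(instance_numbers[i]))),
      .dcm_element(0x0020, 0x0032, "DS", .str_val(pos)),
      .dcm_element(0x0020, 0x0037, "DS", .str_val(orient)),
      .dcm_element(0x0028, 0x0002, "US", .u16(1)),
      .dcm_element(0x0028, 0x0004, "CS", .str_val("MONOCHROME2")),
      .dcm_element(0x0028, 0x0010, "US", .u16(ny)),
      .dcm_element(0x0028, 0x0011, "US", .u16(nx)),
      .dcm_element(0x0028, 0x0030, "DS",
                   .str_val(paste(format(series$pixel_spacing_mm),
                                  collapse = "\\"))),
      .dcm_element(0x0028, 0x0100, "US", .u16(16)),
      .dcm_element(0x0028, 0x0101, "US", .u16(16)),
      .dcm_element(0x0028, 0x0102, "US", .u16(15)),
      .dcm_element(0x0028, 0x0103, "US", .u16(0)),
      .dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    meta_body <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_element(0x0002, 0x0002, "UI", .str_val(DICOM_SOP_MR, as.raw(0))),
      .dcm_element(0x0002, 0x0003, "UI", .str_val(sop_uid, as.raw(0))),
      .dcm_element(0x0002, 0x0010, "UI",
                   .str_val(DICOM_TS_EXPLICIT_LE, as.raw(0)))
    )
    meta <- c(.dcm_element(0x0002, 0x0000, "UL", .u32(length(meta_body))),
              meta_body)
    paths[i] <- file.path(dir, file_names[i])
    con <- file(paths[i], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(paths)
}

# Parse one Part-10 file into a tag -> value list. Values are parsed by VR:
# US as integer, numeric strings (DS/IS) as numeric vectors, text VRs as
# trimmed strings, OW pixel data as an integer vector (uint16 LE).
.read_dicom_file <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("parse failure: %s is not a DICOM Part-10 file",
                 basename(path)))
  pos <- 133L
  out <- list()
  n <- length(raw)
  rows <- cols <- NA_integer_
  while (pos + 7L <= n) {
    group <- readBin(raw[pos:(pos + 1)], "integer", size = 2,
                     endian = "little", signed = FALSE)
    elem <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                    endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("parse failure: %s uses an unsupported (implicit VR?) encoding",
                   basename(path)))
    if (vr %in% .long_vrs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > n)
      stop(sprintf("parse failure: truncated element in %s", basename(path)))
    val_raw <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- switch(
      vr,
      US = readBin(val_raw, "integer", n = len / 2, size = 2,
                   endian = "little", signed = FALSE),
      UL = readBin(val_raw, "integer", n = len / 4, size = 4,
                   endian = "little"),
      DS = ,
      IS = as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
      OW = readBin(val_raw, "integer", n = len / 2, size = 2,
                   endian = "little", signed = FALSE),
      OB = val_raw,
      UN = val_raw,
      SQ = val_raw,
      trimws(rawToChar(val_raw[val_raw != as.raw(0)]))
    )
    pos <- vstart + len
  }
  out
}

# Project an ImagePositionPatient point onto the slice normal implied by
# ImageOrientationPatient (row direction x column direction).
.slice_sort_key <- function(tags) {
  ori <- tags[["0020,0037"]]
  ipp <- tags[["0020,0032"]]
  if (is.null(ori) || is.null(ipp) || length(ori) != 6 || length(ipp) != 3)
    return(NA_real_)
  r <- ori[1:3]; cvec <- ori[4:6]
  normal <- c(r[2] * cvec[3] - r[3] * cvec[2],
              r[3] * cvec[1] - r[1] * cvec[3],
              r[1] * cvec[2] - r[2] * cvec[1])
  sum(ipp * normal)
}
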