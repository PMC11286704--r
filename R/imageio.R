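# Core containers and DICOM/NIfTI plumbing.
#
# Axis convention used throughout: 3D arrays are indexed (slice, row, col).
# For the coronal stacks this engine targets, slices run anterior->posterior,
# rows run craniocaudally (superior->inferior) and columns run right->left.

#' Construct an image series
#'
#' A single 3D grayscale stack plus the voxel geometry needed for
#' volumetry: in-plane pixel spacing (row, col) and slice thickness, in mm.
#'
#' @param voxels 3D numeric array indexed (slice, row, col), nonnegative
#' @param pixel_spacing_mm length-2 positive numeric, (row, col) spacing
#' @param slice_thickness_mm positive scalar
#' @param series_label free-text label
#' @param patient_meta named character vector/list; may be empty
#' @return an object of class `image_series`
#' @export
image_series <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                         series_label = "", patient_meta = list()) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (slice, row, col)")
  d <- dim(voxels)
  if (d[1] < 1L || d[2] < 16L || d[3] < 16L)
    stop("series must have >= 1 slice, each slice >= 16x16")
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and >= 0")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two positive values (row, col)")
  if (length(slice_thickness_mm) != 1L || slice_thickness_mm <= 0)
    stop("slice_thickness_mm must be a positive scalar")
  structure(list(voxels = voxels,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 series_label = as.character(series_label),
                 patient_meta = patient_meta),
            class = "image_series")
}

#' Voxel geometry of a series (or standalone spacing object)
#'
#' @param pixel_spacing_mm length-2 positive numeric (row, col), mm
#' @param slice_thickness_mm positive scalar, mm
#' @return a `voxel_spacing` list
#' @export
voxel_spacing <- function(pixel_spacing_mm, slice_thickness_mm) {
  stopifnot(length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0),
            slice_thickness_mm > 0)
  structure(list(pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "voxel_spacing")
}

#' @export
#' @rdname voxel_spacing
#' @param series an [image_series]
series_spacing <- function(series) {
  voxel_spacing(series$pixel_spacing_mm, series$slice_thickness_mm)
}

# mm^3 per voxel
.voxel_mm3 <- function(spacing) {
  prod(spacing$pixel_spacing_mm) * spacing$slice_thickness_mm
}

#' Construct a geometry-matched exam pair
#'
#' Pre- and post-secretin series must share array shape, pixel spacing and
#' slice thickness; the whole pipeline assumes voxelwise correspondence.
#'
#' @param pre,post [image_series] objects
#' @return an object of class `exam_pair`
#' @export
exam_pair <- function(pre, post) {
  stopifnot(inherits(pre, "image_series"), inherits(post, "image_series"))
  if (!identical(dim(pre$voxels), dim(post$voxels)) ||
      !isTRUE(all.equal(pre$pixel_spacing_mm, post$pixel_spacing_mm)) ||
      !isTRUE(all.equal(pre$slice_thickness_mm, post$slice_thickness_mm))) {
    stop(sprintf(paste0(
      "geometry mismatch: pre %s @ %s/%s mm vs post %s @ %s/%s mm"),
      paste(dim(pre$voxels), collapse = "x"),
      paste(pre$pixel_spacing_mm, collapse = "x"), pre$slice_thickness_mm,
      paste(dim(post$voxels), collapse = "x"),
      paste(post$pixel_spacing_mm, collapse = "x"), post$slice_thickness_mm))
  }
  structure(list(pre = pre, post = post), class = "exam_pair")
}

#' Read a single-frame DICOM series into an image series
#'
#' All files in `directory` must belong to one series (one series instance
#' UID). Slices are ordered by the projection of the image position onto
#' the slice normal; instance number is the fallback when position or
#' orientation is absent.
#'
#' @param directory path containing the DICOM files of one series
#' @return an [image_series]
#' @export
read_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("parse failure: no files in ", directory)
  parsed <- lapply(files, .read_dicom_file)
  uids <- vapply(parsed, function(t) {
    u <- t[["0020,000E"]]; if (is.null(u)) "" else u
  }, character(1))
  if (length(unique(uids)) > 1L)
    stop("mixed series: directory contains series UIDs ",
         paste(unique(uids), collapse = ", "))
  spac <- parsed[[1]][["0028,0030"]]
  thick <- parsed[[1]][["0018,0050"]]
  if (is.null(spac) || is.null(thick) || length(spac) != 2L)
    stop("incomplete geometry: pixel spacing or slice thickness missing")
  keys <- vapply(parsed, .slice_sort_key, numeric(1))
  if (anyNA(keys)) {
    keys <- vapply(parsed, function(t) {
      k <- t[["0020,0013"]]; if (is.null(k)) NA_real_ else k[1]
    }, numeric(1))
    if (anyNA(keys))
      stop("incomplete geometry: neither position nor instance number present")
  }
  ord <- order(keys)
  parsed <- parsed[ord]
  ny <- parsed[[1]][["0028,0010"]]
  nx <- parsed[[1]][["0028,0011"]]
  nz <- length(parsed)
  vox <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) {
    pix <- parsed[[i]][["7FE0,0010"]]
    if (is.null(pix) || length(pix) != ny * nx)
      stop(sprintf("parse failure: bad pixel data in %s",
                   basename(files[ord[i]])))
    vox[i, , ] <- t(matrix(pix, nrow = nx, ncol = ny))
  }
  lab <- parsed[[1]][["0008,103E"]]
  pname <- parsed[[1]][["0010,0010"]]
  image_series(vox, pixel_spacing_mm = spac, slice_thickness_mm = thick,
               series_label = if (is.null(lab)) "" else lab,
               patient_meta = if (is.null(pname)) list() else
                 list(patient_name = pname))
}

#' Load and validate a matched pre/post exam
#'
#' @param pre_dir,post_dir DICOM directories for the pre- and post-secretin
#'   series
#' @return an [exam_pair]
#' @export
load_exam <- function(pre_dir, post_dir) {
  exam_pair(read_series(pre_dir), read_series(post_dir))
}

#' Assemble a result bundle
#'
#' The save-file contents of one processed exam: both masks, total volumes,
#' per-slice fluid-volume curves and analysis metadata. The construction
#' enforces the accounting identities (delta = post - pre; each curve sums
#' to its total volume).
#'
#' @param pre_mask,post_mask logical 3D masks aligned to the exam
#' @param spacing a [voxel_spacing]
#' @param analysis_meta named list of strings (software version, parameters,
#'   elapsed seconds, ...)
#' @return an object of class `result_bundle`
#' @export
result_bundle <- function(pre_mask, post_mask, spacing,
                          analysis_meta = list()) {
  stopifnot(identical(dim(pre_mask), dim(post_mask)))
  pre_curve <- slice_curve(pre_mask, spacing)
  post_curve <- slice_curve(post_mask, spacing)
  pre_ml <- sum(pre_curve)
  post_ml <- sum(post_curve)
  structure(list(pre_mask = pre_mask, post_mask = post_mask,
                 spacing = spacing,
                 pre_volume_ml = pre_ml, post_volume_ml = post_ml,
                 delta_volume_ml = post_ml - pre_ml,
                 slice_curve_pre = pre_curve, slice_curve_post = post_curve,
                 analysis_meta = analysis_meta),
            class = "result_bundle")
}

.validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (abs(bundle$delta_volume_ml -
          (bundle$post_volume_ml - bundle$pre_volume_ml)) > 1e-9)
    stop("invalid bundle: delta_volume_ml != post - pre")
  if (abs(sum(bundle$slice_curve_pre) - bundle$pre_volume_ml) > 1e-9 ||
      abs(sum(bundle$slice_curve_post) - bundle$post_volume_ml) > 1e-9)
    stop("invalid bundle: slice curves do not sum to totals")
  invisible(TRUE)
}

# logical (slice,row,col) mask -> NIfTI on disk, uint8 {0,1}
.write_mask_nifti <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- c(spacing$slice_thickness_mm,
                           spacing$pixel_spacing_mm)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

.read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img) != 0, dim = dim(img))
}

#' Write a result bundle to disk
#'
#' Masks are written as compressed NIfTI volumes with a {0,1} 8-bit
#' payload; volumes, curves and metadata as a JSON report. Re-reading with
#' [read_bundle()] reproduces the masks bit-exactly.
#'
#' @param bundle a [result_bundle]
#' @param out_dir output directory
#' @param overwrite overwrite an existing bundle? Default `FALSE`
#' @return `out_dir`, invisibly
#' @export
write_bundle <- function(bundle, out_dir, overwrite = FALSE) {
  .validate_bundle(bundle)
  report_path <- file.path(out_dir, "report.json")
  if (file.exists(report_path) && !overwrite)
    stop("refuse to overwrite existing bundle at ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  .write_mask_nifti(bundle$pre_mask, bundle$spacing,
                    file.path(out_dir, "pre_mask.nii.gz"))
  .write_mask_nifti(bundle$post_mask, bundle$spacing,
                    file.path(out_dir, "post_mask.nii.gz"))
  report <- list(
    pre_volume_ml = bundle$pre_volume_ml,
    post_volume_ml = bundle$post_volume_ml,
    delta_volume_ml = bundle$delta_volume_ml,
    slice_curve_pre = bundle$slice_curve_pre,
    slice_curve_post = bundle$slice_curve_post,
    spacing = list(pixel_spacing_mm = bundle$spacing$pixel_spacing_mm,
                   slice_thickness_mm = bundle$spacing$slice_thickness_mm),
    analysis_meta = bundle$analysis_meta
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Read a result bundle written by [write_bundle()]
#'
#' @param dir bundle directory
#' @return a [result_bundle]
#' @export
read_bundle <- function(dir) {
  report <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  spacing <- voxel_spacing(report$spacing$pixel_spacing_mm,
                           report$spacing$slice_thickness_mm)
  result_bundle(.read_mask_nifti(file.path(dir, "pre_mask.nii.gz")),
                .read_mask_nifti(file.path(dir, "post_mask.nii.gz")),
                spacing, analysis_meta = report$analysis_meta)
}
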