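# Volumetry: masks -> mL, per-slice fluid-volume curves, secretory response.

#' Volume of a binary mask in mL
#'
#' Segmented voxel count times the voxel volume from the acquisition
#' geometry: row spacing x col spacing x slice thickness (mm^3), divided by
#' 1000. Full floating-point precision is retained; round for display only.
#'
#' @param mask logical 3D array
#' @param spacing a [voxel_spacing]
#' @return volume in mL
#' @export
compute_volume <- function(mask, spacing) {
  sum(mask) * .voxel_mm3(spacing) / 1000
}

#' Per-slice fluid-volume curve
#'
#' Element i is the volume (mL) of the mask restricted to slice i; the
#' curve sums exactly to [compute_volume()].
#'
#' @inheritParams compute_volume
#' @return numeric vector, one mL value per slice
#' @export
slice_curve <- function(mask, spacing) {
  apply(mask, 1, sum) * .voxel_mm3(spacing) / 1000
}

#' Secretory response
#'
#' Post-secretin minus pre-secretin bowel fluid volume, in mL. May be
#' negative.
#'
#' @param pre_ml,post_ml volumes in mL (>= 0)
#' @return delta volume in mL
#' @export
secretory_response <- function(pre_ml, post_ml) {
  stopifnot(all(pre_ml >= 0), all(post_ml >= 0))
  post_ml - pre_ml
}
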