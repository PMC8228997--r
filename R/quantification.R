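#' Vessel area density
#'
#' The primary readout: vessel pixels inside the cornea mask as a percent
#' of the cornea-mask pixel count (area covered by vessels relative to
#' total cornea area). A pure pixel ratio; no metric conversion enters.
#'
#' @param segmentation a [segment_vessels()] result or a logical matrix.
#' @param cornea_mask logical matrix; defaults to the mask stored in a
#'   `vessel_segmentation` input.
#' @return density in percent, in `[0, 100]`.
#' @export
vessel_density <- function(segmentation, cornea_mask = NULL) {
  m <- if (inherits(segmentation, "vessel_segmentation")) {
    if (is.null(cornea_mask)) cornea_mask <- segmentation$cornea_mask
    segmentation$mask
  } else segmentation
  stopifnot(is.matrix(m), is.matrix(cornea_mask),
            all(dim(m) == dim(cornea_mask)))
  n_cornea <- sum(cornea_mask)
  if (n_cornea == 0) stopf("empty cornea mask")
  100 * sum(m & cornea_mask) / n_cornea
}

#' Total cornea area from an ROI
#'
#' Pixel count of the rasterized annulus between the limbal edge and the
#' inner exclusion border, plus the metric area at the given pixel size.
#'
#' @param roi a [cornea_roi()].
#' @param shape raster `c(height, width)`.
#' @param pixel_size_um microns per pixel (default 1.3).
#' @return list with `area_px` and `area_mm2`
#'   (`area_px * (pixel_size_um / 1000)^2`).
#' @export
cornea_area <- function(roi, shape, pixel_size_um = 1.3) {
  check_scalar_num(pixel_size_um, "pixel_size_um", min = 1e-9)
  n <- sum(rasterize_roi(roi, shape))
  list(area_px = n, area_mm2 = n * (pixel_size_um / 1000)^2)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty (perfect agreement on absence).
#'
#' @param mask_a,mask_b logical matrices of equal shape.
#' @return value in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(is.matrix(mask_a), is.matrix(mask_b))
  if (!all(dim(mask_a) == dim(mask_b)))
    stopf("mask shapes differ: %d x %d vs %d x %d",
          nrow(mask_a), ncol(mask_a), nrow(mask_b), ncol(mask_b))
  a <- sum(mask_a); b <- sum(mask_b)
  if (a + b == 0) return(1)
  2 * sum(mask_a & mask_b) / (a + b)
}

#' Density record for one eye
#'
#' Bundles the per-eye readouts written to the density table.
#'
#' @param eye_id,group,day metadata fields.
#' @param lymphatic,blood `vessel_segmentation` objects (or logical masks)
#'   for the two classes.
#' @param roi the [cornea_roi()] used.
#' @param shape raster shape.
#' @param pixel_size_um microns per pixel.
#' @return one-row data frame with densities, cornea area in pixels and
#'   mm^2.
#' @export
density_record <- function(eye_id, group, day, lymphatic, blood, roi,
                           shape, pixel_size_um = 1.3) {
  cm <- rasterize_roi(roi, shape)
  area <- cornea_area(roi, shape, pixel_size_um)
  data.frame(eye_id = eye_id, group = group, day = day,
             lymphatic_density_pct = vessel_density(
               if (inherits(lymphatic, "vessel_segmentation"))
                 lymphatic$mask else lymphatic, cm),
             blood_density_pct = vessel_density(
               if (inherits(blood, "vessel_segmentation"))
                 blood$mask else blood, cm),
             cornea_area_px = area$area_px,
             cornea_area_mm2 = area$area_mm2,
             stringsAsFactors = FALSE)
}
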