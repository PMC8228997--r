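#' Flat-mount image container
#'
#' An RGB whole-mount fluorescence image of a cornea, with the pixel size
#' and the eye/group/day metadata needed downstream. By the staining
#' convention used throughout, the red channel carries the LYVE-1 (Cy3)
#' lymphatic signal and the green channel the CD31 (FITC) blood-vessel
#' signal; the blue channel is unused counterstain background.
#'
#' @param pixels numeric `H x W x 3` array with intensities in `[0, 1]`.
#' @param pixel_size_um microns per pixel (default 1.3, the acquisition
#'   scale of the reference microscope setup).
#' @param meta named list, typically `eye_id`, `group` (one of `"naive"`,
#'   `"syngeneic"`, `"allogeneic"`) and `day` (0 for baseline, or 7, 14,
#'   21, 28 days post transplantation).
#' @param bit_depth 8 or 16; governs on-disk encoding.
#' @return an object of class `flat_mount_image`.
#' @export
flat_mount_image <- function(pixels, pixel_size_um = 1.3, meta = list(),
                             bit_depth = 8L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("'pixels' must be an H x W x 3 array (got %d dimensions)",
          length(dim(pixels)))
  if (dim(pixels)[3] != 3L)
    stopf("expected 3 channels, got %d", dim(pixels)[3])
  if (any(dim(pixels)[1:2] < 1L)) stopf("image must be non-empty")
  check_scalar_num(pixel_size_um, "pixel_size_um", min = 1e-9)
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 meta = meta, bit_depth = as.integer(bit_depth)),
            class = "flat_mount_image")
}

#' @export
print.flat_mount_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("flat_mount_image: %d x %d px, %d-bit RGB, %.3g um/px\n",
              d[1], d[2], x$bit_depth, x$pixel_size_um))
  if (length(x$meta)) {
    info <- paste(names(x$meta), unlist(lapply(x$meta, format)),
                  sep = "=", collapse = ", ")
    cat(" ", info, "\n")
  }
  invisible(x)
}

#' Read and write flat-mount images
#'
#' TIFF and PNG (by file extension) readers and writers for RGB
#' flat-mount images. Round trips are lossless at the stored bit depth;
#' 16-bit data is supported for TIFF (PNG output is 8-bit).
#' The pixel size is configuration (a function argument), not read from
#' image tags, to avoid TIFF dialect drift.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size_um microns per pixel to attach on read (default 1.3).
#' @param meta metadata list to attach on read.
#' @return `read_image` returns a [flat_mount_image()]; `write_image`
#'   returns `path` invisibly.
#' @export
read_image <- function(path, pixel_size_um = 1.3, meta = list()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, info = FALSE),
    png = png::readPNG(path),
    stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (length(dim(px)) != 3L || dim(px)[3] < 3L)
    stopf("expected 3 channels, got %d",
          if (length(dim(px)) == 2L) 1L else dim(px)[3])
  px <- px[, , 1:3, drop = FALSE]  # drop alpha if present
  # infer stored depth: 16-bit files contain values at 1/65535 granularity
  bits <- if (any(abs(px * 255 - round(px * 255)) > 1e-9)) 16L else 8L
  attributes(px) <- list(dim = dim(px))
  flat_mount_image(px, pixel_size_um = pixel_size_um, meta = meta,
                   bit_depth = bits)
}

#' @param image a [flat_mount_image()].
#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "flat_mount_image"))
  ext <- tolower(tools::file_ext(path))
  px <- image$pixels
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path,
                                   bits.per.sample = image$bit_depth),
    png = {
      if (image$bit_depth == 16L)
        stopf("16-bit images must be written as TIFF")
      png::writePNG(px, path)
    },
    stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  invisible(path)
}

#' Read and write binary masks as PNG
#'
#' Masks (segmentations, ground truth, manual corrections) are stored as
#' single-channel PNGs with background 0 and foreground full intensity.
#'
#' @param path PNG file path.
#' @return `read_mask` returns a logical matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' @param mask logical matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
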