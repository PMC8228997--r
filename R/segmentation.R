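#' Segmentation pipeline parameters
#'
#' Parameters of the operator chain from RGB flat mount to cleaned binary
#' vessel mask: channel isolation, Perona-Malik anisotropic diffusion,
#' median filtering, white top-hat background subtraction, multiscale
#' Frangi vesselness, region-restricted Otsu thresholding and small-object
#' removal. The `"fullsize"` preset carries the acquisition-scale defaults
#' (15 x 15 median kernel, top-hat disc radius 45 px, Frangi scales 20 and
#' 25 px, objects under 50 px removed) for 2048 x 2048 images at
#' 1.3 um/px; the `"test"` preset scales the length parameters down x4
#' for the 512 x 512 synthetic canvas.
#'
#' @param vessel_class `"lymphatic"` (red channel) or `"blood"` (green).
#' @param preset `"fullsize"` or `"test"`; supplies defaults for any
#'   argument left `NULL`.
#' @param diffusion list with `iterations`, `kappa` (conductance scale on
#'   0-255 intensities) and `lambda` (step size, stable at <= 0.25).
#' @param median_kernel odd median window size in pixels.
#' @param tophat_radius_px disc structuring-element radius of the white
#'   top-hat.
#' @param frangi_scales_px Gaussian scales (sigma, pixels) of the
#'   vesselness filter; the response is the per-pixel maximum over scales.
#' @param frangi_beta blob-suppression constant (default 0.5).
#' @param frangi_gamma structure-sensitivity constant; `NULL` sets it per
#'   scale to half the maximum Hessian norm (the standard adaptive
#'   choice).
#' @param min_object_px connected components with fewer pixels than this
#'   are removed (strictly "less than").
#' @param connectivity 4 or 8 (default 8) for component labeling.
#' @param otsu_scope `"roi"` restricts the Otsu histogram to the cornea
#'   mask (default, so background outside the limbus cannot bias the
#'   threshold); `"frame"` uses the whole image.
#' @param otsu_bins histogram bins for Otsu (default 256).
#' @return a validated parameter list of class `pipeline_params`.
#' @export
pipeline_params <- function(vessel_class = c("lymphatic", "blood"),
                            preset = c("fullsize", "test"),
                            diffusion = NULL, median_kernel = NULL,
                            tophat_radius_px = NULL, frangi_scales_px = NULL,
                            frangi_beta = 0.5, frangi_gamma = NULL,
                            min_object_px = NULL, connectivity = 8,
                            otsu_scope = c("roi", "frame"),
                            otsu_bins = 256) {
  vessel_class <- match.arg(vessel_class)
  preset <- match.arg(preset)
  otsu_scope <- match.arg(otsu_scope)
  def <- if (preset == "fullsize") {
    list(diffusion = list(iterations = 10, kappa = 20, lambda = 0.2),
         median_kernel = 15, tophat_radius_px = 45,
         frangi_scales_px = c(20, 25), min_object_px = 50)
  } else {
    list(diffusion = list(iterations = 10, kappa = 20, lambda = 0.2),
         median_kernel = 5, tophat_radius_px = 30,
         frangi_scales_px = c(3, 5, 7), min_object_px = 30)
  }
  if (is.null(diffusion)) diffusion <- def$diffusion
  if (is.null(median_kernel)) median_kernel <- def$median_kernel
  if (is.null(tophat_radius_px)) tophat_radius_px <- def$tophat_radius_px
  if (is.null(frangi_scales_px)) frangi_scales_px <- def$frangi_scales_px
  if (is.null(min_object_px)) min_object_px <- def$min_object_px
  stopifnot(is.list(diffusion),
            all(c("iterations", "kappa", "lambda") %in% names(diffusion)))
  if (diffusion$iterations < 0) stopf("diffusion iterations must be >= 0")
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    stopf("median_kernel must be a positive odd integer")
  check_scalar_num(tophat_radius_px, "tophat_radius_px", min = 1)
  if (length(frangi_scales_px) < 1 || any(frangi_scales_px <= 0))
    stopf("frangi_scales_px must be a non-empty vector of positive scales")
  check_scalar_num(frangi_beta, "frangi_beta", min = 1e-9)
  check_scalar_num(min_object_px, "min_object_px", min = 0)
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  check_scalar_num(otsu_bins, "otsu_bins", min = 2)
  structure(list(vessel_class = vessel_class, preset = preset,
                 diffusion = diffusion,
                 median_kernel = as.integer(median_kernel),
                 tophat_radius_px = as.integer(tophat_radius_px),
                 frangi_scales_px = frangi_scales_px,
                 frangi_beta = frangi_beta, frangi_gamma = frangi_gamma,
                 min_object_px = as.integer(min_object_px),
                 connectivity = as.integer(connectivity),
                 otsu_scope = otsu_scope,
                 otsu_bins = as.integer(otsu_bins)),
            class = "pipeline_params")
}

#' Isolate the channel carrying a vessel class
#'
#' Lymphatics (LYVE-1/Cy3) live in the red channel, blood vessels
#' (CD31/FITC) in the green channel.
#'
#' @param image a [flat_mount_image()].
#' @param vessel_class `"lymphatic"` or `"blood"`.
#' @return the corresponding channel plane as a numeric matrix, unchanged.
#' @export
isolate_channel <- function(image, vessel_class) {
  stopifnot(inherits(image, "flat_mount_image"))
  k <- switch(vessel_class, lymphatic = 1L, blood = 2L,
              stopf("unknown vessel_class '%s'", vessel_class))
  image$pixels[, , k]
}

#' Edge-preserving contrast enhancement by anisotropic diffusion
#'
#' Perona-Malik diffusion with exponential conductance
#' `g(d) = exp(-(d/kappa)^2)`: smooths within regions while preserving
#' (and mildly sharpening) edges. Zero iterations return the input
#' unchanged.
#'
#' @param gray numeric matrix.
#' @param diffusion list with `iterations` (>= 0), `kappa` (> 0, on the
#'   intensity scale of `gray`) and `lambda` (explicit-scheme step size).
#' @return diffused matrix of the same shape.
#' @export
enhance_contrast_diffusion <- function(gray,
                                       diffusion = list(iterations = 10,
                                                        kappa = 20,
                                                        lambda = 0.2)) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  if (diffusion$iterations < 0) stopf("iterations must be >= 0")
  perona_malik_cpp(gray, as.integer(diffusion$iterations),
                   diffusion$kappa, diffusion$lambda)
}

#' Median filter with reflected borders
#'
#' @param gray numeric matrix.
#' @param kernel odd window size (default 15, the acquisition-scale
#'   default).
#' @return filtered matrix; each pixel is the exact median of its
#'   `kernel x kernel` neighborhood under reflect padding.
#' @export
median_filter <- function(gray, kernel = 15) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  if (kernel < 1 || kernel %% 2 == 0)
    stopf("median kernel must be a positive odd integer")
  median_filter_cpp(gray, as.integer(kernel))
}

#' White top-hat background subtraction
#'
#' Subtracts the morphological opening with a flat disc structuring
#' element from the image: slowly varying background is removed while
#' bright structures thinner than the disc survive. Output is
#' non-negative.
#'
#' @param gray numeric matrix.
#' @param radius disc structuring-element radius in pixels (default 45).
#' @return background-subtracted matrix.
#' @export
tophat_subtract <- function(gray, radius = 45) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  check_scalar_num(radius, "radius", min = 1)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  # grayscale morphology operates on [0, 1]; opening commutes with a
  # positive affine map, so rescale, open, and map back
  mn <- min(gray); mx <- max(gray)
  if (mx <= mn) return(matrix(0, nrow(gray), ncol(gray)))
  opened <- as.matrix(EBImage::opening((gray - mn) / (mx - mn), brush))
  pmax(gray - (opened * (mx - mn) + mn), 0)
}

# reflect-padded convolution via EBImage's FFT filter; interior values are
# exact regardless of filter2's own boundary mode because the pad width
# covers the kernel half-width
conv_reflect <- function(x, kern) {
  h <- (dim(kern) - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  if (h[1] >= nr || h[2] >= nc)
    stopf("image (%d x %d) too small for kernel half-width (%d, %d)",
          nr, nc, h[1], h[2])
  padded <- x[c(rev(seq_len(h[1]) + 1), seq_len(nr),
                nr - seq_len(h[1])), , drop = FALSE][,
              c(rev(seq_len(h[2]) + 1), seq_len(nc),
                nc - seq_len(h[2])), drop = FALSE]
  out <- as.matrix(EBImage::filter2(padded, kern, boundary = "circular"))
  out[h[1] + seq_len(nr), h[2] + seq_len(nc)]
}

# 1-D Gaussian and its derivatives on a +/- 3 sigma support
gauss_kernels_1d <- function(sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  x <- seq(-hw, hw)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  d2g <- (x^2 - sigma^2) / sigma^4 * g
  d2g <- d2g - mean(d2g)  # zero DC response despite support truncation
  list(g = g, dg = -x / sigma^2 * g, d2g = d2g)
}

#' Multiscale Frangi vesselness
#'
#' Hessian-eigenvalue tubularity measure for bright vessels on a dark
#' background. At each Gaussian scale sigma the scale-normalized Hessian
#' `sigma^2 H` is computed by Gaussian-derivative convolution (reflected
#' borders); with eigenvalues ordered `|l1| <= |l2|`, the response is
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2+l2^2) / (2 gamma^2)))`
#' where `l2 < 0`, and 0 elsewhere. Responses are combined across scales
#' by the per-pixel maximum.
#'
#' @param gray numeric matrix (bright vessels on dark background).
#' @param scales Gaussian sigmas in pixels (default `c(20, 25)`, the
#'   acquisition-scale default).
#' @param beta blob-suppression constant (default 0.5).
#' @param gamma structure-sensitivity constant; `NULL` (default) uses half
#'   the maximum Frobenius norm of the scale-normalized Hessian, per
#'   scale.
#' @return vesselness response matrix with values in `[0, 1]`.
#' @export
frangi_vesselness <- function(gray, scales = c(20, 25), beta = 0.5,
                              gamma = NULL) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  if (length(scales) < 1 || any(scales <= 0))
    stopf("scales must be a non-empty vector of positive sigmas")
  check_scalar_num(beta, "beta", min = 1e-9)
  best <- matrix(0, nrow(gray), ncol(gray))
  for (s in scales) {
    k <- gauss_kernels_1d(s)
    # rows are y, columns are x; kernel[r, c] = f_y(r) * f_x(c)
    lxx <- s^2 * conv_reflect(gray, outer(k$g, k$d2g))
    lyy <- s^2 * conv_reflect(gray, outer(k$d2g, k$g))
    lxy <- s^2 * conv_reflect(gray, outer(k$dg, k$dg))
    tmp <- sqrt(((lxx - lyy) / 2)^2 + lxy^2)
    m <- (lxx + lyy) / 2
    e1 <- m + tmp; e2 <- m - tmp
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)  # smaller magnitude
    l2 <- ifelse(swap, e1, e2)  # larger magnitude
    s2 <- l1^2 + l2^2
    g <- if (is.null(gamma)) 0.5 * sqrt(max(s2)) else gamma
    # a vanishing Hessian norm everywhere means no structure at all
    v <- if (g <= 1e-8) matrix(0, nrow(gray), ncol(gray)) else {
      rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
      exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * g^2)))
    }
    v[l2 >= 0] <- 0
    best <- pmax(best, v)
  }
  best[best < 1e-9] <- 0  # clamp FFT roundoff so flat regions are exactly 0
  best
}

# Otsu's bin index on a histogram: split after bin t (0-based) maximizing
# between-class variance; first maximum on ties
otsu_bin <- function(counts) {
  n <- sum(counts)
  if (n == 0) stopf("degenerate histogram: no samples")
  k <- length(counts)
  p <- counts / n
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(k))
  mu_t <- mu[k]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  cand <- sigma_b[-k]
  if (max(cand) <= 0) stopf("degenerate histogram: single populated bin")
  which.max(cand) - 1L  # 0-based split index
}

#' Otsu threshold restricted to a region of interest
#'
#' Chooses the threshold maximizing between-class variance of the
#' histogram of response values, restricted to the cornea mask when one is
#' given (so background outside the limbal edge cannot bias the
#' threshold), and returns the binary raster of pixels above it.
#'
#' @param response numeric matrix (e.g. a vesselness response).
#' @param cornea_mask optional logical matrix; histogram and threshold are
#'   computed from `response[cornea_mask]`.
#' @param nbins histogram bins (default 256) on the min-max-normalized
#'   values.
#' @return logical matrix (`response > threshold`), with the chosen
#'   threshold attached as attribute `"threshold"`.
#' @export
otsu_threshold <- function(response, cornea_mask = NULL, nbins = 256) {
  stopifnot(is.matrix(response), is.numeric(response))
  vals <- if (is.null(cornea_mask)) as.vector(response) else {
    stopifnot(all(dim(cornea_mask) == dim(response)))
    response[cornea_mask]
  }
  if (length(vals) == 0) stopf("degenerate histogram: empty region")
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo)
    stopf("degenerate histogram: constant response within the region")
  idx <- pmin(floor((vals - lo) / (hi - lo) * nbins), nbins - 1)
  counts <- tabulate(idx + 1L, nbins)
  t0 <- otsu_bin(counts)
  thr <- lo + (t0 + 1) / nbins * (hi - lo)  # upper edge of split bin
  out <- response > thr
  attr(out, "threshold") <- thr
  out
}

#' Remove out-of-region and small-object pixels from a segmentation
#'
#' Zeroes pixels outside the cornea mask (erroneous segmentation outside
#' the limbal edge or inside the central exclusion region), then removes
#' connected components with strictly fewer than `min_object_px` pixels.
#'
#' @param binary logical matrix.
#' @param cornea_mask logical matrix of the same shape.
#' @param min_object_px minimum retained component size (default 50;
#'   a 50-pixel component is kept, a 49-pixel one removed).
#' @param connectivity 4 or 8 (default 8).
#' @return cleaned logical matrix.
#' @export
clean_segmentation <- function(binary, cornea_mask, min_object_px = 50,
                               connectivity = 8) {
  stopifnot(is.matrix(binary), is.matrix(cornea_mask),
            all(dim(binary) == dim(cornea_mask)))
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  m <- binary & cornea_mask
  if (min_object_px <= 1 || !any(m)) return(m)
  lab <- label_components_cpp(matrix(as.integer(m), nrow(m), ncol(m)),
                              as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Apply manual correction masks to a segmentation
#'
#' Replays externally drawn corrections: pixels in `add_mask` are added,
#' pixels in `remove_mask` removed. The two masks must be disjoint.
#'
#' @param segmentation a [segment_vessels()] result or a logical matrix.
#' @param add_mask,remove_mask logical matrices of the segmentation's
#'   shape, or `NULL`.
#' @return the corrected object; a `vessel_segmentation` input has its
#'   `corrected` flag set when any correction pixels were applied.
#' @export
apply_corrections <- function(segmentation, add_mask = NULL,
                              remove_mask = NULL) {
  is_seg <- inherits(segmentation, "vessel_segmentation")
  m <- if (is_seg) segmentation$mask else segmentation
  stopifnot(is.matrix(m))
  touched <- FALSE
  if (!is.null(add_mask) || !is.null(remove_mask)) {
    if (!is.null(add_mask) && !is.null(remove_mask) &&
        any(add_mask & remove_mask))
      stopf("add and remove correction masks overlap")
    if (!is.null(add_mask)) {
      stopifnot(all(dim(add_mask) == dim(m)))
      touched <- touched || any(add_mask)
      m <- m | add_mask
    }
    if (!is.null(remove_mask)) {
      stopifnot(all(dim(remove_mask) == dim(m)))
      touched <- touched || any(remove_mask)
      m <- m & !remove_mask
    }
  }
  if (is_seg) {
    segmentation$mask <- m
    segmentation$corrected <- segmentation$corrected || touched
    segmentation
  } else m
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("segmentation stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Segment vessels from a flat-mount image
#'
#' The full deterministic operator chain: channel isolation, anisotropic
#' diffusion, median filtering, white top-hat background subtraction,
#' multiscale Frangi vesselness, Otsu thresholding on the
#' cornea-restricted histogram, and removal of out-of-region pixels and
#' small objects. Intensities are processed on a 0-255 scale (matching
#' the diffusion `kappa` convention).
#'
#' @param image a [flat_mount_image()].
#' @param roi a [cornea_roi()].
#' @param params a [pipeline_params()].
#' @return an object of class `vessel_segmentation`: `mask` (logical),
#'   `vessel_class`, `params`, `threshold` (chosen Otsu level),
#'   `cornea_mask`, and `corrected` flag (FALSE until
#'   [apply_corrections()] changes pixels).
#' @export
segment_vessels <- function(image, roi, params = pipeline_params()) {
  stopifnot(inherits(image, "flat_mount_image"), inherits(roi, "cornea_roi"),
            inherits(params, "pipeline_params"))
  cornea_mask <- run_stage("rasterize_roi",
                           rasterize_roi(roi, dim(image$pixels)[1:2]))
  gray <- run_stage("isolate_channel",
                    isolate_channel(image, params$vessel_class)) * 255
  gray <- run_stage("diffusion",
                    enhance_contrast_diffusion(gray, params$diffusion))
  gray <- run_stage("median", median_filter(gray, params$median_kernel))
  gray <- run_stage("tophat", tophat_subtract(gray, params$tophat_radius_px))
  resp <- run_stage("frangi",
                    frangi_vesselness(gray, params$frangi_scales_px,
                                      params$frangi_beta,
                                      params$frangi_gamma))
  # a degenerate (constant) response within the cornea means no tubular
  # structure at all: an empty segmentation, not a failure
  binary <- tryCatch(
    otsu_threshold(
      resp,
      cornea_mask = if (params$otsu_scope == "roi") cornea_mask else NULL,
      nbins = params$otsu_bins),
    error = function(e) {
      if (grepl("degenerate histogram", conditionMessage(e)))
        matrix(FALSE, nrow(resp), ncol(resp))
      else stopf("segmentation stage 'otsu' failed: %s", conditionMessage(e))
    })
  thr <- attr(binary, "threshold")
  mask <- run_stage("clean",
                    clean_segmentation(binary, cornea_mask,
                                       params$min_object_px,
                                       params$connectivity))
  structure(list(mask = mask, vessel_class = params$vessel_class,
                 params = params, threshold = thr,
                 cornea_mask = cornea_mask, corrected = FALSE),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "vessel_segmentation (%s): %d px in mask (%.2f%% of cornea)%s\n",
    x$vessel_class, sum(x$mask),
    100 * sum(x$mask) / max(1, sum(x$cornea_mask)),
    if (x$corrected) ", manually corrected" else ""))
  invisible(x)
}
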