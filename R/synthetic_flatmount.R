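#' Parameters of the synthetic vessel-tree generator
#'
#' The generator grows dendritic vessel trees into the cornea as biased
#' random walks: trunks start at entry points on the limbal (outer) border,
#' drift toward the cornea center, meander, and bifurcate with a fixed
#' per-step probability; tube radius shrinks by a decay factor at each
#' branching level. This is the simplest fully parameter-controlled model
#' that reproduces the limbus-anchored ingrowth morphology of corneal
#' neovascularization.
#'
#' @param n_seeds number of limbal entry points (0 gives an empty tree).
#' @param max_depth maximum branching depth (trunk = level 0).
#' @param branch_prob per-step bifurcation probability in `[0, 1]`.
#' @param step_len_px growth step length in pixels.
#' @param radius_px trunk tube radius in pixels (> 0).
#' @param radius_decay multiplicative radius decay per branching level.
#' @param inward_bias drift weight toward the cornea center in `[0, 1]`;
#'   0 is an unbiased walk, 1 heads straight for the center.
#' @param wiggle_sd standard deviation (radians) of the per-step heading
#'   noise.
#' @param seed RNG seed; the generated tree is a pure function of the
#'   parameters and this seed.
#' @return a validated parameter list of class `vessel_tree_params`.
#' @export
vessel_tree_params <- function(n_seeds = 12, max_depth = 3,
                               branch_prob = 0.06, step_len_px = 6,
                               radius_px = 3.5, radius_decay = 0.85,
                               inward_bias = 0.5, wiggle_sd = 0.15,
                               seed = NULL) {
  check_scalar_num(n_seeds, "n_seeds", min = 0)
  check_scalar_num(max_depth, "max_depth", min = 0)
  check_scalar_num(branch_prob, "branch_prob", min = 0, max = 1)
  check_scalar_num(step_len_px, "step_len_px", min = 1e-6)
  check_scalar_num(radius_px, "radius_px", min = 1e-6)
  check_scalar_num(radius_decay, "radius_decay", min = 0, max = 1)
  check_scalar_num(inward_bias, "inward_bias", min = 0, max = 1)
  check_scalar_num(wiggle_sd, "wiggle_sd", min = 0)
  structure(list(n_seeds = as.integer(n_seeds),
                 max_depth = as.integer(max_depth),
                 branch_prob = branch_prob, step_len_px = step_len_px,
                 radius_px = radius_px, radius_decay = radius_decay,
                 inward_bias = inward_bias, wiggle_sd = wiggle_sd,
                 seed = seed),
            class = "vessel_tree_params")
}

# arc-length-uniform points on a closed polygon boundary
sample_on_boundary <- function(poly, n) {
  e <- poly_edges(poly)
  len <- sqrt(rowSums((e$b - e$a)^2))
  cum <- c(0, cumsum(len))
  u <- runif(n, 0, cum[length(cum)])
  t(vapply(u, function(ui) {
    i <- findInterval(ui, cum, rightmost.closed = TRUE)
    f <- (ui - cum[i]) / len[i]
    e$a[i, ] + f * (e$b[i, ] - e$a[i, ])
  }, numeric(2)))
}

#' Generate a synthetic vessel tree with ground-truth mask
#'
#' Grows branching tubes from the limbal border inward (see
#' [vessel_tree_params()]), rasterizes them at their per-level radii and
#' clips the result to the corneal annulus defined by `roi`.
#'
#' @param roi a [cornea_roi()].
#' @param shape raster `c(height, width)`.
#' @param params a [vessel_tree_params()].
#' @return a list with `mask` (logical matrix, clipped to the annulus),
#'   `centerlines` (data frame `x`, `y`, `radius`, `branch`),
#'   `cornea_mask`, and `true_density_pct` (vessel pixels as percent of
#'   cornea-mask pixels).
#' @export
generate_vessel_tree <- function(roi, shape, params = vessel_tree_params()) {
  stopifnot(inherits(roi, "cornea_roi"), inherits(params, "vessel_tree_params"))
  cornea_mask <- rasterize_roi(roi, shape)
  if (!any(cornea_mask)) stopf("degenerate ROI: rasterized cornea mask is empty")
  center <- colMeans(roi$outer)
  out <- with_seed(params$seed, grow_tree(roi, shape, params, center))
  mask <- out$mask & cornea_mask
  list(mask = mask, centerlines = out$centerlines, cornea_mask = cornea_mask,
       true_density_pct = 100 * sum(mask) / sum(cornea_mask))
}

grow_tree <- function(roi, shape, params, center) {
  h <- shape[1]; w <- shape[2]
  pts_x <- numeric(0); pts_y <- numeric(0); pts_r <- numeric(0)
  br_id <- integer(0)
  empty <- params$n_seeds == 0L
  if (!empty) {
    seeds <- sample_on_boundary(roi$outer, params$n_seeds)
    # stack of active branches: position, heading, level
    stack <- lapply(seq_len(params$n_seeds), function(i) {
      p <- seeds[i, ]
      d <- center - p
      list(pos = p, dir = d / sqrt(sum(d^2)), level = 0L)
    })
    max_steps <- ceiling(2 * sqrt(sum(shape^2)) / params$step_len_px)
    branch_n <- 0L
    while (length(stack) > 0L) {
      b <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      branch_n <- branch_n + 1L
      pos <- b$pos; dir <- b$dir
      radius <- params$radius_px * params$radius_decay^b$level
      for (s in seq_len(max_steps)) {
        to_c <- center - pos
        nc <- sqrt(sum(to_c^2))
        if (nc > 1e-9) to_c <- to_c / nc
        dir <- (1 - params$inward_bias) * dir + params$inward_bias * to_c
        ang <- atan2(dir[2], dir[1]) + rnorm(1, 0, params$wiggle_sd)
        dir <- c(cos(ang), sin(ang))
        nxt <- pos + params$step_len_px * dir
        # stop at the inner exclusion border or when leaving the cornea
        if (!point_in_polygon(nxt[1], nxt[2], roi$outer)) break
        if (!is.null(roi$inner) && point_in_polygon(nxt[1], nxt[2], roi$inner))
          break
        # dense samples along the step for a continuous tube
        nsub <- max(2L, ceiling(params$step_len_px))
        f <- seq(0, 1, length.out = nsub)[-1]
        pts_x <- c(pts_x, pos[1] + f * (nxt[1] - pos[1]))
        pts_y <- c(pts_y, pos[2] + f * (nxt[2] - pos[2]))
        pts_r <- c(pts_r, rep(radius, nsub - 1L))
        br_id <- c(br_id, rep(branch_n, nsub - 1L))
        pos <- nxt
        if (b$level < params$max_depth && runif(1) < params$branch_prob) {
          side <- sample(c(-1, 1), 1)
          bang <- ang + side * runif(1, pi / 6, pi / 3)
          stack[[length(stack) + 1L]] <-
            list(pos = pos, dir = c(cos(bang), sin(bang)),
                 level = b$level + 1L)
        }
      }
    }
  }
  mask <- if (length(pts_x) == 0L) {
    matrix(FALSE, h, w)
  } else {
    stamp_disks_cpp(as.integer(round(pts_y)), as.integer(round(pts_x)),
                    pts_r, h, w)
  }
  list(mask = mask,
       centerlines = data.frame(x = pts_x, y = pts_y, radius = pts_r,
                                branch = br_id))
}

#' Ground truth of a synthetic flat mount
#'
#' Bundles the lymphatic and blood-vessel ground-truth masks with the
#' cornea mask and the true per-class densities (vessel pixels as percent
#' of cornea-mask pixels). Masks are clipped to the cornea annulus.
#'
#' @param lymphatic_mask,blood_mask logical matrices.
#' @param cornea_mask logical matrix (the rasterized ROI).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(lymphatic_mask, blood_mask, cornea_mask) {
  stopifnot(is.matrix(lymphatic_mask), is.matrix(blood_mask),
            is.matrix(cornea_mask),
            all(dim(lymphatic_mask) == dim(cornea_mask)),
            all(dim(blood_mask) == dim(cornea_mask)))
  if (!any(cornea_mask)) stopf("empty cornea mask")
  lymphatic_mask <- lymphatic_mask & cornea_mask
  blood_mask <- blood_mask & cornea_mask
  structure(list(
    lymphatic_mask = lymphatic_mask, blood_mask = blood_mask,
    cornea_mask = cornea_mask,
    true_density_pct = c(
      lymphatic = 100 * sum(lymphatic_mask) / sum(cornea_mask),
      blood = 100 * sum(blood_mask) / sum(cornea_mask))),
    class = "ground_truth")
}

#' Rendering parameters for synthetic flat mounts
#'
#' Controls how ground-truth vessel masks are turned into an RGB
#' fluorescence image: each vessel class is rendered into its assigned
#' channel with a Gaussian cross-section profile on top of a vignetted
#' background, then bright blob artifacts (emulating staining artifacts
#' inside and outside the region of interest) and Gaussian speckle noise
#' are added. The blue channel carries dim structureless background only.
#'
#' @param image_size_px raster `c(height, width)`.
#' @param pixel_size_um microns per pixel (default 1.3).
#' @param channel_assignment named character vector mapping vessel classes
#'   to channels; default `c(lymphatic = "red", blood = "green")`, the
#'   LYVE-1/Cy3 and CD31/FITC staining convention. The two classes must
#'   use distinct channels.
#' @param background_level base background intensity in `[0, 1]`.
#' @param vignette_strength radial intensity falloff (0 = flat field).
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param artifact_count number of bright blob artifacts.
#' @param vessel_amplitude peak vessel intensity above background.
#' @param profile_sigma_px Gaussian blur sigma giving tubes their
#'   cross-section profile.
#' @param seed RNG seed for noise and artifact placement.
#' @return a validated parameter list of class `render_params`.
#' @export
render_params <- function(image_size_px = c(512, 512), pixel_size_um = 1.3,
                          channel_assignment = c(lymphatic = "red",
                                                 blood = "green"),
                          background_level = 0.08, vignette_strength = 0.25,
                          noise_sd = 0.02, artifact_count = 5,
                          vessel_amplitude = 0.7, profile_sigma_px = 2,
                          seed = NULL) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 1))
  check_scalar_num(pixel_size_um, "pixel_size_um", min = 1e-9)
  check_scalar_num(background_level, "background_level", min = 0, max = 1)
  check_scalar_num(vignette_strength, "vignette_strength", min = 0, max = 1)
  check_scalar_num(noise_sd, "noise_sd", min = 0)
  check_scalar_num(artifact_count, "artifact_count", min = 0)
  check_scalar_num(vessel_amplitude, "vessel_amplitude", min = 0, max = 1)
  check_scalar_num(profile_sigma_px, "profile_sigma_px", min = 1e-6)
  cls <- c("lymphatic", "blood")
  if (!all(cls %in% names(channel_assignment)))
    stopf("channel_assignment must name both 'lymphatic' and 'blood'")
  ch <- channel_assignment[cls]
  if (!all(ch %in% c("red", "green", "blue")))
    stopf("channels must be 'red', 'green' or 'blue'")
  if (ch[1] == ch[2])
    stopf("channel collision: both vessel classes assigned to '%s'", ch[1])
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, channel_assignment = ch,
                 background_level = background_level,
                 vignette_strength = vignette_strength, noise_sd = noise_sd,
                 artifact_count = as.integer(artifact_count),
                 vessel_amplitude = vessel_amplitude,
                 profile_sigma_px = profile_sigma_px, seed = seed),
            class = "render_params")
}

channel_index <- function(name) match(name, c("red", "green", "blue"))

#' Render a synthetic flat-mount image from ground truth
#'
#' @param gt a [ground_truth()].
#' @param roi the [cornea_roi()] the ground truth was generated in (used
#'   to place artifacts both inside and outside the annulus).
#' @param params a [render_params()].
#' @param meta metadata list attached to the image.
#' @return a [flat_mount_image()] (8-bit quantized intensities).
#' @export
render_flat_mount <- function(gt, roi, params = render_params(),
                              meta = list()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(params, "render_params"))
  h <- params$image_size_px[1]; w <- params$image_size_px[2]
  if (!all(dim(gt$cornea_mask) == c(h, w)))
    stopf("ground-truth masks (%d x %d) do not match image_size_px (%d x %d)",
          nrow(gt$cornea_mask), ncol(gt$cornea_mask), h, w)
  with_seed(params$seed, {
    # vignetted background field
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
    vig <- 1 - params$vignette_strength * d2 / max(d2)
    base <- params$background_level * vig
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- base; img[, , 2] <- base
    img[, , 3] <- 0.5 * base  # dim counterstain-free blue channel
    # Gaussian-profile tubes per class
    for (cls in c("lymphatic", "blood")) {
      m <- if (cls == "lymphatic") gt$lymphatic_mask else gt$blood_mask
      if (any(m)) {
        prof <- as.matrix(EBImage::gblur(
          matrix(as.numeric(m), h, w), sigma = params$profile_sigma_px))
        prof <- prof / max(prof)
        k <- channel_index(params$channel_assignment[[cls]])
        img[, , k] <- img[, , k] + params$vessel_amplitude * prof
      }
    }
    # bright blob artifacts, inside and outside the annulus
    if (params$artifact_count > 0) {
      ax <- runif(params$artifact_count, 1, w)
      ay <- runif(params$artifact_count, 1, h)
      ar <- runif(params$artifact_count, 4, 12)
      aa <- runif(params$artifact_count, 0.3, 0.7)
      ak <- sample(channel_index(params$channel_assignment),
                   params$artifact_count, replace = TRUE)
      for (i in seq_len(params$artifact_count)) {
        rr <- ceiling(3 * ar[i])
        r0 <- max(1, round(ay[i]) - rr):min(h, round(ay[i]) + rr)
        c0 <- max(1, round(ax[i]) - rr):min(w, round(ax[i]) + rr)
        dd <- outer((r0 - ay[i])^2, (c0 - ax[i])^2, `+`)
        img[r0, c0, ak[i]] <- img[r0, c0, ak[i]] +
          aa[i] * exp(-dd / (2 * ar[i]^2))
      }
    }
    if (params$noise_sd > 0)
      img <- img + rnorm(length(img), 0, params$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255  # 8-bit quantization
    flat_mount_image(img, pixel_size_um = params$pixel_size_um, meta = meta)
  })
}

#' One-call synthetic flat mount with known ground truth
#'
#' Convenience generator used throughout testing and validation: builds a
#' circular cornea ROI, grows lymphatic and blood vessel trees, and renders
#' the RGB image. The `"test"` preset is a 512 x 512 canvas; `"fullsize"`
#' is the 2048 x 2048 acquisition-scale canvas (cornea diameter about
#' 2.6 mm at 1.3 um/px), with all length parameters scaled x4.
#'
#' @param seed integer seed; every random choice derives from it.
#' @param preset `"test"` or `"fullsize"`.
#' @param n_seeds_lymphatic,n_seeds_blood limbal entry points per class.
#' @param noise_sd,artifact_count overrides of the render defaults.
#' @param meta metadata list for the rendered image.
#' @return list with `image` ([flat_mount_image()]), `roi`
#'   ([cornea_roi()]), `gt` ([ground_truth()]).
#' @export
simulate_flat_mount <- function(seed = 1, preset = c("test", "fullsize"),
                                n_seeds_lymphatic = 10, n_seeds_blood = 8,
                                noise_sd = 0.02, artifact_count = 5,
                                meta = list()) {
  preset <- match.arg(preset)
  sc <- if (preset == "test") 1 else 4
  shape <- c(512, 512) * sc
  roi <- circular_roi(shape, outer_radius = 230 * sc,
                      inner_radius = 60 * sc)
  lp <- vessel_tree_params(n_seeds = n_seeds_lymphatic,
                           step_len_px = 6 * sc, radius_px = 3.5 * sc,
                           seed = seed)
  bp <- vessel_tree_params(n_seeds = n_seeds_blood,
                           step_len_px = 6 * sc, radius_px = 3 * sc,
                           seed = seed + 1000003L)
  lt <- generate_vessel_tree(roi, shape, lp)
  bt <- generate_vessel_tree(roi, shape, bp)
  gt <- ground_truth(lt$mask, bt$mask, lt$cornea_mask)
  rp <- render_params(image_size_px = shape, noise_sd = noise_sd,
                      artifact_count = artifact_count,
                      profile_sigma_px = 2 * sc,
                      seed = seed + 2000003L)
  list(image = render_flat_mount(gt, roi, rp, meta = meta),
       roi = roi, gt = gt)
}
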