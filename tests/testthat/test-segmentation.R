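rand_gray <- function(seed, n = 32, scale = 255) {
  set.seed(seed)
  matrix(runif(n * n, 0, scale), n, n)
}

test_that("channel isolation projects the assigned plane exactly", {
  set.seed(1)
  px <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  img <- flat_mount_image(px)
  expect_identical(isolate_channel(img, "lymphatic"), px[, , 1])
  expect_identical(isolate_channel(img, "blood"), px[, , 2])
  # pure-red image: full signal for lymphatic, nothing for blood
  red <- array(0, dim = c(8, 8, 3)); red[, , 1] <- 1
  img2 <- flat_mount_image(red)
  expect_true(all(isolate_channel(img2, "lymphatic") == 1))
  expect_true(all(isolate_channel(img2, "blood") == 0))
  expect_error(isolate_channel(img2, "stromal"), "unknown vessel_class")
})

test_that("diffusion: identity at zero iterations, inert on constants, and edge-preserving", {
  x <- rand_gray(2)
  expect_identical(
    enhance_contrast_diffusion(x, list(iterations = 0, kappa = 20,
                                       lambda = 0.2)), x)
  const <- matrix(77, 16, 16)
  expect_equal(
    enhance_contrast_diffusion(const, list(iterations = 25, kappa = 20,
                                           lambda = 0.2)), const)
  expect_error(
    enhance_contrast_diffusion(x, list(iterations = -1, kappa = 20,
                                       lambda = 0.2)), ">= 0")

  # noisy step edge: in-region variance shrinks, the edge survives
  set.seed(3)
  step <- cbind(matrix(50, 64, 32), matrix(150, 64, 32)) +
    matrix(rnorm(64 * 64, 0, 5), 64, 64)
  sm <- enhance_contrast_diffusion(step, list(iterations = 10, kappa = 20,
                                              lambda = 0.2))
  expect_lt(var(as.vector(sm[, 1:28])), var(as.vector(step[, 1:28])))
  edge_mag <- mean(sm[, 33] - sm[, 32])
  expect_gt(edge_mag, 0.8 * 100)   # within 20% of the clean 100-unit step
  expect_lt(edge_mag, 1.2 * 100)
})

test_that("median filter matches the brute-force neighborhood oracle", {
  expect_error(median_filter(rand_gray(1), kernel = 4), "odd")
  const <- matrix(9, 20, 20)
  expect_equal(median_filter(const, 15), const)
  # single hot pixel in a flat field is removed
  hot <- matrix(10, 31, 31); hot[16, 16] <- 255
  expect_equal(median_filter(hot, 15), matrix(10, 31, 31))
  for (seed in 1:5) {
    x <- rand_gray(seed)
    expect_identical(median_filter(x, 3), oracle_median(x, 3))
    expect_identical(median_filter(x, 5), oracle_median(x, 5))
  }
})

test_that("top-hat removes smooth background but keeps small bright features", {
  const <- matrix(42, 64, 64)
  expect_equal(tophat_subtract(const, 45), matrix(0, 64, 64))
  # bright disc of radius 5 on dark field survives a radius-45 top-hat
  disc <- matrix(0, 128, 128)
  for (r in 1:128) for (c in 1:128)
    if ((r - 64)^2 + (c - 64)^2 <= 25) disc[r, c] <- 200
  th <- tophat_subtract(disc, 45)
  expect_equal(th, disc)
  # a wide smooth ramp is almost entirely removed (the residual that
  # remains is the slope-times-radius edge effect at the image border)
  ramp <- matrix(rep(seq(0, 100, length.out = 512), each = 128), 128, 512,
                 byrow = FALSE)
  resid <- tophat_subtract(ramp, 45)
  expect_lt(max(resid), 0.10 * 100)
  interior <- resid[, 60:450]
  expect_lt(max(interior), 1)
})

test_that("Frangi vesselness prefers ridges over blobs and is rotation-tolerant", {
  expect_true(all(frangi_vesselness(matrix(5, 64, 64), scales = 3) == 0))
  expect_error(frangi_vesselness(rand_gray(1), scales = c(3, -1)),
               "positive")

  n <- 129; s <- 4
  xy <- seq_len(n) - 65
  ridge <- 100 * exp(-outer(xy^2, rep(0, n), `+`) / (2 * s^2))
  blob <- 100 * exp(-outer(xy^2, xy^2, `+`) / (2 * s^2))
  vr <- frangi_vesselness(ridge, scales = s)
  vb <- frangi_vesselness(blob, scales = s)
  expect_gt(vr[65, 65], vb[65, 65])

  # 45-degree ridge: centerline response within 10% of the axis-aligned one
  diag_dist2 <- outer(xy, xy, function(a, b) (a - b)^2 / 2)
  ridge45 <- 100 * exp(-diag_dist2 / (2 * s^2))
  v45 <- frangi_vesselness(ridge45, scales = s)
  expect_lt(abs(v45[65, 65] - vr[65, 65]) / vr[65, 65], 0.10)
})

test_that("Otsu splits a perfectly bimodal image at the gap and rejects constants", {
  set.seed(8)
  vals <- sample(c(rep(0.1, 500), rep(0.9, 500)))
  img <- matrix(vals, 25, 40)
  bin <- otsu_threshold(img)
  expect_equal(sum(bin != (img > 0.5)), 0)
  expect_true(attr(bin, "threshold") > 0.1 && attr(bin, "threshold") < 0.9)
  expect_error(otsu_threshold(matrix(1, 10, 10)), "degenerate histogram")
  # restricted scope: constant inside the mask is degenerate even if the
  # frame is not
  img2 <- matrix(runif(100), 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:3, 1:3] <- TRUE
  img2[mask] <- 0.5
  expect_error(otsu_threshold(img2, mask), "degenerate histogram")
})

test_that("Otsu bin choice matches exhaustive within-class-variance search", {
  for (seed in 1:20) {
    set.seed(seed)
    counts <- rpois(64, lambda = sample(c(2, 20), 64, replace = TRUE))
    if (sum(counts > 0) < 2) next
    expect_identical(corneaquant:::otsu_bin(counts),
                     oracle_otsu_bin(counts))
  }
})

test_that("cleaning enforces the strict under-50-pixel rule and ROI clipping", {
  m <- matrix(FALSE, 40, 80)
  m[2:8, 2:8] <- TRUE              # 49 px: removed
  m[12:18, 42:48] <- TRUE          # 49 px...
  m[12, 49] <- TRUE                # ...plus 1 = 50 px: kept
  cm <- matrix(TRUE, 40, 80)
  out <- clean_segmentation(m, cm, min_object_px = 50)
  expect_equal(sum(out), 50)
  expect_true(all(which(out) %in% which(m)))

  # vessel crossing the limbal edge is clipped; the remainder survives
  vessel <- matrix(FALSE, 40, 80)
  vessel[15:20, 1:30] <- TRUE      # 6 x 30 bar
  cm2 <- matrix(FALSE, 40, 80); cm2[, 20:80] <- TRUE
  out2 <- clean_segmentation(vessel, cm2, min_object_px = 50)
  expect_equal(sum(out2), 6 * 11)
  expect_true(all(cm2[out2]))
})

test_that("component filtering matches the flood-fill oracle on random rasters", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(48 * 48) > 0.55, 48, 48)
    cm <- matrix(runif(48 * 48) > 0.1, 48, 48)
    for (conn in c(4, 8)) {
      expect_identical(clean_segmentation(m, cm, 8, conn),
                       oracle_clean(m, cm, 8, conn))
    }
  }
})

test_that("manual corrections apply set algebra and track the corrected flag", {
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  add <- matrix(FALSE, 10, 10); add[8, 8] <- TRUE
  rem <- matrix(FALSE, 10, 10); rem[3, 3] <- TRUE
  expect_identical(apply_corrections(m), m)
  out <- apply_corrections(m, add, rem)
  expect_true(out[8, 8]); expect_false(out[3, 3])
  expect_error(apply_corrections(m, add, add), "overlap")
  # removing the whole segmentation empties it
  expect_false(any(apply_corrections(m, remove_mask = m)))

  sim <- simulate_flat_mount(seed = 2)
  seg <- segment_vessels(sim$image, sim$roi,
                         pipeline_params("lymphatic", "test"))
  expect_false(seg$corrected)
  seg2 <- apply_corrections(seg, add_mask = matrix(FALSE, 512, 512))
  expect_false(seg2$corrected)   # no pixels changed, flag stays unset
  addbig <- matrix(FALSE, 512, 512); addbig[256, 256] <- TRUE
  expect_true(apply_corrections(seg, add_mask = addbig)$corrected)
})

test_that("the composed pipeline is deterministic and clips to the ROI", {
  sim <- simulate_flat_mount(seed = 4)
  p <- pipeline_params("lymphatic", "test")
  s1 <- segment_vessels(sim$image, sim$roi, p)
  s2 <- segment_vessels(sim$image, sim$roi, p)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$threshold, s2$threshold)
  expect_true(all(s1$cornea_mask[s1$mask]))
  # no connected component below the minimum object size
  lab <- corneaquant:::label_components_cpp(
    matrix(as.integer(s1$mask), 512, 512), 8L)
  expect_true(all(tabulate(lab[lab > 0]) >= p$min_object_px))
})

test_that("structure outside the limbal polygon yields an empty segmentation", {
  # bright tube in the image corner, far from the ROI
  px <- array(0, dim = c(256, 256, 3))
  px[10:16, 10:120, 1] <- 0.9
  img <- flat_mount_image(px)
  roi <- circular_roi(c(256, 256), outer_radius = 60, inner_radius = 0)
  seg <- segment_vessels(img, roi, pipeline_params("lymphatic", "test"))
  expect_false(any(seg$mask))
})

test_that("pipeline failures name their stage", {
  sim <- simulate_flat_mount(seed = 4)
  p <- pipeline_params("lymphatic", "test")
  p$median_kernel <- 4L  # corrupt after construction
  expect_error(segment_vessels(sim$image, sim$roi, p), "stage 'median'")
})
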