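small_roi <- function() circular_roi(c(128, 128), outer_radius = 55,
                                     inner_radius = 15)

test_that("no seeds means no vessels and zero density", {
  tree <- generate_vessel_tree(small_roi(), c(128, 128),
                               vessel_tree_params(n_seeds = 0, seed = 1))
  expect_false(any(tree$mask))
  expect_equal(tree$true_density_pct, 0)
})

test_that("vessel trees are a pure function of parameters and seed", {
  p <- vessel_tree_params(n_seeds = 5, seed = 42)
  t1 <- generate_vessel_tree(small_roi(), c(128, 128), p)
  t2 <- generate_vessel_tree(small_roi(), c(128, 128), p)
  expect_identical(t1$mask, t2$mask)
  expect_identical(t1$centerlines, t2$centerlines)
  # a different seed gives a different tree
  t3 <- generate_vessel_tree(small_roi(), c(128, 128),
                             vessel_tree_params(n_seeds = 5, seed = 43))
  expect_false(identical(t1$mask, t3$mask))
})

test_that("vessels start at the limbus, stay in the annulus, and grow inward", {
  roi <- small_roi()
  tree <- generate_vessel_tree(roi, c(128, 128),
                               vessel_tree_params(n_seeds = 8, seed = 7))
  cm <- rasterize_roi(roi, c(128, 128))
  expect_true(all(cm[tree$mask]))  # confined to the annulus
  # centerline starts lie on the outer boundary (distance ~outer radius)
  first_pts <- tree$centerlines[!duplicated(tree$centerlines$branch), ]
  d <- sqrt((first_pts$x - 64.5)^2 + (first_pts$y - 64.5)^2)
  expect_true(all(d > 40))
  # and some growth reaches well inside
  expect_lt(min(sqrt((tree$centerlines$x - 64.5)^2 +
                       (tree$centerlines$y - 64.5)^2)), 35)
})

test_that("true density is non-decreasing in seed count, in expectation", {
  roi <- small_roi()
  levels <- c(2, 8, 14, 20)
  mean_density <- vapply(levels, function(ns) {
    mean(vapply(1:10, function(s)
      generate_vessel_tree(roi, c(128, 128),
                           vessel_tree_params(n_seeds = ns,
                                              seed = s))$true_density_pct,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_density) > 0))
})

test_that("degenerate ROI is rejected", {
  # outer polygon entirely between pixel centers -> empty raster
  tiny <- cornea_roi(cbind(c(1.1, 1.4, 1.4, 1.1), c(1.1, 1.1, 1.4, 1.4)))
  expect_error(generate_vessel_tree(tiny, c(16, 16), vessel_tree_params()),
               "degenerate ROI")
})

test_that("stored ground-truth density equals recomputation from the masks", {
  sim <- simulate_flat_mount(seed = 5, noise_sd = 0, artifact_count = 0)
  expect_identical(
    unname(sim$gt$true_density_pct["lymphatic"]),
    100 * sum(sim$gt$lymphatic_mask) / sum(sim$gt$cornea_mask))
  expect_identical(
    unname(sim$gt$true_density_pct["blood"]),
    100 * sum(sim$gt$blood_mask) / sum(sim$gt$cornea_mask))
})

test_that("rendering an empty ground truth gives the pure background field", {
  roi <- small_roi()
  cm <- rasterize_roi(roi, c(128, 128))
  gt <- ground_truth(matrix(FALSE, 128, 128), matrix(FALSE, 128, 128), cm)
  rp <- render_params(image_size_px = c(128, 128), noise_sd = 0,
                      artifact_count = 0, seed = 1)
  img <- render_flat_mount(gt, roi, rp)$pixels
  # red and green are the identical vignetted background; blue is half
  expect_identical(img[, , 1], img[, , 2])
  expect_true(all(abs(img[, , 3] - round(img[, , 1] * 0.5 * 255) / 255)
                  <= 1 / 255))
  # radially symmetric vignette: corners darker than center
  expect_lt(img[1, 1, 1], img[64, 64, 1])
})

test_that("vessels render brighter than background in their channel", {
  roi <- small_roi()
  tree <- generate_vessel_tree(roi, c(128, 128),
                               vessel_tree_params(n_seeds = 6, seed = 3))
  gt <- ground_truth(tree$mask, matrix(FALSE, 128, 128), tree$cornea_mask)
  rp <- render_params(image_size_px = c(128, 128), noise_sd = 0,
                      artifact_count = 0, seed = 1)
  img <- render_flat_mount(gt, roi, rp)$pixels
  red <- img[, , 1]
  bg_mean <- mean(red[!gt$lymphatic_mask])
  # every centerline pixel beats the background mean
  cl <- unique(cbind(round(tree$centerlines$y), round(tree$centerlines$x)))
  cl <- cl[cl[, 1] >= 1 & cl[, 1] <= 128 & cl[, 2] >= 1 & cl[, 2] <= 128, ]
  expect_true(all(red[cl] > bg_mean))
  # in-mask vs out-of-mask contrast is strong
  expect_gt(mean(red[gt$lymphatic_mask]) / bg_mean, 1.5)
})

test_that("default-parameter render keeps strong in-mask contrast", {
  sim <- simulate_flat_mount(seed = 9)
  red <- sim$image$pixels[, , 1]
  expect_gt(mean(red[sim$gt$lymphatic_mask]) /
              mean(red[!sim$gt$lymphatic_mask]), 1.5)
})

test_that("channel collisions and mismatched shapes are rejected", {
  expect_error(render_params(channel_assignment = c(lymphatic = "red",
                                                    blood = "red")),
               "channel collision")
  roi <- small_roi()
  cm <- rasterize_roi(roi, c(128, 128))
  gt <- ground_truth(matrix(FALSE, 128, 128), matrix(FALSE, 128, 128), cm)
  expect_error(render_flat_mount(gt, roi,
                                 render_params(image_size_px = c(64, 64))),
               "do not match")
})

test_that("rendering is deterministic given the seed", {
  a <- simulate_flat_mount(seed = 21)
  b <- simulate_flat_mount(seed = 21)
  expect_identical(a$image$pixels, b$image$pixels)
})
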