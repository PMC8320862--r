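test_that("Otsu separates two classes and matches the exhaustive oracle", {
  d <- c(5L, 10L, 10L)
  data <- array(0, d); data[, , 6:10] <- 1000
  vol <- image_volume(data, spacing_iso())
  seg <- otsu_threshold(vol)
  expect_identical(seg$mask, array(as.integer(data == 1000), d))
  expect_gt(seg$threshold_or_centers[["threshold"]], 0)
  expect_lt(seg$threshold_or_centers[["threshold"]], 1000)

  withr::local_seed(31)
  for (i in 1:25) {
    v <- switch(1 + i %% 3,
                runif(1000) * 1000,
                c(rnorm(700, 100, 30), rnorm(300, 600, 80)),
                rpois(1000, 40) * 10)
    got <- vascuseg:::otsu_on_values(v, 64L)
    expect_equal(got, oracle_otsu(v, 64L), tolerance = 1e-10)
  }

  # affine map a I + b gives the identical mask (same binning scheme)
  withr::local_seed(5)
  base <- array(sample.int(500, 4 * 8 * 8, TRUE), c(4, 8, 8))
  v1 <- image_volume(base, spacing_iso())
  v2 <- image_volume(3 * base + 40, spacing_iso())
  expect_identical(otsu_threshold(v1)$mask, otsu_threshold(v2)$mask)

  expect_error(otsu_threshold(image_volume(array(9, d), spacing_iso())),
               "constant")
})

test_that("k-means recovers well-separated groups and is deterministic", {
  withr::local_seed(77)
  d <- c(5L, 12L, 12L)
  lab <- array(runif(prod(d)) < 0.4, d)
  data <- array(0, d)
  data[lab] <- round(rnorm(sum(lab), 800, 10))
  data[!lab] <- round(rnorm(sum(!lab), 50, 10))
  vol <- image_volume(pmax(data, 0), spacing_iso())
  seg <- kmeans_segment(vol, k = 2, seed = 48)
  # Lloyd fixed point for two separated groups: centres at the group means
  expect_lt(abs(seg$threshold_or_centers[1] - mean(data[!lab])), 1)
  expect_lt(abs(seg$threshold_or_centers[2] - mean(data[lab])), 1)
  expect_identical(seg$mask, array(as.integer(lab), d))

  seg2 <- kmeans_segment(vol, k = 2, seed = 48)
  expect_identical(seg$mask, seg2$mask)          # same seed, same mask
  expect_identical(seg$threshold_or_centers, seg2$threshold_or_centers)

  # binary image: k = 2 k-means and Otsu give the same partition
  b <- array(0, d); b[lab] <- 1000
  vb <- image_volume(b, spacing_iso())
  expect_identical(kmeans_segment(vb, k = 2)$mask, otsu_threshold(vb)$mask)

  expect_error(kmeans_segment(vb, k = 4), "distinct")
})

test_that("SRM follows its merge predicate and Q monotonicity", {
  # constant image: single region, degenerate, flagged
  d <- c(4L, 8L, 8L)
  cvol <- image_volume(array(50, d), spacing_iso(), bit_depth = 8)
  expect_warning(s <- srm_segment(cvol), "degenerate")
  expect_equal(s$params_echo$n_regions, 1L)
  expect_true(s$params_echo$degenerate)
  expect_true(all(s$mask == 0L))

  # two constant halves, |dmean| = 200: predicate arithmetic keeps them
  # apart for small Q. b2(R) + b2(R) with |R| = 128, Q = 2, g = 256:
  # 2 * 256^2 * ln(2 * 6 * 256^2) / (2 * 2 * 128) = 3368 < 200^2 -> no merge
  h <- array(10, c(2L, 8L, 16L)); h[, , 9:16] <- 210
  hv <- image_volume(h, spacing_iso(), bit_depth = 8)
  s2 <- srm_segment(hv, Q = 2)
  expect_equal(s2$params_echo$n_regions, 2L)
  expect_identical(s2$mask, array(as.integer(h > 100), dim(h)))

  # ... and merges them for a Q small enough that b2 exceeds the contrast
  s1 <- suppressWarnings(srm_segment(hv, Q = 0.05))
  expect_equal(s1$params_echo$n_regions, 1L)
  expect_true(s1$params_echo$degenerate)

  # region count non-increasing in 1/Q on noisy phantoms (5 seeds)
  for (seed in 1:5) {
    sc <- tiny_tube_scene(d = 4, noise_sd = 20, poisson = TRUE, seed = seed,
                          shape = c(6L, 24L, 24L), sp = voxel_spacing(0.5, 0.5, 1))
    r <- render_scene(sc)
    v8 <- image_volume(round(vascuseg:::rescale_to_depth(r$volume$data, 8)),
                       sc$spacing, bit_depth = 8)
    n2 <- srm_segment(v8, Q = 2)$params_echo$n_regions
    n32 <- srm_segment(v8, Q = 32)$params_echo$n_regions
    expect_lte(n2, n32)
  }

  expect_error(srm_segment(cvol, Q = 0), "positive")
  expect_warning(srm_segment(image_volume(array(c(0, 40000), c(2, 4, 4)),
                                          spacing_iso(), bit_depth = 16)),
                 "8-bit")
})

test_that("vascular volume is exact bookkeeping over the ROI", {
  sp <- spacing_lsfm()
  d <- c(10L, 20L, 20L)
  mask <- array(0L, d); mask[1:5, 1:10, 1:20] <- 1L   # 1000 voxels
  roi <- array(1L, d)
  vr <- vascular_volume(mask, roi, sp)
  expect_equal(vr$n_vascular_voxels, 1000)
  expect_equal(vr$volume_um3, 1000 * 0.334 * 0.334 * 0.69)
  expect_equal(vr$volume_um3, vr$n_vascular_voxels * vr$voxel_volume)

  # empty mask, halved ROI, errors
  expect_equal(vascular_volume(array(0L, d), roi, sp)$volume_um3, 0)
  half <- array(0L, d); half[1:5, 1:5, 1:20] <- 1L
  expect_equal(vascular_volume(mask, half, sp)$volume_um3, vr$volume_um3 / 2)
  expect_error(vascular_volume(mask, array(0L, d), sp), "empty")
  expect_error(vascular_volume(mask, roi[1:2, , ], sp), "differ")
})

test_that("coefficient of variation uses the sample sd", {
  expect_equal(coefficient_of_variation(c(100, 100, 100)), 0)
  expect_equal(coefficient_of_variation(c(90, 110)),
               100 * sqrt(200) / 100)            # sd = 14.142..., CoV 14.14%
  x <- c(85, 95, 100, 105, 115)
  expect_equal(coefficient_of_variation(x), 100 * sd(x) / mean(x))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})
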