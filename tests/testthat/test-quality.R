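make_cnr_fixture <- function(mu_v = 100, mu_nv = 40, sigma_bg = 10, seed = 1) {
  # constant vessel and tissue patches plus a known-noise background patch
  d <- c(4L, 20L, 30L)
  data <- array(0, d)
  vessel <- array(0L, d); nonv <- array(0L, d); bg <- array(0L, d)
  vessel[, 1:6, ] <- 1L;  data[, 1:6, ] <- mu_v
  nonv[, 8:12, ] <- 1L;   data[, 8:12, ] <- mu_nv
  bg[, 14:20, ] <- 1L
  noise <- withr::with_seed(seed, rnorm(sum(bg), mean = 20, sd = sigma_bg))
  noise <- (noise - mean(noise)) / sd(noise) * sigma_bg + 20  # exact sd
  data[bg == 1L] <- noise
  list(vol = image_volume(data, spacing_iso(), bit_depth = 16),
       rois = roi_set(vessel = vessel, non_vascular = nonv, background = bg))
}

test_that("CNR reproduces hand arithmetic and is affine-invariant", {
  f <- make_cnr_fixture()
  r <- compute_cnr(f$vol, f$rois)
  expect_equal(r$cnr, (100 - 40) / 10, tolerance = 1e-12)
  expect_equal(r$mu_v, 100)
  expect_equal(r$mu_nv, 40)
  expect_equal(r$sigma_bg, 10)
  expect_equal(r$cnr, (r$mu_v - r$mu_nv) / r$sigma_bg)  # identity invariant

  # equal vessel/non-vascular means -> 0
  f0 <- make_cnr_fixture(mu_v = 40, mu_nv = 40)
  expect_equal(compute_cnr(f0$vol, f0$rois)$cnr, 0)

  # a I + b leaves CNR unchanged (a > 0); x3 scaling exactly
  f3 <- f
  f3$vol$data <- 3 * f3$vol$data + 17
  expect_equal(compute_cnr(f3$vol, f3$rois)$cnr, r$cnr, tolerance = 1e-10)

  # negative CNR is reported, not clamped
  fn <- make_cnr_fixture(mu_v = 30, mu_nv = 40)
  expect_lt(compute_cnr(fn$vol, fn$rois)$cnr, 0)
})

test_that("CNR rejects empty masks, tiny backgrounds and zero variance", {
  f <- make_cnr_fixture()
  r2 <- f$rois; r2$vessel <- array(0L, dim(f$vol$data))
  expect_error(compute_cnr(f$vol, r2), "empty: vessel")
  small <- f$rois
  keep <- which(small$background == 1L)[1:50]
  small$background <- array(0L, dim(f$vol$data)); small$background[keep] <- 1L
  expect_error(compute_cnr(f$vol, small), "at least 100")
  flat <- f
  flat$vol$data[f$rois$background == 1L] <- 5
  expect_error(compute_cnr(flat$vol, flat$rois), "zero")
})

test_that("cylinder_roi builds the cross-section-over-5um protocol mask", {
  vol <- image_volume(array(0, c(20, 40, 40)), spacing_iso())
  roi <- cylinder_roi(vol, centre = c(10, 20, 20), direction = c(0, 0, 1),
                      diameter = 8, length = 5)
  expect_gt(sum(roi), 0)
  # every ROI voxel lies within radius of the axis and the 5 um extent
  idx <- which(roi == 1L, arr.ind = TRUE)
  zc <- (idx[, 1] - 0.5); yc <- (idx[, 2] - 0.5); xc <- (idx[, 3] - 0.5)
  expect_true(all(sqrt((zc - 10)^2 + (yc - 20)^2) <= 4 + 1e-9))
  expect_true(all(abs(xc - 20) <= 2.5 + 1e-9))
})

test_that("profiles sample physical positions exactly", {
  vol <- image_volume(array(7, c(10, 30, 30)), spacing_iso())
  p <- extract_profile(vol, c(5, 10, 10), c(5, 20, 10), n_samples = 11)
  expect_equal(p$positions, 0:10)               # |p1-p0| = 10 um, n = 11
  expect_true(all(p$values == 7))               # constant image
  expect_error(extract_profile(vol, c(5, 10, 10), c(5, 10, 10)), "coincide")
  expect_error(extract_profile(vol, c(5, 10, 10), c(5, 99, 10)), "outside")
  expect_error(extract_profile(vol, c(5, 1, 1), c(5, 2, 2), n_samples = 4), ">= 8")
})

test_that("membrane cross-profile peaks sit near +/- the radius", {
  sc <- standard_scenes(seed = 1)[["membrane10"]]
  sc$noise_sd <- 0; sc$poisson <- FALSE
  r <- render_scene(sc)
  zc <- 48 * 0.69 / 2
  p0 <- c(zc, 24 - 12, 24); p1 <- c(zc, 24 + 12, 24)
  prof <- extract_profile(r$volume, p0, p1, 201)
  cl <- classify_profile(prof)
  expect_equal(cl$shape, "double")
  centred <- cl$peak_positions - 12              # line midpoint = tube axis
  expect_equal(sort(sign(centred)), c(-1, 1))
  expect_lt(max(abs(abs(centred) - 5)), 0.75)    # near +/- 5 um

  # nearest-voxel brute-force sampling agrees within one sample spacing
  t <- seq(0, 1, length.out = 201)
  pts <- outer(t, p1 - p0) + rep(p0, each = 201)
  nn <- mapply(function(z, y, x) {
    r$volume$data[pmin(pmax(round(z / 0.69 + 0.5), 1), 48),
                  pmin(pmax(round(y / 0.334 + 0.5), 1), 144),
                  pmin(pmax(round(x / 0.334 + 0.5), 1), 144)]
  }, pts[, 1], pts[, 2], pts[, 3])
  cl_nn <- classify_profile(structure(list(positions = prof$positions,
                                           values = nn, line = prof$line),
                                      class = "intensity_profile"))
  expect_equal(cl_nn$shape, "double")
  expect_lt(max(abs(cl_nn$peak_positions - cl$peak_positions)), 0.12 + 1e-9)
})

test_that("profile classification follows peak count and prominence", {
  pos <- seq(0, 20, by = 0.1)
  flat <- structure(list(positions = pos, values = rep(3, length(pos)),
                         line = NULL), class = "intensity_profile")
  expect_equal(classify_profile(flat)$shape, "none")

  bump <- structure(list(positions = pos,
                         values = exp(-(pos - 10)^2 / (2 * 2^2)),
                         line = NULL), class = "intensity_profile")
  cb <- classify_profile(bump)
  expect_equal(cb$shape, "single")
  expect_lt(abs(cb$peak_positions - 10), 0.11)

  # two Gaussians 8 um apart, sd 1.5: analytic mixture is bimodal
  # (separation > 2 sd), so the class must be double with a positive dip
  two <- exp(-(pos - 6)^2 / (2 * 1.5^2)) + exp(-(pos - 14)^2 / (2 * 1.5^2))
  ct <- classify_profile(structure(list(positions = pos, values = two,
                                        line = NULL),
                                   class = "intensity_profile"))
  expect_equal(ct$shape, "double")
  expect_gt(ct$dip_depth, 0)
  expect_lt(max(abs(sort(ct$peak_positions) - c(6, 14))), 0.5)

  # low-prominence ripples are not peaks
  ripple <- 10 + 0.01 * sin(pos * 4) + exp(-(pos - 10)^2 / 8)
  cr <- classify_profile(structure(list(positions = pos, values = ripple,
                                        line = NULL),
                                   class = "intensity_profile"))
  expect_equal(cr$shape, "single")
})

test_that("profile averaging resamples onto the first grid", {
  mk <- function(pos, val) structure(list(positions = pos, values = val,
                                          line = NULL),
                                     class = "intensity_profile")
  p1 <- mk(0:10, rep(10, 11))
  p2 <- mk(seq(0, 10, by = 0.5), rep(20, 21))
  av <- average_profiles(list(p1, p2))
  expect_equal(av$positions, 0:10)
  expect_true(all(av$values == 15))              # constants 10 and 20 -> 15
  expect_equal(average_profiles(list(p1))$values, p1$values)  # singleton
  asym <- mk(0:10, c(0:5, 4:0))
  mirr <- mk(0:10, rev(c(0:5, 4:0)))
  avg <- average_profiles(list(asym, mirr))
  expect_equal(avg$values, rev(avg$values))      # mirror pair -> symmetric
  expect_error(average_profiles(list()), "empty")
})
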