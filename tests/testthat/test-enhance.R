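test_that("median filter: constants, impulses, brute-force oracle", {
  const <- image_volume(array(42, c(2, 20, 20)), spacing_iso())
  expect_true(all(median_filter_2d(const, 6)$data == 42))

  imp <- image_volume(array(0, c(1, 30, 30)), spacing_iso())
  imp$data[1, 15, 15] <- 1000
  expect_equal(median_filter_2d(imp, 6)$data[1, 15, 15], 0)

  withr::local_seed(21)
  slice <- matrix(runif(32 * 32) * 1000, 32, 32)
  vol <- image_volume(array(slice, c(1, 32, 32)), spacing_iso())
  got <- median_filter_2d(vol, 2)$data[1, , ]
  expect_equal(got, oracle_median_disc(slice, 2), tolerance = 1e-12)

  expect_error(median_filter_2d(const, 11), "exceeds")
})

test_that("rolling ball: flat background removal, ridge preservation, oracle", {
  const <- image_volume(array(300, c(1, 40, 40)), spacing_iso())
  out <- rolling_ball_2d(const, 10)
  expect_lte(max(abs(out$data)), 1)              # constant -> ~0

  # narrow bright ridge on a linear ramp: ridge kept, ramp removed
  ny <- 60; nx <- 60
  ramp <- matrix(rep(seq(0, 300, length.out = nx), each = ny), ny, nx)
  ridge <- matrix(0, ny, nx); ridge[, 29:31] <- 500
  vol <- image_volume(array(ramp + ridge, c(1, ny, nx)), spacing_iso())
  out2 <- rolling_ball_2d(vol, 20)
  expect_gt(min(out2$data[1, 10:50, 30]), 0.9 * 500)
  expect_lt(max(out2$data[1, 10:50, c(10, 50)]), 0.1 * 500)
  expect_true(all(out2$data >= 0))
  expect_true(all(out2$data <= vol$data + 1e-9))

  withr::local_seed(8)
  slice <- matrix(runif(64 * 64) * 255, 64, 64)
  got <- rolling_ball_2d(image_volume(array(slice, c(1, 64, 64)), spacing_iso()),
                         8)$data[1, , ]
  expect_equal(got, pmax(slice - oracle_ball_opening(slice, 8), 0),
               tolerance = 1e-9)

  # full-window code path (ball wider than the slice) against the same oracle
  small <- matrix(runif(24 * 24) * 255, 24, 24)
  got2 <- rolling_ball_2d(image_volume(array(small, c(1, 24, 24)), spacing_iso()),
                          40)$data[1, , ]
  expect_equal(got2, pmax(small - oracle_ball_opening(small, 40), 0),
               tolerance = 1e-9)
})

test_that("general filtering composes median then ball and echoes params", {
  const <- image_volume(array(1234, c(1, 30, 30)), spacing_iso())
  gf <- general_filtering(const, enhance_params(gf_median_radius = 3,
                                                gf_ball_radius = 10))
  expect_lte(max(abs(gf$data)), 1)
  expect_equal(gf$provenance$gf_median_radius, 3L)
  gfd <- general_filtering(const)
  expect_equal(gfd$provenance$gf_median_radius, 6L)   # defaults echoed
  expect_equal(gfd$provenance$gf_ball_radius, 200)
})

test_that("Hessian: ramps vanish, quadratics give their second derivative", {
  d <- c(10L, 24L, 24L)
  xs <- ((1:24) - 0.5) * 1.0
  ramp <- image_volume(array(rep(xs * 10, each = 10 * 24), d), spacing_iso())
  H <- hessian_at_scale(ramp, 1.5, normalize = FALSE)
  inner <- H$xx[4:7, 10:15, 10:15]    # interior: clear of boundary reflections
  expect_lt(max(abs(inner)), 1e-6)

  quad <- image_volume(array(rep(xs^2, each = 10 * 24), d), spacing_iso())
  Hq <- hessian_at_scale(quad, 1.5, normalize = FALSE)
  expect_equal(mean(Hq$xx[3:8, 8:17, 10:15]), 2, tolerance = 1e-3)
  expect_lt(max(abs(Hq$yy[3:8, 8:17, 10:15])), 1e-6)

  expect_error(hessian_at_scale(ramp, 0.5), "below")
})

test_that("closed-form symmetric eigenvalues match base eigen()", {
  withr::local_seed(13)
  n <- 4000
  a11 <- rnorm(n); a22 <- rnorm(n); a33 <- rnorm(n)
  a12 <- rnorm(n); a13 <- rnorm(n); a23 <- rnorm(n)
  e <- vascuseg:::eigen3_sym_field(a11, a22, a33, a12, a13, a23)
  for (i in seq(1, n, by = 37)) {
    M <- matrix(c(a11[i], a12[i], a13[i],
                  a12[i], a22[i], a23[i],
                  a13[i], a23[i], a33[i]), 3, 3)
    ref <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    got <- c(e$l1[i], e$l2[i], e$l3[i])
    expect_lt(max(abs(got - ref)) / max(abs(ref), 1e-8), 1e-8)
  }
})

test_that("tubeness matches the finite-difference + eigen oracle", {
  withr::local_seed(4)
  raw <- array(runif(16^3) * 100, c(16, 16, 16))
  raw <- vascuseg:::gaussian_smooth_zyx(raw, c(1, 1, 1))  # mild band-limit
  vol <- image_volume(raw, spacing_iso(), name = "rand")
  got <- tubeness(vol, 2)$data
  ref <- oracle_tubeness(vol, 2)
  expect_lt(max(abs(got - ref)) / max(ref), 1e-8)
})

test_that("tubeness sign gate and scale matching behave physically", {
  const <- image_volume(array(7, c(8, 20, 20)), spacing_iso())
  expect_true(all(tubeness(const, 2)$data == 0))

  # bright Gaussian cylinder along x: response on the axis, maximal near
  # the matched scale, zero for the dark (inverted) version
  d <- c(24L, 48L, 48L)
  zc <- ((1:24) - 0.5); yc <- ((1:48) - 0.5)
  r2 <- outer((zc - 12)^2, (yc - 24)^2, "+")
  a <- 4   # cylinder "radius" (Gaussian sd, um)
  cyl <- array(rep(1000 * exp(-r2 / (2 * a^2)), 48), d)
  vol <- image_volume(cyl, spacing_iso())
  resp <- function(s) tubeness(vol, s)$data[12, 24, 24]
  matched <- resp(a)
  expect_gt(matched, resp(a / 4))
  expect_gt(matched, resp(4 * a))

  dark <- image_volume(max(cyl) - cyl, spacing_iso())
  expect_equal(tubeness(dark, a)$data[12, 24, 24], 0)
  expect_true(all(tubeness(vol, a)$data >= 0))
})

test_that("tubular filtering rescales to the declared bit depth", {
  sc <- tiny_tube_scene(d = 5, noise_sd = 10, poisson = TRUE, seed = 2,
                        shape = c(12L, 48L, 48L), sp = voxel_spacing(0.5, 0.5, 1))
  r <- render_scene(sc)
  tf <- tubular_filtering(r$volume, enhance_params(tf_sigma = 5))
  expect_equal(min(tf$data), 0)
  expect_equal(max(tf$data), 65535)
  expect_true(all(tf$data == round(tf$data)))
  expect_equal(tf$provenance$kernel_sd_um, 2.5)  # sd = scale/2
})

test_that("2d slice-wise tubeness responds to in-plane tubes", {
  sc <- tiny_tube_scene(d = 5, noise_sd = 0, shape = c(6L, 48L, 48L),
                        sp = voxel_spacing(0.5, 0.5, 1))
  r <- render_scene(sc)
  tf2 <- tubular_filtering(r$volume, enhance_params(tf_sigma = 5, tf_mode = "2d"))
  expect_gt(tf2$data[3, 24, 24], 0.5 * max(tf2$data))
})

test_that("scale sweep classifies the double->single transition", {
  sc <- tiny_tube_scene(d = 5, noise_sd = 0, mode = "membrane",
                        shape = c(24L, 64L, 64L),
                        sp = voxel_spacing(0.334, 0.334, 0.69))
  r <- render_scene(sc)
  zc <- 24 * 0.69 / 2; ymid <- 64 * 0.334 / 2
  line <- list(p0 = c(zc, ymid - 6, 10), p1 = c(zc, ymid + 6, 10),
               n_samples = 151)
  sw <- scale_sweep(r$volume, c(2, 5, 9), line)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$shape[1], "double")
  expect_equal(sw$shape[3], "single")
  expect_equal(attr(sw, "selected_sigma"), sw$sigma_um[min(which(sw$shape == "single"))])
  expect_error(scale_sweep(r$volume, 5, line), "at least 2")

  # cytosolic tube: no dip to remove, single at and beyond the matched scale
  sc2 <- tiny_tube_scene(d = 5, noise_sd = 0,
                         shape = c(24L, 64L, 64L),
                         sp = voxel_spacing(0.334, 0.334, 0.69))
  r2 <- render_scene(sc2)
  sw2 <- scale_sweep(r2$volume, c(5, 9, 14), line)
  expect_true(all(sw2$shape == "single"))
})
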