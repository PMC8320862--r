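test_that("tube and scene specs enforce their invariants", {
  ax <- rbind(c(0, 5, 0), c(0, 5, 20))
  expect_error(tube_spec(ax, diameter = -1), "diameter")
  expect_error(tube_spec(ax, 5, "membrane", wall_fraction = 0.8), "wall_fraction")
  expect_error(phantom_scene(c(4, 8, 8), spacing_iso(), list(tube_spec(ax, 5)),
                             noise_sd = -1, seed = 1), "noise_sd")
  expect_error(phantom_scene(c(4, 8, 8), spacing_iso(),
                             list(tube_spec(ax, 5))), "seed")
})

test_that("cytosolic tubes render unimodal with the maximum on the axis", {
  sc <- tiny_tube_scene(d = 6, noise_sd = 0)
  r <- render_scene(sc)
  zc_i <- 6; ymid_i <- 24                       # axis voxel indices
  prof <- r$volume$data[zc_i, , 24]
  expect_lt(abs(which.max(prof) - ymid_i), 2)   # max within 1 voxel of axis
  cl <- classify_profile(extract_profile(r$volume, c(3, 2, 12), c(3, 22, 12), 101))
  expect_equal(cl$shape, "single")
})

test_that("membrane tubes show a double-peak with a deep on-axis dip", {
  # tube along z so the cross-plane is isotropic in-plane (0.5 um)
  sp <- spacing_iso(0.5)
  shape <- c(24L, 64L, 64L)
  ymid <- 64 * 0.5 / 2; xmid <- ymid
  zmax <- 24 * 0.5
  d_um <- 6 * 0.5                                # exactly 6 in-plane voxels
  sc <- phantom_scene(shape, sp,
                      list(tube_spec(rbind(c(-1, ymid, xmid), c(zmax + 1, ymid, xmid)),
                                     diameter = d_um, label_mode = "membrane",
                                     peak_intensity = 8000, wall_fraction = 0.25)),
                      background_level = 0, noise_sd = 0, seed = 1)
  r <- expect_no_warning(render_scene(sc))
  prof <- extract_profile(r$volume, c(6, ymid - 4, xmid), c(6, ymid + 4, xmid), 161)
  cl <- classify_profile(prof, smoothing_fwhm = 0.3)
  expect_equal(cl$shape, "double")
  expect_gte(cl$dip_depth, 0.2)                  # >= 20% dip at 6 voxels diameter
  # strict: on-axis intensity below intensity at the wall radius (noiseless)
  zi <- 12
  centre <- r$volume$data[zi, 32, 32]
  wall <- r$volume$data[zi, 32 + 3, 32]
  expect_lt(centre, wall)
})

test_that("ground-truth mask volume matches the analytic cylinder", {
  # d >= 8 in-plane voxels: Eq-2 style count within 5% of pi r^2 L
  sc <- tiny_tube_scene(d = 5, shape = c(16L, 48L, 48L),
                        sp = voxel_spacing(0.5, 0.5, 0.5))
  r <- render_scene(sc)
  L <- 48 * 0.5
  analytic <- pi * 2.5^2 * L
  measured <- sum(r$mask) * voxel_volume_um3(sc$spacing)
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("rendering is deterministic given the scene seed", {
  sc <- tiny_tube_scene(noise_sd = 40, poisson = TRUE, seed = 7)
  r1 <- render_scene(sc); r2 <- render_scene(sc)
  expect_identical(r1$volume$data, r2$volume$data)
  sc2 <- tiny_tube_scene(noise_sd = 40, poisson = TRUE, seed = 8)
  expect_false(identical(render_scene(sc2)$volume$data, r1$volume$data))
})

test_that("rendered series carry injected shifts and fresh per-frame noise", {
  sc <- motion_scene(noise_sd = 20, seed = 3)
  zero <- motion_trace(matrix(0, 3, 2))
  s0 <- render_series(sc, 3, zero)
  d01 <- s0$series$frames[[1]]$data - s0$series$frames[[2]]$data
  expect_gt(sd(d01), 0)                          # frames differ only by noise
  expect_lt(mean(abs(d01)), 5 * 20)

  # integer shift: cross-correlation oracle recovers (3, -2) voxels
  tr <- motion_trace(rbind(c(0, 0), c(3 * 0.5, -2 * 0.5)))  # (3, -2) voxels
  s1 <- render_series(sc, 2, tr)
  pa <- apply(s1$series$frames[[1]]$data, c(2, 3), mean)
  pb <- apply(s1$series$frames[[2]]$data, c(2, 3), mean)
  sh <- oracle_shift_search(pa, pb, 5)           # shift aligning frame2 to frame1
  expect_equal(unname(sh), c(-3, 2))

  expect_error(render_series(sc, 1, motion_trace(matrix(0, 1, 2))), "at least 2")
  big <- motion_trace(rbind(c(0, 0), c(20, 0)))  # > 25% of the 24 um field
  expect_error(render_series(sc, 2, big), "25%")
})

test_that("the scene catalogue is stable and correctly calibrated", {
  s1 <- standard_scenes(); s2 <- standard_scenes()
  expect_identical(names(s1), names(s2))
  expect_true(all(c("bright+dim", "membrane10", "bifurcation", "noisy16")
                  %in% names(s1)))

  # membrane10: mask diameter ~ 10 um within one in-plane voxel
  r <- render_scene(standard_scenes(seed = 2)[["membrane10"]])
  zc_i <- 24
  yext <- range(which(rowSums(r$mask[zc_i, , ]) > 0))
  width_um <- (yext[2] - yext[1] + 1) * 0.334
  expect_lt(abs(width_um - 10), 2 * 0.334 + 1e-9)

  # noisy16: measured CNR within the calibrated band around 48
  sc <- standard_scenes(seed = 5)[["noisy16"]]
  rn <- render_scene(sc)
  cnr <- compute_cnr(rn$volume, phantom_rois(sc, rn$mask))
  expect_gt(cnr$cnr, 38)
  expect_lt(cnr$cnr, 58)
})

test_that("phantom QC ROIs are usable and disjoint from vessels", {
  sc <- standard_scenes(seed = 1)[["bright+dim"]]
  r <- render_scene(sc)
  rois <- phantom_rois(sc, r$mask)
  expect_gte(sum(rois$background), 100)
  expect_gte(sum(rois$non_vascular), 100)
  expect_equal(sum(rois$vessel & rois$background), 0)
  expect_equal(sum(rois$vessel & rois$non_vascular), 0)
})
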