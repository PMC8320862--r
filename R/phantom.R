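#' Specify a synthetic vessel tube
#'
#' A tube is a polyline axis in physical coordinates with a diameter and a
#' labelling mode. `cytosolic` tubes are filled (single-peak cross profile,
#' as for cytosolic fluorophores); `membrane` tubes are hollow shells whose
#' cross profile shows the double-peak signature of membrane-localised
#' reporters in lumenised vessels: two maxima near the walls and a dip over
#' the lumen.
#'
#' @param axis Numeric matrix with columns `(z, y, x)` in µm: the polyline
#'   vertices of the tube centreline (at least 2 rows).
#' @param diameter Tube diameter in µm (> 0).
#' @param label_mode `"cytosolic"` or `"membrane"`.
#' @param peak_intensity Peak signal in grey levels (> 0).
#' @param wall_fraction Membrane mode only: wall Gaussian sd as a fraction of
#'   the radius, in (0, 0.5].
#' @return Object of class `tube_spec`.
#' @export
tube_spec <- function(axis, diameter, label_mode = c("cytosolic", "membrane"),
                      peak_intensity = 10000, wall_fraction = 0.2) {
  label_mode <- match.arg(label_mode)
  axis <- as.matrix(axis)
  if (ncol(axis) != 3L || nrow(axis) < 2L)
    stop("`axis` must be a matrix of (z, y, x) points with >= 2 rows")
  if (diameter <= 0) stop("`diameter` must be > 0")
  if (peak_intensity <= 0) stop("`peak_intensity` must be > 0")
  if (label_mode == "membrane" &&
      (wall_fraction <= 0 || wall_fraction > 0.5))
    stop("`wall_fraction` must be in (0, 0.5]")
  structure(list(axis = axis, diameter = diameter, label_mode = label_mode,
                 peak_intensity = peak_intensity,
                 wall_fraction = wall_fraction),
            class = "tube_spec")
}

#' Specify a synthetic vascular scene
#'
#' Bundles the geometry and image-formation parameters of one phantom stack:
#' tubes, a flat background level, a linear intensity gradient across the
#' field (autofluorescence-like), multiplicative attenuation stripes
#' (light-sheet shadowing-like), Poisson shot noise and Gaussian read noise.
#' A seed is mandatory: every stochastic path derives from it.
#'
#' @param shape Integer vector `(nz, ny, nx)`.
#' @param spacing A [voxel_spacing()].
#' @param tubes List of [tube_spec()] objects.
#' @param background_level Flat background offset (grey levels).
#' @param gradient_amplitude Peak-to-peak linear ramp along y (grey levels).
#' @param stripe_amplitude Depth of multiplicative attenuation bands along x,
#'   expressed in grey levels at the brightest structure.
#' @param noise_sd Gaussian read-noise sd (grey levels).
#' @param poisson Apply Poisson shot noise before the Gaussian read noise.
#' @param bit_depth Declared sample depth of the rendered stack.
#' @param seed Integer seed (mandatory).
#' @param name Scene label.
#' @return Object of class `phantom_scene`.
#' @export
phantom_scene <- function(shape, spacing, tubes, background_level = 200,
                          gradient_amplitude = 0, stripe_amplitude = 0,
                          noise_sd = 0, poisson = FALSE, bit_depth = 16L,
                          seed, name = "phantom") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0))
    stop("`shape` must be positive (nz, ny, nx)")
  stopifnot(is_voxel_spacing(spacing))
  if (!is.list(tubes) || !all(vapply(tubes, inherits, logical(1), "tube_spec")))
    stop("`tubes` must be a list of tube_spec objects")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory for a phantom scene")
  structure(list(shape = shape, spacing = spacing, tubes = tubes,
                 background_level = background_level,
                 gradient_amplitude = gradient_amplitude,
                 stripe_amplitude = stripe_amplitude,
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 name = name),
            class = "phantom_scene")
}

# Point-to-segment distances for a block of physical points (n x 3, (z,y,x)).
dist_to_segment <- function(P, A, B) {
  AB <- B - A
  len2 <- sum(AB^2)
  if (len2 == 0) {
    D <- sweep(P, 2, A)
    return(sqrt(rowSums(D^2)))
  }
  t <- ((P[, 1] - A[1]) * AB[1] + (P[, 2] - A[2]) * AB[2] +
        (P[, 3] - A[3]) * AB[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dz <- P[, 1] - (A[1] + t * AB[1])
  dy <- P[, 2] - (A[2] + t * AB[2])
  dx <- P[, 3] - (A[3] + t * AB[3])
  sqrt(dz^2 + dy^2 + dx^2)
}

# Distance from every voxel centre to a tube axis polyline, computed on
# bounding boxes around each segment (Inf elsewhere).
tube_distance_field <- function(shape, sp_zyx, axis, reach) {
  zc <- (seq_len(shape[1]) - 0.5) * sp_zyx[1]
  yc <- (seq_len(shape[2]) - 0.5) * sp_zyx[2]
  xc <- (seq_len(shape[3]) - 0.5) * sp_zyx[3]
  dist <- array(Inf, shape)
  for (s in seq_len(nrow(axis) - 1L)) {
    A <- axis[s, ]; B <- axis[s + 1L, ]
    lo <- pmin(A, B) - reach
    hi <- pmax(A, B) + reach
    zi <- which(zc >= lo[1] & zc <= hi[1])
    yi <- which(yc >= lo[2] & yc <= hi[2])
    xi <- which(xc >= lo[3] & xc <= hi[3])
    if (!length(zi) || !length(yi) || !length(xi)) next  # tube outside: clip
    nz <- length(zi); ny <- length(yi); nx <- length(xi)
    P <- cbind(rep(zc[zi], times = ny * nx),
               rep(rep(yc[yi], each = nz), times = nx),
               rep(xc[xi], each = nz * ny))
    d <- dist_to_segment(P, A, B)
    blk <- dist[zi, yi, xi]
    dist[zi, yi, xi] <- pmin(blk, array(d, c(nz, ny, nx)))
  }
  dist
}

# Noiseless scene: returns the clean intensity array (before noise) and the
# ground-truth mask. The PSF-like blur (0.5 um lateral, 1.0 um axial) is
# applied to the whole structure image so that edges are optically soft.
render_clean <- function(scene) {
  sp <- spacing_zyx(scene$spacing)
  shape <- scene$shape
  signal <- array(0, shape)
  gt <- array(0L, shape)
  edge <- 0.4  # cytosolic soft-edge sd, um
  for (tb in scene$tubes) {
    R <- tb$diameter / 2
    if (tb$diameter < 2 * max(sp[2], sp[3]))
      warning("tube diameter ", tb$diameter,
              " um is below 2 in-plane voxels; rendering anyway")
    sw <- if (tb$label_mode == "membrane") tb$wall_fraction * R else edge
    reach <- R + 4 * sw + 2
    dist <- tube_distance_field(shape, sp, tb$axis, reach)
    fin <- which(is.finite(dist))
    r <- dist[fin]
    I <- if (tb$label_mode == "cytosolic") {
      core <- pmax(r - (R - edge), 0)
      tb$peak_intensity * exp(-core^2 / (2 * edge^2))
    } else {
      tb$peak_intensity * exp(-(r - R)^2 / (2 * sw^2))
    }
    signal[fin] <- pmax(signal[fin], I)
    gt[fin[r <= R]] <- 1L
  }
  psf_sd_vox <- c(1.0 / sp[1], 0.5 / sp[2], 0.5 / sp[3])
  signal <- gaussian_smooth_zyx(signal, psf_sd_vox)
  clean <- signal + scene$background_level
  if (scene$gradient_amplitude != 0) {
    ramp <- scene$gradient_amplitude * (seq_len(shape[2]) - 1) / max(shape[2] - 1, 1)
    clean <- clean + rep(rep(ramp, each = shape[1]), times = shape[3])
  }
  if (scene$stripe_amplitude != 0) {
    xc <- (seq_len(shape[3]) - 0.5) * sp[3]
    depth <- scene$stripe_amplitude / max(clean)
    fac <- 1 - depth * sin(2 * pi * xc / 15)^2
    clean <- clean * rep(fac, each = shape[1] * shape[2])
  }
  list(clean = clean, gt = gt)
}

add_noise <- function(clean, scene, seed) {
  top <- 2^scene$bit_depth - 1
  with_seed(seed, {
    v <- clean
    if (scene$poisson) v <- array(rpois(length(v), pmax(v, 0)), dim(v))
    if (scene$noise_sd > 0) v <- v + rnorm(length(v), sd = scene$noise_sd)
    array(pmin(pmax(round(v), 0), top), dim(v))
  })
}

#' Render a phantom scene to an image volume plus ground truth
#'
#' Tubes are rendered in physical coordinates (circular in µm, elliptical in
#' voxels under anisotropic spacing), low-pass filtered with a PSF-like
#' Gaussian (0.5 µm lateral, 1.0 µm axial), composited over background,
#' gradient and stripe artefacts, then degraded with Poisson and Gaussian
#' noise. Rendering is deterministic given the scene seed.
#'
#' @param scene A [phantom_scene()].
#' @return List with `volume` (an [image_volume()]), `mask` (ground-truth
#'   binary array: voxels within `diameter/2` of a tube axis) and `scene`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  rc <- render_clean(scene)
  data <- add_noise(rc$clean, scene, scene$seed)
  vol <- image_volume(data, scene$spacing, bit_depth = scene$bit_depth,
                      name = scene$name)
  list(volume = vol, mask = rc$gt, scene = scene)
}

#' Per-frame rigid motion trace
#'
#' Frame-wise 2D translations (and optional in-plane rotations) applied to
#' the ground-truth scene when rendering a time series. Frame 1 must be the
#' identity.
#'
#' @param translations Numeric matrix `n x 2` of per-frame `(dy, dx)` shifts
#'   in µm.
#' @param rotations Optional numeric vector of per-frame rotations (radians).
#' @return Object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations = NULL) {
  translations <- as.matrix(translations)
  if (ncol(translations) != 2L) stop("`translations` must be n x 2 (dy, dx) in um")
  if (any(translations[1, ] != 0))
    stop("frame 1 of a motion trace must be the identity")
  if (!is.null(rotations)) {
    stopifnot(length(rotations) == nrow(translations))
    if (rotations[1] != 0) stop("frame 1 of a motion trace must be the identity")
  }
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' Render a drifting time series from a phantom scene
#'
#' Each frame is the clean scene translated by the trace entry for that frame
#' (subvoxel shifts via bilinear interpolation, applied slice-wise), with
#' fresh noise drawn per frame from the scene seed. The trace is returned as
#' ground truth for registration benchmarks.
#'
#' @param scene A [phantom_scene()].
#' @param n_frames Number of frames (>= 2).
#' @param trace A [motion_trace()] with `n_frames` rows.
#' @param dt Frame interval in seconds.
#' @return List with `series` (a [time_series()]) and `trace`.
#' @export
render_series <- function(scene, n_frames, trace, dt = 3) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(trace, "motion_trace"))
  if (n_frames < 2L) stop("a time series needs at least 2 frames")
  if (nrow(trace$translations) != n_frames)
    stop("trace length must equal n_frames")
  sp <- spacing_zyx(scene$spacing)
  field_um <- scene$shape[2:3] * sp[2:3]
  if (any(abs(trace$translations) > 0.25 * rep(field_um, each = n_frames)))
    stop("motion trace exceeds 25% of the field; registration contract void")
  # render on a canvas padded beyond the field of view so drifting frames
  # show true scene content sliding in at the edges, as a real acquisition
  # would, instead of a flat fill
  pad_y <- ceiling(max(abs(trace$translations[, 1])) / sp[2]) + 2L
  pad_x <- ceiling(max(abs(trace$translations[, 2])) / sp[3]) + 2L
  padded <- scene
  padded$shape <- scene$shape + c(0L, 2L * pad_y, 2L * pad_x)
  padded$tubes <- lapply(scene$tubes, function(tb) {
    tb$axis <- tb$axis + rep(c(0, pad_y * sp[2], pad_x * sp[3]),
                             each = nrow(tb$axis))
    tb
  })
  rc <- render_clean(padded)
  ys <- pad_y + seq_len(scene$shape[2])
  xs <- pad_x + seq_len(scene$shape[3])
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    dy <- trace$translations[k, 1] / sp[2]
    dx <- trace$translations[k, 2] / sp[3]
    shifted <- rc$clean
    if (dy != 0 || dx != 0) {
      for (z in seq_len(padded$shape[1]))
        shifted[z, , ] <- bilinear_shift_2d(rc$clean[z, , ], dy, dx,
                                            fill = scene$background_level)
    }
    data <- add_noise(shifted[, ys, xs, drop = FALSE], scene,
                      scene$seed + 7919L * k)
    frames[[k]] <- image_volume(data, scene$spacing,
                                bit_depth = scene$bit_depth,
                                name = sprintf("%s/frame%03d", scene$name, k))
  }
  list(series = time_series(frames, dt = dt), trace = trace)
}

#' Catalogue of standard phantom scenes
#'
#' Fixed, named study conditions used throughout the test-bed:
#' \describe{
#'   \item{bright+dim}{Two parallel cytosolic tubes: a bright 10 µm vessel
#'     and a dim small-calibre 2.5 µm vessel at 20\% of its intensity.
#'     Dim vessels in embryonic reporters are typically newly formed
#'     small-calibre vessels, which is what defeats kernel-based general
#'     filtering.}
#'   \item{membrane10}{A single membrane-labelled 10 µm vessel at the
#'     acquisition spacing 0.334 x 0.334 x 0.69 µm: the double-peak
#'     cross-profile test-bed for scale selection.}
#'   \item{bifurcation}{A Y-junction of cytosolic vessels (8 µm parent,
#'     6 µm daughters).}
#'   \item{noisy16}{A 16-bit cytosolic vessel whose read-noise sd is set so
#'     the nominal contrast-to-noise ratio is about 48, the level of the
#'     best membrane reporter line.}
#' }
#'
#' @param seed Base seed recorded in each scene (catalogue geometry is fixed;
#'   the seed only drives noise).
#' @return Named list of [phantom_scene()] objects; names are stable.
#' @export
standard_scenes <- function(seed = 1L) {
  sp <- voxel_spacing(0.334, 0.334, 0.69)
  shape <- c(48L, 144L, 144L)
  zc <- shape[1] * 0.69 / 2
  xmax <- shape[3] * 0.334
  along_x <- function(y_um, z_um = zc)
    rbind(c(z_um, y_um, -2), c(z_um, y_um, xmax + 2))
  scenes <- list(
    "bright+dim" = phantom_scene(
      shape, sp,
      tubes = list(
        tube_spec(along_x(12), diameter = 10, label_mode = "cytosolic",
                  peak_intensity = 10000),
        tube_spec(along_x(36), diameter = 2.5, label_mode = "cytosolic",
                  peak_intensity = 2000)),
      background_level = 200, noise_sd = 30, poisson = TRUE,
      seed = seed, name = "bright+dim"),
    "membrane10" = phantom_scene(
      shape, sp,
      tubes = list(
        tube_spec(along_x(24), diameter = 10, label_mode = "membrane",
                  peak_intensity = 10000, wall_fraction = 0.2)),
      background_level = 200, noise_sd = 87, poisson = TRUE,
      seed = seed, name = "membrane10"),
    "bifurcation" = phantom_scene(
      shape, sp,
      tubes = list(
        tube_spec(rbind(c(zc, 24, -2), c(zc, 24, 22)), diameter = 8,
                  label_mode = "cytosolic", peak_intensity = 9000),
        tube_spec(rbind(c(zc, 24, 22), c(zc, 12, xmax + 2)), diameter = 6,
                  label_mode = "cytosolic", peak_intensity = 8000),
        tube_spec(rbind(c(zc, 24, 22), c(zc, 38, xmax + 2)), diameter = 6,
                  label_mode = "cytosolic", peak_intensity = 8000)),
      background_level = 200, noise_sd = 30, poisson = TRUE,
      seed = seed, name = "bifurcation"),
    "noisy16" = phantom_scene(
      shape, sp,
      tubes = list(
        tube_spec(along_x(24), diameter = 8, label_mode = "cytosolic",
                  peak_intensity = 8000)),
      background_level = 200, noise_sd = 154, poisson = TRUE,
      seed = seed, name = "noisy16")
  )
  scenes
}

#' Build quality-control ROIs for a rendered phantom
#'
#' Derives the three masks the contrast-to-noise protocol needs from the
#' scene geometry: `vessel` (the ground-truth mask of the brightest tube),
#' `non_vascular` (tissue-level region away from every tube) and
#' `background` (a far corner region standing in for the area outside the
#' sample). Also sets `quantification` to the full field.
#'
#' @param scene A [phantom_scene()].
#' @param mask Ground-truth mask from [render_scene()] (for the vessel ROI).
#' @return An [roi_set()].
#' @export
phantom_rois <- function(scene, mask) {
  sp <- spacing_zyx(scene$spacing)
  shape <- scene$shape
  far <- array(TRUE, shape)
  for (tb in scene$tubes) {
    d <- tube_distance_field(shape, sp, tb$axis, reach = tb$diameter / 2 + 8)
    far <- far & !(d < tb$diameter / 2 + 6)
  }
  corner <- array(FALSE, shape)
  nzc <- max(4L, shape[1] %/% 4L)
  corner[seq_len(nzc), seq_len(max(10L, shape[2] %/% 6L)),
         seq_len(max(10L, shape[3] %/% 6L))] <- TRUE
  background <- far & corner
  central <- array(FALSE, shape)
  central[, seq(shape[2] %/% 3L, 2L * shape[2] %/% 3L),
          seq(shape[3] %/% 3L, 2L * shape[3] %/% 3L)] <- TRUE
  non_vascular <- far & central
  if (sum(background) < 100L || sum(non_vascular) < 100L)
    stop("phantom geometry leaves too few tube-free voxels for QC ROIs")
  roi_set(vessel = mask * 1L,
          non_vascular = non_vascular * 1L,
          background = background * 1L,
          quantification = array(1L, shape))
}
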