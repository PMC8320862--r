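#' Contrast-to-noise ratio of a vascular ROI
#'
#' CNR = (mu_v - mu_nv) / sigma_bg: mean vascular signal minus mean
#' non-vascular (tissue) signal, divided by the standard deviation of a
#' background region placed outside the sample. The value is reported
#' signed: a negative CNR is a meaningful quality-control failure, not an
#' error. Scale-invariant under affine intensity changes `a*I + b`, a > 0.
#'
#' @param vol An [image_volume()].
#' @param rois An [roi_set()] with non-empty `vessel`, `non_vascular` and
#'   `background` masks (background disjoint from vessel). The background
#'   region must contain at least 100 voxels for a stable sd estimate; its
#'   size is reported.
#' @return Object of class `cnr_result`: list with `mu_v`, `mu_nv`,
#'   `sigma_bg`, `cnr`, `n_background`.
#' @export
compute_cnr <- function(vol, rois) {
  stopifnot(is_image_volume(vol), inherits(rois, "roi_set"))
  for (nm in c("vessel", "non_vascular", "background")) {
    if (is.null(rois[[nm]]) || sum(rois[[nm]]) == 0L)
      stop("required ROI is empty: ", nm)
    if (!identical(dim(rois[[nm]]), dim(vol$data)))
      stop(nm, " ROI shape does not match the volume")
  }
  if (any(rois$vessel & rois$background))
    stop("background ROI must be disjoint from the vessel ROI")
  nbg <- sum(rois$background)
  if (nbg < 100L)
    stop("background ROI has ", nbg, " voxels; at least 100 required")
  mu_v <- mean(vol$data[rois$vessel == 1L])
  mu_nv <- mean(vol$data[rois$non_vascular == 1L])
  sigma_bg <- sd(vol$data[rois$background == 1L])
  if (!is.finite(sigma_bg) || sigma_bg == 0)
    stop("background standard deviation is zero; CNR undefined")
  structure(list(mu_v = mu_v, mu_nv = mu_nv, sigma_bg = sigma_bg,
                 cnr = (mu_v - mu_nv) / sigma_bg, n_background = nbg),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("CNR = %.3f  (mu_v %.2f, mu_nv %.2f, sigma_bg %.3f, n_bg %d)%s\n",
              x$cnr, x$mu_v, x$mu_nv, x$sigma_bg, x$n_background,
              if (x$cnr < 0) "  [flag: negative]" else ""))
  invisible(x)
}

#' Cylinder-segment vessel ROI
#'
#' Builds the mask the CNR protocol uses for the vascular mean: the whole
#' vessel cross-section over a fixed length along the vessel axis (default
#' 5 µm), from an axis point, a direction and the vessel diameter.
#'
#' @param vol Reference [image_volume()].
#' @param centre Axis point `(z, y, x)` in µm.
#' @param direction Axis direction `(z, y, x)` (need not be normalised).
#' @param diameter Vessel diameter in µm.
#' @param length Segment length along the axis in µm.
#' @return Binary integer array matching the volume shape.
#' @export
cylinder_roi <- function(vol, centre, direction, diameter, length = 5) {
  stopifnot(is_image_volume(vol), diameter > 0, length > 0)
  u <- direction / sqrt(sum(direction^2))
  sp <- spacing_zyx(vol$spacing)
  d <- dim(vol$data)
  zc <- (seq_len(d[1]) - 0.5) * sp[1] - centre[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2] - centre[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3] - centre[3]
  Z <- array(rep(zc, times = d[2] * d[3]), d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), d)
  X <- array(rep(xc, each = d[1] * d[2]), d)
  t_ax <- Z * u[1] + Y * u[2] + X * u[3]
  rad2 <- (Z - t_ax * u[1])^2 + (Y - t_ax * u[2])^2 + (X - t_ax * u[3])^2
  array(as.integer(abs(t_ax) <= length / 2 & rad2 <= (diameter / 2)^2), d)
}

#' Sample an intensity profile along a physical line
#'
#' Trilinear interpolation at `n_samples` evenly spaced points from `p0` to
#' `p1` (inclusive). Positions are arc-length offsets in µm from `p0`,
#' correct under anisotropic spacing because all geometry is physical.
#'
#' @param vol An [image_volume()].
#' @param p0,p1 Endpoints `(z, y, x)` in µm, both inside the volume.
#' @param n_samples Number of samples (>= 8).
#' @return Object of class `intensity_profile`: list with `positions`
#'   (µm), `values`, `line` (endpoints).
#' @export
extract_profile <- function(vol, p0, p1, n_samples = 101L) {
  stopifnot(is_image_volume(vol))
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L)
    stop("endpoints must be (z, y, x) in um")
  if (all(p0 == p1)) stop("profile endpoints coincide")
  if (n_samples < 8L) stop("n_samples must be >= 8")
  sp <- spacing_zyx(vol$spacing)
  ext <- dim(vol$data) * sp
  for (p in list(p0, p1)) {
    if (any(p < 0) || any(p > ext))
      stop("profile endpoint outside the volume (extent ",
           paste(sprintf("%.3g", ext), collapse = " x "), " um)")
  }
  t <- seq(0, 1, length.out = n_samples)
  pts <- outer(t, p1 - p0) + rep(p0, each = n_samples)
  # physical -> 0-based fractional voxel index: centre of voxel i is (i+0.5)*sp
  zi <- pts[, 1] / sp[1] - 0.5
  yi <- pts[, 2] / sp[2] - 0.5
  xi <- pts[, 3] / sp[3] - 0.5
  len <- sqrt(sum((p1 - p0)^2))
  structure(list(positions = t * len,
                 values = trilinear_interp(vol$data, zi, yi, xi),
                 line = list(p0 = p0, p1 = p1)),
            class = "intensity_profile")
}

#' Pointwise mean of intensity profiles
#'
#' All profiles are resampled by linear interpolation onto the first
#' profile's position grid, then averaged pointwise.
#'
#' @param profiles Non-empty list of `intensity_profile` objects.
#' @return An `intensity_profile` on the first profile's grid.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "intensity_profile")))
  grid <- profiles[[1]]$positions
  vals <- vapply(profiles, function(p) {
    stats::approx(p$positions, p$values, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  structure(list(positions = grid,
                 values = rowMeans(as.matrix(vals)),
                 line = profiles[[1]]$line),
            class = "intensity_profile")
}

# Local maxima of a numeric vector with topographic prominence.
# Returns data.frame(index, height, prominence). Plateaus take their centre.
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  # collapse exact plateaus so sign changes are well-defined
  ds <- diff(v)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j <= n - 1L && v[j + 1L] < v[j]) cand <- c(cand, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(data.frame(index = integer(0), height = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(p) {
    h <- v[p]
    # walk left until a strictly higher point; key saddle = min along the way
    lmin <- h
    k <- p
    while (k > 1L && v[k] <= h) { k <- k - 1L; lmin <- min(lmin, v[k]) }
    lbase <- if (v[k] > h) lmin else min(v[1:p])
    rmin <- h
    k <- p
    while (k < n && v[k] <= h) { k <- k + 1L; rmin <- min(rmin, v[k]) }
    rbase <- if (v[k] > h) rmin else min(v[p:n])
    h - max(lbase, rbase)
  }, numeric(1))
  data.frame(index = cand, height = v[cand], prominence = prom)
}

#' Classify a cross-vessel intensity profile
#'
#' Smooths the profile with a Gaussian of the given FWHM, counts local
#' maxima whose prominence exceeds `prominence_frac` of the smoothed range,
#' and classifies: 0 peaks = `none`, 1 = `single` (cytosolic-like), 2 =
#' `double` (membrane-labelled lumenised vessel); more than 2 gives `none`
#' with a warning. For a double profile the relative lumen dip depth is
#' reported; `edge_width` is the mean distance over which the smoothed
#' profile falls from 80\% to 20\% of its maximum on the two outer flanks.
#'
#' @param profile An `intensity_profile`.
#' @param smoothing_fwhm Gaussian FWHM in µm (default 1).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   smoothed profile range (default 0.05).
#' @return Object of class `profile_class`: list with `shape`,
#'   `peak_positions` (µm), `dip_depth`, `edge_width` (µm), `n_peaks`.
#' @export
classify_profile <- function(profile, smoothing_fwhm = 1, prominence_frac = 0.05) {
  stopifnot(inherits(profile, "intensity_profile"))
  pos <- profile$positions
  dp <- pos[2] - pos[1]
  sm <- gaussian_smooth_1d(profile$values, smoothing_fwhm / 2.3548 / dp)
  rng <- max(sm) - min(sm)
  none <- structure(list(shape = "none", peak_positions = numeric(0),
                         dip_depth = NA_real_, edge_width = NA_real_,
                         n_peaks = 0L, smoothed = sm),
                    class = "profile_class")
  if (rng <= 1e-12 * max(abs(sm), 1)) return(none)  # flat up to float dust
  pk <- find_peaks(sm)
  pk <- pk[pk$prominence >= prominence_frac * rng, , drop = FALSE]
  np <- nrow(pk)
  if (np == 0L) return(none)
  if (np > 2L) {
    warning("profile has ", np, " prominent peaks; classifying as 'none'")
    none$n_peaks <- np
    return(none)
  }
  shape <- if (np == 1L) "single" else "double"
  dip <- NA_real_
  if (np == 2L) {
    between <- sm[pk$index[1]:pk$index[2]]
    dip <- (mean(pk$height) - min(between)) / mean(pk$height)
  }
  structure(list(shape = shape, peak_positions = pos[pk$index],
                 dip_depth = dip,
                 edge_width = edge_width_1d(pos, sm, pk$index),
                 n_peaks = np, smoothed = sm),
            class = "profile_class")
}

# Mean 80%->20%-of-max fall distance on the outer flanks.
edge_width_1d <- function(pos, sm, peak_idx) {
  m <- max(sm)
  cross_out <- function(idx, dir) {
    # walk outward from idx in direction dir; return positions of the first
    # crossings below 0.8 m and 0.2 m (linear interpolation), or NA
    p80 <- NA_real_; p20 <- NA_real_
    k <- idx
    n <- length(sm)
    while ((dir < 0 && k > 1L) || (dir > 0 && k < n)) {
      k2 <- k + dir
      for (lvl in c(0.8, 0.2)) {
        tgt <- lvl * m
        hit <- if (lvl == 0.8) is.na(p80) else is.na(p20)
        if (hit && sm[k] >= tgt && sm[k2] < tgt) {
          f <- (sm[k] - tgt) / (sm[k] - sm[k2])
          pp <- pos[k] + f * (pos[k2] - pos[k])
          if (lvl == 0.8) p80 <- pp else p20 <- pp
        }
      }
      k <- k2
    }
    if (is.na(p80) || is.na(p20)) NA_real_ else abs(p20 - p80)
  }
  w <- c(cross_out(min(peak_idx), -1L), cross_out(max(peak_idx), +1L))
  if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
}

#' @export
print.profile_class <- function(x, ...) {
  cat(sprintf("profile: %s (%d peak%s)", x$shape, x$n_peaks,
              if (x$n_peaks == 1L) "" else "s"))
  if (length(x$peak_positions))
    cat(" at ", paste(sprintf("%.2f", x$peak_positions), collapse = ", "), " um",
        sep = "")
  if (!is.na(x$dip_depth)) cat(sprintf("; dip depth %.2f", x$dip_depth))
  if (!is.na(x$edge_width)) cat(sprintf("; edge width %.2f um", x$edge_width))
  cat("\n")
  invisible(x)
}
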