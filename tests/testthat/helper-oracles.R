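# Shared fixtures and independent brute-force oracles. Oracles are written
# as directly as possible (loops, base eigen(), exhaustive searches) and are
# deliberately slower than the implementations they check.

spacing_iso <- function(s = 1) voxel_spacing(s, s, s)
spacing_lsfm <- function() voxel_spacing(0.334, 0.334, 0.69)

# a small straight cytosolic tube along x, for quick checks
tiny_tube_scene <- function(d = 4, peak = 6000, noise_sd = 0, poisson = FALSE,
                            seed = 1, shape = c(12L, 48L, 48L),
                            sp = voxel_spacing(0.5, 0.5, 1), mode = "cytosolic",
                            wall_fraction = 0.25) {
  zc <- shape[1] * spacing_zyx_(sp)[1] / 2
  ymid <- shape[2] * spacing_zyx_(sp)[2] / 2
  xmax <- shape[3] * spacing_zyx_(sp)[3]
  phantom_scene(shape, sp,
                list(tube_spec(rbind(c(zc, ymid, -1), c(zc, ymid, xmax + 1)),
                               diameter = d, label_mode = mode,
                               peak_intensity = peak,
                               wall_fraction = wall_fraction)),
                background_level = 100, noise_sd = noise_sd, poisson = poisson,
                seed = seed, name = "tiny")
}

spacing_zyx_ <- function(sp) unname(c(sp[["dz"]], sp[["dy"]], sp[["dx"]]))

# two crossing diagonal tubes: structure in both in-plane directions, so
# translations are identifiable (a single axis-parallel tube is degenerate
# for registration)
motion_scene <- function(noise_sd = 30, seed = 5, shape = c(4L, 64L, 64L),
                         sp = voxel_spacing(0.5, 0.5, 1)) {
  zc <- shape[1] * sp[["dz"]] / 2
  ymax <- shape[2] * sp[["dy"]]; xmax <- shape[3] * sp[["dx"]]
  phantom_scene(shape, sp,
                list(tube_spec(rbind(c(zc, 0.2 * ymax, -1), c(zc, 0.75 * ymax, xmax + 1)),
                               diameter = 4, peak_intensity = 6000),
                     tube_spec(rbind(c(zc, 0.8 * ymax, -1), c(zc, 0.3 * ymax, xmax + 1)),
                               diameter = 3, peak_intensity = 4000)),
                background_level = 100, noise_sd = noise_sd, poisson = noise_sd > 0,
                seed = seed, name = "motion")
}

# ---- oracles ---------------------------------------------------------------

oracle_median_disc <- function(slice, radius) {
  ny <- nrow(slice); nx <- ncol(slice)
  out <- slice
  mirror <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 2 - i, i)
      i <- ifelse(i > n, 2 * n - i, i)
    }
    i
  }
  for (y in 1:ny) for (x in 1:nx) {
    vals <- c()
    for (dy in -radius:radius) for (dx in -radius:radius) {
      if (dy^2 + dx^2 <= radius^2)
        vals <- c(vals, slice[mirror(y + dy, ny), mirror(x + dx, nx)])
    }
    out[y, x] <- median(vals)
  }
  out
}

# grayscale opening with an exact ball (border handled by omission)
oracle_ball_opening <- function(slice, radius) {
  ny <- nrow(slice); nx <- ncol(slice)
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2) - radius
  morph <- function(img, erode) {
    out <- matrix(if (erode) Inf else -Inf, ny, nx)
    for (y in 1:ny) for (x in 1:nx) {
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
        if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
        v <- if (erode) img[yy, xx] - offs$h[k] else img[yy, xx] + offs$h[k]
        out[y, x] <- if (erode) min(out[y, x], v) else max(out[y, x], v)
      }
    }
    out
  }
  morph(morph(slice, TRUE), FALSE)
}

# exhaustive O(bins^2) Otsu: try every boundary, compute class stats directly
oracle_otsu <- function(v, n_bins = 64L) {
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  best <- -Inf; best_thr <- breaks[2]
  for (k in 1:(n_bins - 1L)) {
    thr <- breaks[k + 1L]
    bin <- findInterval(v, breaks, all.inside = TRUE)
    lo <- v[bin <= k]; hi <- v[bin > k]
    if (!length(lo) || !length(hi)) next
    # between-class variance from binned means (same binning convention)
    mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    mu0 <- mean(mids[bin[bin <= k]]); mu1 <- mean(mids[bin[bin > k]])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_thr <- thr }
  }
  best_thr
}

# brute-force integer-shift search maximizing overlap Pearson correlation
oracle_shift_search <- function(ref, mov, max_shift) {
  best <- -Inf; best_s <- c(0, 0)
  d <- dim(ref)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ys_r <- max(1, 1 + dy):min(d[1], d[1] + dy)
    xs_r <- max(1, 1 + dx):min(d[2], d[2] + dx)
    ys_m <- ys_r - dy; xs_m <- xs_r - dx
    a <- ref[ys_r, xs_r]; b <- mov[ys_m, xs_m]
    if (sd(a) == 0 || sd(b) == 0) next
    r <- cor(as.vector(a), as.vector(b))
    if (r > best) { best <- r; best_s <- c(dy, dx) }
  }
  c(ty = best_s[1], tx = best_s[2])
}

# Gaussian-smoothed finite-difference + base::eigen tubeness oracle
oracle_tubeness <- function(vol, sigma) {
  sp <- spacing_zyx_(vol$spacing)
  f <- vascuseg:::gaussian_smooth_zyx(vol$data, sigma / sp)
  d <- dim(f)
  sh <- function(ax, by) {
    idx <- pmin(pmax(seq_len(d[ax]) + by, 1), d[ax])
    if (ax == 1) f[idx, , ] else if (ax == 2) f[, idx, ] else f[, , idx]
  }
  d2 <- function(a1, a2) {
    if (a1 == a2) (sh(a1, 1) - 2 * f + sh(a1, -1)) / sp[a1]^2
    else {
      g <- (sh(a1, 1) - sh(a1, -1)) / (2 * sp[a1])
      gd <- dim(g)
      shg <- function(ax, by) {
        idx <- pmin(pmax(seq_len(gd[ax]) + by, 1), gd[ax])
        if (ax == 1) g[idx, , ] else if (ax == 2) g[, idx, ] else g[, , idx]
      }
      (shg(a2, 1) - shg(a2, -1)) / (2 * sp[a2])
    }
  }
  Hzz <- d2(1, 1) * sigma^2; Hyy <- d2(2, 2) * sigma^2; Hxx <- d2(3, 3) * sigma^2
  Hzy <- d2(1, 2) * sigma^2; Hzx <- d2(1, 3) * sigma^2; Hyx <- d2(2, 3) * sigma^2
  out <- array(0, d)
  for (i in seq_along(out)) {
    M <- matrix(c(Hzz[i], Hzy[i], Hzx[i],
                  Hzy[i], Hyy[i], Hyx[i],
                  Hzx[i], Hyx[i], Hxx[i]), 3, 3)
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    out[i] <- if (ev[1] < 0 && ev[2] < 0) sqrt(ev[1] * ev[2]) else 0
  }
  out
}
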