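# Internal array math: separable Gaussian smoothing with reflective
# boundaries, edge-replicated shifts for finite differences, and bilinear
# resampling. Kept in plain R; the per-axis convolution is a banded matrix
# product, which BLAS handles quickly at the stack sizes this package targets.

# n x n convolution matrix for a 1D Gaussian (sd in voxels), symmetric
# (mirror) boundary handling. Kernel truncated at 4 sd.
gauss_conv_matrix <- function(n, sd_vox) {
  if (sd_vox <= 0) return(diag(n))
  L <- max(1L, ceiling(4 * sd_vox))
  w <- dnorm(-L:L, sd = sd_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in -L:L) {
    j <- idx + k
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 2L - j, j)       # reflect about 1 (edge repeated once)
      j <- ifelse(j > n, 2L * n - j, j)    # reflect about n
    }
    ij <- cbind(idx, j)
    K[ij] <- K[ij] + w[k + L + 1L]
  }
  K
}

# Smooth a (z,y,x) array with per-axis Gaussian sds given in voxels.
gaussian_smooth_zyx <- function(a, sd_vox) {
  d <- dim(a)
  if (sd_vox[1] > 0) {
    a <- array(gauss_conv_matrix(d[1], sd_vox[1]) %*% matrix(a, d[1]), d)
  }
  if (sd_vox[2] > 0) {
    ap <- aperm(a, c(2L, 1L, 3L))
    ap <- array(gauss_conv_matrix(d[2], sd_vox[2]) %*% matrix(ap, d[2]),
                c(d[2], d[1], d[3]))
    a <- aperm(ap, c(2L, 1L, 3L))
  }
  if (sd_vox[3] > 0) {
    ap <- aperm(a, c(3L, 2L, 1L))
    ap <- array(gauss_conv_matrix(d[3], sd_vox[3]) %*% matrix(ap, d[3]),
                c(d[3], d[2], d[1]))
    a <- aperm(ap, c(3L, 2L, 1L))
  }
  a
}

# Integer shift along one axis with edge replication (for central differences).
shift_replicate <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Smooth a 1D signal with a Gaussian (sd in samples), mirror boundaries.
gaussian_smooth_1d <- function(v, sd_samp) {
  if (sd_samp <= 0) return(v)
  as.numeric(gauss_conv_matrix(length(v), sd_samp) %*% v)
}

# Bilinear translation of a 2D matrix by (dy, dx) voxels (value at output
# pixel p is taken from input at p - shift). Out-of-field pixels are filled
# with `fill`; the returned "valid" attribute marks in-field pixels.
bilinear_shift_2d <- function(m, dy, dx, fill = 0) {
  d <- dim(m)
  ys <- seq_len(d[1]) - dy
  xs <- seq_len(d[2]) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  yin <- ys >= 1 & ys <= d[1]
  xin <- xs >= 1 & xs <= d[2]
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  y0c <- cl(y0, d[1]); y1c <- cl(y0 + 1, d[1])
  x0c <- cl(x0, d[2]); x1c <- cl(x0 + 1, d[2])
  w00 <- outer(1 - fy, 1 - fx)
  w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx)
  w11 <- outer(fy, fx)
  out <- m[y0c, x0c] * w00 + m[y0c, x1c] * w01 +
         m[y1c, x0c] * w10 + m[y1c, x1c] * w11
  valid <- outer(yin, xin)
  out[!valid] <- fill
  attr(out, "valid") <- valid
  out
}

# Trilinear interpolation of a (z,y,x) array at fractional voxel-index
# coordinates (0-based voxel centres; caller converts from physical units).
trilinear_interp <- function(a, zi, yi, xi) {
  d <- dim(a)
  cl <- function(i, n) pmin(pmax(i, 0), n - 1)
  zi <- cl(zi, d[1]); yi <- cl(yi, d[2]); xi <- cl(xi, d[3])
  z0 <- pmin(floor(zi), d[1] - 2); y0 <- pmin(floor(yi), d[2] - 2)
  x0 <- pmin(floor(xi), d[3] - 2)
  z0 <- pmax(z0, 0); y0 <- pmax(y0, 0); x0 <- pmax(x0, 0)
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  at <- function(z, y, x) a[cbind(z + 1, y + 1, x + 1)]
  v000 <- at(z0, y0, x0);     v001 <- at(z0, y0, x0 + 1)
  v010 <- at(z0, y0 + 1, x0); v011 <- at(z0, y0 + 1, x0 + 1)
  v100 <- at(z0 + 1, y0, x0); v101 <- at(z0 + 1, y0, x0 + 1)
  v110 <- at(z0 + 1, y0 + 1, x0); v111 <- at(z0 + 1, y0 + 1, x0 + 1)
  v00 <- v000 * (1 - fx) + v001 * fx
  v01 <- v010 * (1 - fx) + v011 * fx
  v10 <- v100 * (1 - fx) + v101 * fx
  v11 <- v110 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v01 * fy
  v1 <- v10 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

# Rescale values linearly so min -> 0 and max -> 2^depth - 1. Constant
# input maps to 0.
rescale_to_depth <- function(a, bit_depth) {
  top <- 2^bit_depth - 1
  rng <- range(a)
  if (rng[2] <= rng[1]) return(array(0, dim(a)))
  (a - rng[1]) / (rng[2] - rng[1]) * top
}

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All stochastic paths in the package funnel through
# this so results are reproducible and never perturb the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
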