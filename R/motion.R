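#' Rigid 2D transform (translation + optional rotation)
#'
#' @param tx,ty Translation along x (columns) and y (rows), in voxels;
#'   subvoxel values allowed.
#' @param theta In-plane rotation in radians (about the field centre).
#' @return Object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(tx = 0, ty = 0, theta = 0) {
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 theta = as.numeric(theta)),
            class = "rigid_transform2d")
}

is_identity_transform <- function(t, tol = 0) {
  abs(t$tx) <= tol && abs(t$ty) <= tol && abs(t$theta) <= tol
}

# Resample a 2D matrix under a rigid transform (content moves by (ty, tx),
# rotated by theta about the centre). Bilinear; fill 0; "valid" attribute.
resample_rigid_2d <- function(m, transform, fill = 0) {
  if (transform$theta == 0)
    return(bilinear_shift_2d(m, transform$ty, transform$tx, fill = fill))
  d <- dim(m)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  ct <- cos(transform$theta); st <- sin(transform$theta)
  ys <- ct * (yy - transform$ty) - st * (xx - transform$tx) + cy
  xs <- st * (yy - transform$ty) + ct * (xx - transform$tx) + cx
  valid <- ys >= 1 & ys <= d[1] & xs >= 1 & xs <= d[2]
  y0 <- pmin(pmax(floor(ys), 1), d[1] - 1)
  x0 <- pmin(pmax(floor(xs), 1), d[2] - 1)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  at <- function(dyy, dxx) m[cbind(as.vector(y0 + dyy), as.vector(x0 + dxx))]
  out <- (1 - fy) * (1 - fx) * at(0, 0) + (1 - fy) * fx * at(0, 1) +
         fy * (1 - fx) * at(1, 0) + fy * fx * at(1, 1)
  out <- matrix(out, d[1], d[2])
  out[!valid] <- fill
  attr(out, "valid") <- valid
  out
}

#' Apply a rigid 2D transform to a frame
#'
#' Bilinear resampling, applied slice-wise for 3D frames. Voxels sampled
#' from outside the field are filled with 0 and marked invalid in the
#' frame's `valid` mask so correlation measures can exclude them. Applying
#' a translation and then its negation recovers the original to
#' interpolation tolerance on smooth images.
#'
#' @param frame An [image_volume()] or 2D matrix.
#' @param transform A [rigid_transform2d()].
#' @return Same type as `frame`; `image_volume` results carry a `valid`
#'   logical array.
#' @export
apply_transform <- function(frame, transform) {
  stopifnot(inherits(transform, "rigid_transform2d"))
  if (is.matrix(frame)) return(resample_rigid_2d(frame, transform))
  stopifnot(is_image_volume(frame))
  if (is_identity_transform(transform)) {
    frame$valid <- array(TRUE, dim(frame$data))
    return(frame)
  }
  d <- dim(frame$data)
  out <- frame$data
  valid2d <- NULL
  for (z in seq_len(d[1])) {
    s <- resample_rigid_2d(frame$data[z, , ], transform)
    if (is.null(valid2d)) valid2d <- attr(s, "valid")
    out[z, , ] <- s
  }
  frame$data <- out
  frame$valid <- array(rep(valid2d, each = d[1]), d)
  frame
}

# Estimate the translation aligning `mov` to `ref`: windowed FFT
# cross-correlation locates the integer peak, then a hierarchical direct
# search maximizes the overlap-normalized Pearson correlation around it.
# Pixels marked invalid (zero-filled borders of resampled frames) are
# mean-filled for the FFT stage and excluded from the correlation in the
# refinement stage. Returns c(ty, tx): the shift to APPLY to mov.
estimate_shift_2d <- function(ref, mov, max_shift,
                              ref_valid = NULL, mov_valid = NULL) {
  d <- dim(ref)
  if (!is.null(ref_valid) && any(!ref_valid))
    ref[!ref_valid] <- mean(ref[ref_valid])
  if (!is.null(mov_valid) && any(!mov_valid))
    mov[!mov_valid] <- mean(mov[mov_valid])
  # Hann apodization: structure crossing the field edges otherwise wraps
  # around in the circular FFT correlation and drags the peak
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1))
  W <- outer(wy, wx)
  r0 <- (ref - mean(ref)) * W
  m0 <- (mov - mean(mov)) * W
  CP <- fft(r0) * Conj(fft(m0))
  X <- Re(fft(CP, inverse = TRUE))
  # index (i,j) corresponds to displacement u = (i-1, j-1) with wrap-around;
  # X(u) = sum_p ref(p + u) mov(p); if mov is ref moved by s, peak at u = -s,
  # and the aligning correction equals u*.
  uy <- c(0:(d[1] %/% 2), -((d[1] - 1) %/% 2):-1)
  ux <- c(0:(d[2] %/% 2), -((d[2] - 1) %/% 2):-1)
  allowed <- outer(abs(uy) <= max_shift, abs(ux) <= max_shift)
  Xm <- X
  Xm[!allowed] <- -Inf
  pk <- arrayInd(which.max(Xm), d)
  u0 <- c(uy[pk[1]], ux[pk[2]])
  # refine by hierarchical direct search maximizing the overlap-normalized
  # Pearson correlation (the FFT covariance peak is biased when structure
  # slides in and out of the field; the normalized overlap metric is not)
  # score on mildly smoothed copies, splitting the candidate shift equally
  # between the two images: both sides then suffer identical interpolation
  # blur at every candidate, removing the bias of bilinear resampling
  # toward integer shifts
  Ks <- gauss_conv_matrix(d[1], 1)
  Kx <- if (d[2] == d[1]) Ks else gauss_conv_matrix(d[2], 1)
  refS <- Ks %*% ref %*% t(Kx)
  movS <- Ks %*% mov %*% t(Kx)
  rv <- if (is.null(ref_valid)) matrix(1, d[1], d[2]) else ref_valid * 1
  mv <- if (is.null(mov_valid)) matrix(1, d[1], d[2]) else mov_valid * 1
  score <- function(dy, dx) {
    sr <- bilinear_shift_2d(refS, -dy / 2, -dx / 2)
    sm <- bilinear_shift_2d(movS, dy / 2, dx / 2)
    srv <- bilinear_shift_2d(rv, -dy / 2, -dx / 2)
    smv <- bilinear_shift_2d(mv, dy / 2, dx / 2)
    keep <- attr(sr, "valid") & attr(sm, "valid") &
      srv > 0.999 & smv > 0.999
    if (sum(keep) < 32) return(NA_real_)
    a <- sr[keep]; b <- sm[keep]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  best <- u0
  best_s <- score(best[1], best[2])
  for (lv in list(c(2, 0.5), c(0.4, 0.1), c(0.08, 0.02))) {
    grid_y <- best[1] + seq(-lv[1], lv[1], by = lv[2])
    grid_x <- best[2] + seq(-lv[1], lv[1], by = lv[2])
    for (gy in grid_y) for (gx in grid_x) {
      if (abs(gy) > max_shift + 1 || abs(gx) > max_shift + 1) next
      s <- score(gy, gx)
      if (!is.na(s) && s > best_s) { best <- c(gy, gx); best_s <- s }
    }
  }
  c(ty = best[1], tx = best[2])
}

# z-mean projection; carries the 2D valid mask of the frame (if any)
frame_projection <- function(frame) {
  d <- dim(frame$data)
  p <- if (d[1] == 1L) frame$data[1, , ] else apply(frame$data, c(2, 3), mean)
  attr(p, "valid2d") <- if (!is.null(frame$valid)) frame$valid[1, , ] else NULL
  p
}

pair_correlation <- function(a, b, valid_a = NULL, valid_b = NULL) {
  keep <- rep(TRUE, length(a))
  if (!is.null(valid_a)) keep <- keep & as.vector(valid_a)
  if (!is.null(valid_b)) keep <- keep & as.vector(valid_b)
  x <- as.vector(a)[keep]; y <- as.vector(b)[keep]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Mean successive-frame Pearson correlation of a time series
#'
#' The standard motion readout: Pearson correlation of voxel intensities
#' between each consecutive frame pair, averaged over pairs. Voxels marked
#' invalid in either frame (zero-filled after resampling) are excluded
#' pairwise. Pairs with a constant frame are skipped with a warning;
#' an error is raised if no pair is usable.
#'
#' @param series A [time_series()].
#' @return Mean Pearson r over successive pairs.
#' @export
series_correlation <- function(series) {
  stopifnot(inherits(series, "time_series"))
  n <- length(series$frames)
  rs <- numeric(0)
  for (k in seq_len(n - 1L)) {
    fa <- series$frames[[k]]; fb <- series$frames[[k + 1L]]
    r <- pair_correlation(fa$data, fb$data, fa$valid, fb$valid)
    if (is.na(r)) warning("constant frame in pair ", k, "-", k + 1, "; skipped")
    else rs <- c(rs, r)
  }
  if (!length(rs)) stop("no usable frame pair (all constant)")
  mean(rs)
}

#' Register a drifting time series
#'
#' Intensity-based rigid registration: each frame is aligned to its
#' reference (by default the previous, already-corrected frame, so drift is
#' corrected cumulatively) using windowed FFT cross-correlation of z-mean
#' projections with least-squares quadratic subpixel peak refinement.
#' Out-of-field voxels are zero-filled and excluded from all correlation
#' measures. Frames whose estimated shift exceeds `max_shift` are flagged
#' and left uncorrected. Rotation estimation (coarse grid search) can be
#' enabled but is off by default: embedding-medium drift is predominantly
#' translational.
#'
#' @param series A [time_series()].
#' @param reference `"previous"` (chained, default) or `"first"`.
#' @param allow_rotation Also search a small in-plane rotation.
#' @param max_shift Maximum allowed shift in voxels (default: 25\% of the
#'   smaller in-plane field extent).
#' @return List with `series` (corrected [time_series()]) and `report`
#'   (class `registration_report`): per-frame transforms and mean
#'   successive-frame correlation before/after.
#' @export
register_series <- function(series, reference = c("previous", "first"),
                            allow_rotation = FALSE, max_shift = NULL) {
  stopifnot(inherits(series, "time_series"))
  reference <- match.arg(reference)
  d <- dim(series$frames[[1]]$data)
  if (is.null(max_shift)) max_shift <- min(d[2], d[3]) %/% 5L
  if (max_shift > 0.25 * min(d[2], d[3]))
    stop("max_shift must stay below 25% of the field")
  corr_before <- series_correlation(series)
  n <- length(series$frames)
  corrected <- series
  transforms <- vector("list", n)
  transforms[[1]] <- rigid_transform2d()
  corrected$frames[[1]]$valid <- array(TRUE, d)
  flagged <- logical(n)
  # search somewhat beyond max_shift so over-limit drift is detected (and
  # flagged) rather than clipped to the window edge
  search <- min(ceiling(max_shift * 1.5) + 2, min(d[2], d[3]) %/% 3L)
  thetas <- if (allow_rotation) seq(-0.05, 0.05, by = 0.01) else 0
  for (k in 2:n) {
    refp <- frame_projection(corrected$frames[[switch(reference,
                                                      previous = k - 1L,
                                                      first = 1L)]])
    movp <- frame_projection(series$frames[[k]])
    best <- NULL
    for (th in thetas) {
      mv <- if (th == 0) movp else resample_rigid_2d(movp, rigid_transform2d(theta = th))
      mv_valid <- attr(mv, "valid")
      if (!is.null(attr(movp, "valid2d"))) {
        mv_valid <- if (is.null(mv_valid)) attr(movp, "valid2d") != 0
                    else mv_valid & (attr(movp, "valid2d") != 0)
      }
      sh <- estimate_shift_2d(refp, mv, search,
                              ref_valid = if (!is.null(attr(refp, "valid2d")))
                                attr(refp, "valid2d") != 0,
                              mov_valid = mv_valid)
      cand <- rigid_transform2d(tx = sh[["tx"]], ty = sh[["ty"]], theta = th)
      al <- resample_rigid_2d(movp, cand)
      sc <- pair_correlation(refp, al, valid_a = attr(refp, "valid2d"),
                             valid_b = attr(al, "valid"))
      if (is.null(best) || (!is.na(sc) && sc > best$score))
        best <- list(t = cand, score = sc)
    }
    t <- best$t
    if (max(abs(c(t$tx, t$ty))) > max_shift) {
      flagged[k] <- TRUE
      t <- rigid_transform2d()
    }
    transforms[[k]] <- t
    corrected$frames[[k]] <- apply_transform(series$frames[[k]], t)
  }
  corr_after <- series_correlation(corrected)
  report <- structure(
    list(transforms = transforms,
         table = data.frame(frame = seq_len(n),
                            tx = vapply(transforms, `[[`, numeric(1), "tx"),
                            ty = vapply(transforms, `[[`, numeric(1), "ty"),
                            theta = vapply(transforms, `[[`, numeric(1), "theta"),
                            flagged = flagged),
         correlation_before = corr_before,
         correlation_after = corr_after),
    class = "registration_report")
  list(series = corrected, report = report)
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("registration: %d frames, correlation %.3f -> %.3f%s\n",
              nrow(x$table), x$correlation_before, x$correlation_after,
              if (any(x$table$flagged)) sprintf(" (%d flagged uncorrected)",
                                                sum(x$table$flagged)) else ""))
  invisible(x)
}
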