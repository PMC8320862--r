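new_segmentation_result <- function(mask, method, params_echo, scalars) {
  structure(list(mask = mask, method = method, params_echo = params_echo,
                 threshold_or_centers = scalars),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation (%s): %d vascular voxels; %s = %s\n",
              x$method, sum(x$mask),
              if (x$method == "otsu") "threshold" else
                if (x$method == "kmeans") "centres" else "scalars",
              paste(signif(x$threshold_or_centers, 6), collapse = ", ")))
  invisible(x)
}

# Otsu threshold on a plain numeric vector; returns the bin boundary
# maximizing between-class variance (first = lowest on ties).
otsu_on_values <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (rng[2] <= rng[1]) stop("constant input: Otsu threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(v, breaks, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  sb <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[seq_len(n_bins - 1L)])
  breaks[k + 1L]
}

#' Global Otsu segmentation
#'
#' Builds an `n_bins` histogram between the observed minimum and maximum of
#' the whole 3D stack and thresholds at the bin boundary maximizing the
#' between-class variance (ties resolved toward the lower boundary).
#' Vascular voxels are those strictly above the threshold; the fluorescent
#' reporter is bright on dark.
#'
#' @param vol An [image_volume()] with at least 2 distinct intensities.
#' @param n_bins Histogram bins (default 256, the common reference-framework
#'   behaviour even for 16-bit input; raise for full-resolution binning).
#' @return A `segmentation_result` (`threshold_or_centers` = threshold).
#' @export
otsu_threshold <- function(vol, n_bins = 256L) {
  stopifnot(is_image_volume(vol))
  v <- as.vector(vol$data)
  thr <- otsu_on_values(v, n_bins)
  mask <- array(as.integer(vol$data > thr), dim(vol$data))
  new_segmentation_result(mask, "otsu",
                          list(n_bins = as.integer(n_bins),
                               input_range = range(v)),
                          c(threshold = thr))
}

#' Intensity k-means segmentation
#'
#' Lloyd iterations over the voxel-intensity histogram with k-means++
#' initialisation driven by `seed` (default 48, the conventional default
#' randomisation seed; `k = 4` detects one background cluster and three
#' vessel clusters of varying brightness). Convergence when the largest
#' centre displacement drops below `tol` grey levels. The vessel mask is
#' the union of the `k - 1` brightest clusters. Deterministic given the
#' seed; intensities are treated on their integer grid.
#'
#' @param vol An [image_volume()] with at least `k` distinct intensities.
#' @param k Number of clusters (>= 2).
#' @param tol Centre-displacement tolerance (default 1e-4).
#' @param seed RNG seed for the k-means++ initialisation (default 48).
#' @return A `segmentation_result` (`threshold_or_centers` = sorted centres).
#' @export
kmeans_segment <- function(vol, k = 4L, tol = 1e-4, seed = 48L) {
  stopifnot(is_image_volume(vol))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  v <- as.vector(vol$data)
  uv <- sort(unique(v))
  if (length(uv) < k)
    stop("volume has ", length(uv), " distinct intensities; fewer than k = ", k)
  cnt <- as.numeric(table(factor(v, levels = uv)))
  centres <- with_seed(seed, {
    cs <- numeric(k)
    cs[1] <- uv[sample.int(length(uv), 1L, prob = cnt)]
    d2 <- (uv - cs[1])^2
    for (j in seq_len(k - 1L) + 1L) {
      w <- cnt * d2
      if (sum(w) <= 0) w <- cnt
      cs[j] <- uv[sample.int(length(uv), 1L, prob = w)]
      d2 <- pmin(d2, (uv - cs[j])^2)
    }
    sort(cs)
  })
  for (it in seq_len(200L)) {
    bounds <- (centres[-1] + centres[-k]) / 2
    assign <- findInterval(uv, bounds) + 1L
    new_c <- vapply(seq_len(k), function(j) {
      sel <- assign == j
      if (!any(sel)) centres[j] else weighted.mean(uv[sel], cnt[sel])
    }, numeric(1))
    move <- max(abs(new_c - centres))
    centres <- sort(new_c)
    if (move < tol) break
  }
  bounds <- (centres[-1] + centres[-k]) / 2
  mask <- array(as.integer(vol$data > bounds[1]), dim(vol$data))
  new_segmentation_result(mask, "kmeans",
                          list(k = k, tol = tol, seed = as.integer(seed),
                               iterations = it,
                               background_boundary = bounds[1]),
                          centres)
}

#' Statistical region merging segmentation
#'
#' Regions start as single voxels; 6-connected neighbour pairs are processed
#' in ascending order of absolute intensity difference and merged when
#' `(mean_i - mean_j)^2 <= b2(Ri) + b2(Rj)` with
#' `b(R) = g * sqrt(log(2/delta) / (2 Q |R|))`, `g = 256`,
#' `delta = 1/(6 N^2)`. Larger `Q` merges less (the region count is
#' non-increasing in `1/Q`). SRM operates on 8-bit input; 16-bit volumes
#' are rescaled with a warning, matching the usual implementation
#' requirement. The merged region-mean image is binarized to a vessel mask
#' by Otsu.
#'
#' @param vol An [image_volume()].
#' @param Q Coarseness parameter (> 0; default 25).
#' @return A `segmentation_result`; `params_echo$n_regions` holds the
#'   region count, `params_echo$degenerate` flags a constant result.
#' @export
srm_segment <- function(vol, Q = 25) {
  stopifnot(is_image_volume(vol))
  if (Q <= 0) stop("`Q` must be positive")
  v <- vol$data
  rescaled <- FALSE
  if (vol$bit_depth > 8L || max(v) > 255) {
    warning("SRM requires 8-bit input; rescaling ", vol$bit_depth,
            "-bit volume to 0..255")
    v <- round(rescale_to_depth(v, 8L))
    rescaled <- TRUE
  }
  res <- .srm_3d(as.numeric(v), dim(v), Q, 256)
  means <- array(res$means, dim(v))
  degenerate <- res$n_regions == 1L || max(means) <= min(means)
  if (degenerate) {
    warning("SRM produced a single region; degenerate segmentation (empty mask)")
    mask <- array(0L, dim(v))
    thr <- NA_real_
  } else {
    thr <- otsu_on_values(as.vector(means), 256L)
    mask <- array(as.integer(means > thr), dim(v))
  }
  new_segmentation_result(mask, "srm",
                          list(Q = Q, g = 256, connectivity = 6L,
                               rescaled_to_8bit = rescaled,
                               n_regions = res$n_regions,
                               degenerate = degenerate),
                          c(region_mean_threshold = thr))
}

#' ROI-restricted vascular volume
#'
#' `Vol = N_vasc * V_voxel`: the count of vascular voxels inside the
#' quantification ROI times the physical voxel volume `dx*dy*dz`.
#'
#' @param seg A `segmentation_result` (or a binary mask array).
#' @param roi Non-empty binary quantification mask matching the mask shape.
#' @param spacing A [voxel_spacing()].
#' @return Object of class `volume_report`: `n_vascular_voxels`,
#'   `voxel_volume` (µm³), `volume_um3`, `roi_voxel_count`.
#' @export
vascular_volume <- function(seg, roi, spacing) {
  mask <- if (inherits(seg, "segmentation_result")) seg$mask else seg
  stopifnot(is.array(mask), is_voxel_spacing(spacing))
  if (!identical(dim(mask), dim(roi))) stop("mask and ROI shapes differ")
  nroi <- sum(roi != 0)
  if (nroi == 0L) stop("quantification ROI is empty")
  nv <- sum(mask != 0 & roi != 0)
  vv <- voxel_volume_um3(spacing)
  structure(list(n_vascular_voxels = nv, voxel_volume = vv,
                 volume_um3 = nv * vv, roi_voxel_count = nroi),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("vascular volume: %.2f um^3 (%d voxels x %.5f um^3; ROI %d voxels)\n",
              x$volume_um3, x$n_vascular_voxels, x$voxel_volume,
              x$roi_voxel_count))
  invisible(x)
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; the
#' robustness readout for repeated volume measurements.
#'
#' @param values Numeric vector (>= 2 values, nonzero mean).
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CoV undefined")
  100 * sd(values) / m
}
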