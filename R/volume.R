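#' 3D image volume
#'
#' The universal currency of the package: a 3D scalar intensity grid indexed
#' `(z, y, x)` together with its physical voxel spacing and declared sample
#' depth. Axis order is slice-major, matching multi-page microscopy TIFFs
#' (page = z slice, rows = y, columns = x). Voxel indices are 0-based in
#' physical-coordinate formulas: the centre of voxel `i` lies at
#' `(i + 0.5) * spacing` along its axis.
#'
#' @param data A 3D numeric array indexed `(z, y, x)`. A 2D matrix is
#'   promoted to a single-slice volume.
#' @param spacing A [voxel_spacing()].
#' @param bit_depth Declared sample depth, 8 or 16.
#' @param name Free-text provenance label.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `bit_depth`, `name`.
#' @seealso [validate_volume()], [read_volume()], [write_volume()]
#' @export
image_volume <- function(data, spacing, bit_depth = 16L, name = "") {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (!is_voxel_spacing(spacing)) stop("`spacing` must be a voxel_spacing object")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(list(data = data, spacing = spacing, bit_depth = bit_depth,
                 name = as.character(name)[1]),
            class = "image_volume")
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume '%s': %d x %d x %d voxels (z,y,x), %d-bit\n",
              x$name, d[1], d[2], d[3], x$bit_depth))
  print(x$spacing)
  cat(sprintf("intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Validate an image volume
#'
#' Checks every invariant of the data model and reports violations instead of
#' raising: spacing positivity/finiteness, non-negative intensities, and
#' intensities within the declared bit depth. An empty result means valid.
#'
#' @param vol An [image_volume()].
#' @return Character vector of violation descriptions (empty when valid).
#' @examples
#' v <- image_volume(array(0, c(2, 4, 4)), voxel_spacing(0.334, 0.334, 0.69))
#' validate_volume(v)  # character(0)
#' @export
validate_volume <- function(vol) {
  out <- character(0)
  if (!is_image_volume(vol)) return("not an image_volume object")
  sp <- unclass(vol$spacing)
  for (ax in c("dx", "dy", "dz")) {
    if (!is.finite(sp[[ax]]) || sp[[ax]] <= 0)
      out <- c(out, sprintf("spacing along %s is not strictly positive and finite",
                            sub("d", "", ax)))
  }
  if (!is.numeric(vol$data)) {
    out <- c(out, "intensity data is not numeric")
    return(out)
  }
  if (anyNA(vol$data)) out <- c(out, "intensity data contains NA")
  rng <- range(vol$data, na.rm = TRUE)
  if (rng[1] < 0) out <- c(out, "negative intensities present")
  top <- 2^vol$bit_depth - 1
  if (rng[2] > top)
    out <- c(out, sprintf("intensity %g exceeds declared %d-bit maximum %d",
                          rng[2], vol$bit_depth, top))
  out
}

#' Time series of image volumes
#'
#' An ordered sequence of frames sharing shape and spacing, with a fixed
#' frame interval. Frames may be thin (`nz = 1`) for effectively 2D series.
#'
#' @param frames List of [image_volume()] objects, all with identical shape
#'   and spacing; at least two.
#' @param dt Frame interval in seconds.
#' @return Object of class `time_series` with fields `frames`, `dt`.
#' @export
time_series <- function(frames, dt = 3) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a time series needs at least 2 frames")
  if (!all(vapply(frames, is_image_volume, logical(1))))
    stop("all frames must be image_volume objects")
  d0 <- dim(frames[[1]]$data)
  s0 <- spacing_zyx(frames[[1]]$spacing)
  for (k in seq_along(frames)) {
    if (!identical(dim(frames[[k]]$data), d0))
      stop("frame ", k, " has a different shape")
    if (max(abs(spacing_zyx(frames[[k]]$spacing) - s0)) > 1e-9)
      stop("frame ", k, " has a different spacing")
  }
  structure(list(frames = frames, dt = as.numeric(dt)), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$data)
  cat(sprintf("time_series: %d frames of %d x %d x %d (z,y,x), dt = %g s\n",
              length(x$frames), d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$frames)

#' Labelled ROI mask set
#'
#' Holds the binary masks used by quality control and volumetry: the vessel
#' ROI (mean vascular signal), a non-vascular tissue ROI, a background/noise
#' ROI, and the quantification ROI within which vascular volume is counted.
#' All masks are strictly binary and must match the reference volume shape.
#'
#' @param vessel,non_vascular,background,quantification Optional binary 3D
#'   arrays (any nonzero value is treated as 1).
#' @param reference Optional [image_volume()] whose shape the masks must match.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(vessel = NULL, non_vascular = NULL, background = NULL,
                    quantification = NULL, reference = NULL) {
  norm <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (is.matrix(m)) m <- array(m, c(1L, dim(m)))
    if (!is.array(m) || length(dim(m)) != 3L)
      stop(what, " mask must be a 3D array")
    if (!is.null(reference) && !identical(dim(m), dim(reference$data)))
      stop(what, " mask shape does not match the reference volume")
    array(as.integer(m != 0), dim(m))
  }
  out <- structure(list(vessel = norm(vessel, "vessel"),
                        non_vascular = norm(non_vascular, "non_vascular"),
                        background = norm(background, "background"),
                        quantification = norm(quantification, "quantification")),
                   class = "roi_set")
  if (!is.null(out$vessel) && !is.null(out$background) &&
      any(out$vessel & out$background))
    stop("vessel and background ROIs overlap")
  out
}

#' @export
print.roi_set <- function(x, ...) {
  for (nm in names(x)) {
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-14s %d voxels\n", nm, sum(x[[nm]])))
  }
  invisible(x)
}
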