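#' Physical voxel spacing
#'
#' Records the physical edge length of a voxel along each axis, in micrometres.
#' Light-sheet stacks are typically anisotropic (finer in-plane than axially),
#' so every operation that works in physical units converts through this
#' object. The anisotropy ratio `dz/dx` is recorded for convenience.
#'
#' @param dx,dy,dz Physical length per voxel along x, y and z (µm). All three
#'   must be strictly positive and finite.
#' @return An object of class `voxel_spacing`: a named numeric vector with
#'   elements `dx`, `dy`, `dz` and attribute `anisotropy` (`dz/dx`).
#' @examples
#' voxel_spacing(0.334, 0.334, 0.69)
#' @export
voxel_spacing <- function(dx, dy = dx, dz = dx) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0)) {
    bad <- names(s)[!is.finite(s) | s <= 0]
    stop("voxel spacing must be strictly positive and finite; offending axis: ",
         paste(sub("d", "", bad), collapse = ", "))
  }
  attr(s, "anisotropy") <- unname(s["dz"] / s["dx"])
  class(s) <- "voxel_spacing"
  s
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: %g x %g x %g um (x,y,z); anisotropy dz/dx = %.3g\n",
              x[["dx"]], x[["dy"]], x[["dz"]], attr(x, "anisotropy")))
  invisible(x)
}

is_voxel_spacing <- function(x) inherits(x, "voxel_spacing")

# spacing as c(z, y, x) -- the array axis order used throughout
spacing_zyx <- function(spacing) {
  unname(c(spacing[["dz"]], spacing[["dy"]], spacing[["dx"]]))
}

#' Voxel volume in cubic micrometres
#'
#' @param spacing A [voxel_spacing()].
#' @return `dx * dy * dz` (µm³).
#' @export
voxel_volume_um3 <- function(spacing) {
  stopifnot(is_voxel_spacing(spacing))
  unname(spacing[["dx"]] * spacing[["dy"]] * spacing[["dz"]])
}
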