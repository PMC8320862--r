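#' Read a multi-page grayscale TIFF as an image volume
#'
#' Pages become z slices. Voxel spacing is resolved in this order: an explicit
#' `spacing_override` always wins; otherwise embedded metadata (TIFF x/y
#' resolution tags plus an ImageJ-style `spacing=` entry in the description
#' tag, as written by ImageJ/Fiji and tifffile); otherwise a plain-text
#' sidecar file `<path>.meta` as written by [write_volume()]; otherwise an
#' error, because physical-unit filtering is meaningless without spacing.
#'
#' @param path TIFF file path.
#' @param spacing_override Optional [voxel_spacing()] taking precedence over
#'   any file metadata.
#' @param name Provenance label; defaults to the file name.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  if (length(dim(pages[[1]])) > 2L)
    stop("RGB/multi-channel TIFF not supported; supply a grayscale stack")
  bits <- info$bits.per.sample
  if (is.null(bits) || !bits %in% c(8L, 16L))
    stop("only 8- and 16-bit grayscale TIFFs are supported")
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]

  spacing <- spacing_override
  if (is.null(spacing)) spacing <- spacing_from_tiff_info(info)
  if (is.null(spacing)) spacing <- spacing_from_sidecar(paste0(path, ".meta"))
  if (is.null(spacing))
    stop("no voxel spacing available for ", path,
         ": none embedded, no sidecar, and no spacing_override given")
  image_volume(arr, spacing, bit_depth = bits, name = name)
}

#' Write an image volume to a multi-page grayscale TIFF
#'
#' Intensities are rounded and stored at the declared bit depth. Because the
#' available TIFF writer cannot embed resolution/description tags, the voxel
#' spacing (plus depth and name) is stored in a plain-text sidecar
#' `<path>.meta`; [read_volume()] understands both the sidecar and genuine
#' embedded metadata, and `read_volume(write_volume(v))` is the identity on
#' data, shape, bit depth and spacing.
#'
#' @param vol An [image_volume()]; must pass [validate_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  bad <- validate_volume(vol)
  if (length(bad)) stop("refusing to write invalid volume: ", paste(bad, collapse = "; "))
  top <- 2^vol$bit_depth - 1
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) round(vol$data[k, , ]) / top)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = vol$bit_depth,
                                 reduce = FALSE),
                 error = function(e) stop("cannot write TIFF at ", path, ": ",
                                          conditionMessage(e)))
  yaml::write_yaml(list(dx = unname(vol$spacing[["dx"]]),
                        dy = unname(vol$spacing[["dy"]]),
                        dz = unname(vol$spacing[["dz"]]),
                        unit = "micron",
                        bit_depth = vol$bit_depth,
                        name = vol$name),
                   paste0(path, ".meta"))
  invisible(path)
}

#' Read a binary mask TIFF aligned to a reference volume
#'
#' Any nonzero voxel is part of the mask. A single-page TIFF can be broadcast
#' over all z slices of the reference when `broadcast = TRUE` (per-slice 2D
#' ROI polygons exported as a flat mask).
#'
#' @param path TIFF file path.
#' @param reference [image_volume()] defining the target shape.
#' @param broadcast Broadcast a single page over z.
#' @return Binary integer 3D array matching `dim(reference$data)`.
#' @export
read_mask <- function(path, reference, broadcast = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is_image_volume(reference))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(reference$data)
  pd <- dim(pages[[1]])
  if (!identical(as.integer(pd), as.integer(d[2:3])))
    stop("mask page size ", pd[1], "x", pd[2],
         " does not match reference ", d[2], "x", d[3])
  if (length(pages) == 1L && d[1] > 1L) {
    if (!broadcast)
      stop("mask has 1 page but reference has ", d[1],
           " slices; pass broadcast = TRUE to replicate it over z")
    m <- array(0L, d)
    for (k in seq_len(d[1])) m[k, , ] <- as.integer(pages[[1]] != 0)
    return(m)
  }
  if (length(pages) != d[1])
    stop("mask has ", length(pages), " pages but reference has ", d[1], " slices")
  m <- array(0L, d)
  for (k in seq_len(d[1])) m[k, , ] <- as.integer(pages[[k]] != 0)
  m
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param mask Binary 3D array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  pages <- lapply(seq_len(dim(mask)[1]), function(k) (mask[k, , ] != 0) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

# ---- metadata helpers ------------------------------------------------------

# Parse an ImageJ-style TIFF description string ("key=value" lines).
# Returns a named character vector.
parse_imagej_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(character(0))
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  if (!length(lines)) return(character(0))
  out <- trimws(sub("^[^=]*=", "", lines))
  names(out) <- trimws(sub("=.*$", "", lines))
  out
}

meta_field <- function(meta, key) {
  if (key %in% names(meta)) unname(meta[[key]]) else NULL
}

spacing_from_tiff_info <- function(info) {
  xres <- info$x.resolution
  yres <- info$y.resolution
  meta <- parse_imagej_description(info$description)
  unit <- meta_field(meta, "unit")
  if (is.null(xres) || is.null(unit) || !unit %in% c("um", "micron", "µm"))
    return(NULL)
  dz <- suppressWarnings(as.numeric(meta_field(meta, "spacing")))
  if (!length(dz) || is.na(dz)) return(NULL)
  dx <- 1 / xres
  dy <- if (!is.null(yres)) 1 / yres else dx
  voxel_spacing(dx, dy, dz)
}

spacing_from_sidecar <- function(meta_path) {
  if (!file.exists(meta_path)) return(NULL)
  m <- tryCatch(yaml::read_yaml(meta_path), error = function(e) NULL)
  if (is.null(m) || is.null(m$dx) || is.null(m$dy) || is.null(m$dz)) return(NULL)
  voxel_spacing(m$dx, m$dy, m$dz)
}
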