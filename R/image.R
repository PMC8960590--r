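#' Single-channel image plane
#'
#' The unit every analysis stage consumes: a 2D grid of non-negative
#' intensities with a physical pixel size. Intensities live on the native
#' integer scale of the acquisition (`0 .. 2^bit_depth - 1`) but are stored
#' as doubles so that processed (background-subtracted, smoothed) planes can
#' carry fractional values.
#'
#' @param pixels numeric matrix of intensities, all in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size_nm physical size of one pixel edge, nanometres.
#' @param channel marker name, e.g. `"psd95"`, `"vglut2"`, `"pap"`.
#' @param bit_depth 8 or 16.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size_nm, channel = "unknown",
                        bit_depth = 16L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a single positive number")
  }
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (any(pixels > 2^bit_depth - 1)) {
    stop("intensities exceed the range of the stated bit depth")
  }
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel = channel, bit_depth = as.integer(bit_depth)),
    class = "image_plane"
  )
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

#' @export
print.image_plane <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_plane> %d x %d px, %.3g nm/px, channel '%s', %d-bit\n",
    d[1], d[2], x$pixel_size_nm, x$channel, x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a single-plane TIFF as an image plane
#'
#' Reads 8- or 16-bit single-plane grayscale TIFF. Pixel size is taken from
#' TIFF resolution tags when present, else from a `<file>.meta.yaml` sidecar
#' (written by [write_image()]), else from the `pixel_size_nm` override; with
#' none of the three available the call errors and names the override.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm optional override for the physical pixel size.
#' @param channel optional channel name override.
#' @return An [image_plane()].
#' @export
read_image <- function(path, pixel_size_nm = NULL, channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  if (length(dim(px)) != 2) {
    stop("expected a single-plane grayscale TIFF: ", path)
  }
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits) || !bits %in% c(8L, 16L)) {
    stop("unsupported bit depth (need 8 or 16): ", path)
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  psz <- pixel_size_nm
  if (is.null(psz)) {
    xres <- attr(px, "x.resolution")  # pixels per resolution unit
    unit <- attr(px, "resolution.unit")
    if (!is.null(xres) && xres > 0 && identical(unit, "cm")) {
      psz <- 1e7 / xres
    } else if (!is.null(meta$pixel_size_nm)) {
      psz <- meta$pixel_size_nm
    }
  }
  if (is.null(psz)) {
    stop("pixel size not found in TIFF metadata or sidecar for '", path,
         "'; pass pixel_size_nm= to override")
  }
  if (is.null(channel)) {
    channel <- if (!is.null(meta$channel)) meta$channel else "unknown"
  }
  m <- matrix(as.numeric(px), nrow = nrow(px))
  image_plane(m, pixel_size_nm = psz, channel = channel,
              bit_depth = as.integer(bits))
}

#' Write an image plane as a single-plane TIFF
#'
#' Writes an uncompressed grayscale TIFF at the plane's native bit depth.
#' Intensities are rounded to the integer grid. Pixel size and channel are
#' recorded in a `<file>.meta.yaml` sidecar so that [read_image()] can
#' restore them.
#'
#' @param image an [image_plane()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_plane"))
  maxv <- 2^image$bit_depth - 1
  m <- round(pmin(pmax(image$pixels, 0), maxv)) / maxv
  tiff::writeTIFF(m, path, bits.per.sample = image$bit_depth,
                  compression = "none")
  yaml::write_yaml(
    list(pixel_size_nm = image$pixel_size_nm, channel = image$channel,
         bit_depth = image$bit_depth),
    sidecar_path(path))
  invisible(path)
}
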