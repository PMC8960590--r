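#' Names of the eight Rexed laminae groupings used for spinal cord mapping
#'
#' Laminae I-II and III-IV are merged, as is conventional for hemisection
#' synaptome maps; VIII covers medial motor pools and IX lateral motor pools.
#' @export
REGION_NAMES <- c("I-II", "III-IV", "V", "VI", "VII", "VIII", "IX", "X")

#' Build a synthetic region atlas
#'
#' Partitions a rectangular field into the eight laminae regions used by the
#' mapping analysis. This stands in for the hand-drawn laminae delineation of
#' real hemisection maps: `"bands"` slices the field into horizontal bands of
#' near-equal height (dorsal I-II at the top through X at the bottom),
#' `"wedges"` into angular sectors around the field centre.
#'
#' @param field_size_px integer `(rows, cols)`.
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param layout `"bands"` or `"wedges"`.
#' @return An object of class `region_atlas`: integer label image (1..8,
#'   row-major), region names, per-region area in square micrometres.
#' @export
build_region_atlas <- function(field_size_px, pixel_size_nm,
                               layout = c("bands", "wedges")) {
  layout <- match.arg(layout)
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 1),
            pixel_size_nm > 0)
  nr <- as.integer(field_size_px[1]); nc <- as.integer(field_size_px[2])
  n_reg <- length(REGION_NAMES)
  labels <- matrix(0L, nr, nc)
  if (layout == "bands") {
    if (nr < n_reg) {
      stop(sprintf("field too small: %d rows cannot hold %d band regions",
                   nr, n_reg))
    }
    # near-equal bands; earlier (dorsal) bands absorb the remainder
    sizes <- rep(nr %/% n_reg, n_reg)
    extra <- nr %% n_reg
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    row_lab <- rep(seq_len(n_reg), times = sizes)
    labels[] <- row_lab[row(labels)]
  } else {
    if (nr < 3 || nc < 3) {
      stop("field too small for a wedges atlas (need at least 3 x 3)")
    }
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    ang <- atan2(row(labels) - cr, col(labels) - cc)  # (-pi, pi]
    idx <- pmin(n_reg, 1L + as.integer(floor((ang + pi) / (2 * pi) * n_reg)))
    labels[] <- idx
    if (length(unique(as.vector(labels))) < n_reg) {
      stop("field too small: wedges layout left a region with no pixels")
    }
  }
  counts <- tabulate(labels, nbins = n_reg)
  area_um2 <- counts * (pixel_size_nm / 1000)^2
  names(area_um2) <- REGION_NAMES
  structure(
    list(labels = labels, region_names = REGION_NAMES,
         pixel_size_nm = pixel_size_nm, region_area_um2 = area_um2),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<region_atlas> %d x %d px at %.3g nm/px, %d regions\n",
              d[1], d[2], x$pixel_size_nm, length(x$region_names)))
  print(round(x$region_area_um2, 2))
  invisible(x)
}

#' Write / read a region atlas as a label TIFF plus a region-name CSV
#' @param atlas a `region_atlas`.
#' @param tif_path label-image TIFF path; the name CSV goes next to it.
#' @return `tif_path`, invisibly.
#' @export
write_atlas <- function(atlas, tif_path) {
  img <- image_plane(matrix(as.numeric(atlas$labels), nrow(atlas$labels)),
                     atlas$pixel_size_nm, channel = "atlas", bit_depth = 16L)
  write_image(img, tif_path)
  utils::write.csv(
    data.frame(label = seq_along(atlas$region_names),
               region = atlas$region_names,
               area_um2 = as.numeric(atlas$region_area_um2)),
    paste0(tools::file_path_sans_ext(tif_path), "_regions.csv"),
    row.names = FALSE)
  invisible(tif_path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(tif_path) {
  img <- read_image(tif_path)
  reg <- utils::read.csv(
    paste0(tools::file_path_sans_ext(tif_path), "_regions.csv"))
  labels <- matrix(as.integer(round(img$pixels)), nrow(img$pixels))
  counts <- tabulate(labels, nbins = nrow(reg))
  area <- counts * (img$pixel_size_nm / 1000)^2
  names(area) <- reg$region
  structure(
    list(labels = labels, region_names = reg$region,
         pixel_size_nm = img$pixel_size_nm, region_area_um2 = area),
    class = "region_atlas")
}
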