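#' Assign STED-resolved nanoclusters to confocal-resolved PSDs
#'
#' Structures resolved in the STED plane are nanoclusters (NCs); the larger
#' diffraction-limited structures of the paired confocal plane are whole
#' PSDs. Each NC goes to the PSD whose mask contains its centroid pixel; an
#' NC whose centroid is in no PSD mask but whose own mask overlaps at least
#' one PSD goes to the PSD with maximal overlap (ties broken by nearer PSD
#' centroid, then lower PSD id); anything else is an orphan. The rule is a
#' documented package choice — assignment conventions are not standardised.
#'
#' @param psd_set `puncta_set` from the confocal plane.
#' @param nc_set `puncta_set` from the co-registered STED plane (identical
#'   shape and pixel size).
#' @return An object of class `nano_assignment`: `nc` table (`nc_id`,
#'   `psd_id` with NA for orphans, `diameter_nm`), `per_psd` table
#'   (`psd_id`, `nc_count`), `orphan_nc_ids`.
#' @export
assign_nanoclusters <- function(psd_set, nc_set) {
  stopifnot(inherits(psd_set, "puncta_set"), inherits(nc_set, "puncta_set"))
  if (!all(psd_set$dim == nc_set$dim)) {
    stop("confocal and STED planes have different shapes")
  }
  if (!isTRUE(all.equal(psd_set$pixel_size_nm, nc_set$pixel_size_nm))) {
    stop("confocal and STED planes have different pixel sizes")
  }
  ncs <- nc_set$puncta
  psd_lab <- psd_set$label_image
  assigned <- rep(NA_integer_, nrow(ncs))
  if (nrow(ncs) > 0) {
    r <- pmin(pmax(round(ncs$centroid_row), 1), nrow(psd_lab))
    c_ <- pmin(pmax(round(ncs$centroid_col), 1), ncol(psd_lab))
    hit <- psd_lab[cbind(r, c_)]
    assigned[hit > 0] <- hit[hit > 0]
    # fall back to maximal mask overlap for centroid misses
    need <- which(is.na(assigned))
    if (length(need)) {
      ov <- overlap_map(nc_set, psd_set)
      ov <- ov[ov$id_a %in% ncs$id[need], , drop = FALSE]
      if (nrow(ov)) {
        for (i in need) {
          cand <- ov[ov$id_a == ncs$id[i], , drop = FALSE]
          if (!nrow(cand)) next
          cand <- cand[cand$overlap_px == max(cand$overlap_px), ,
                       drop = FALSE]
          if (nrow(cand) > 1) {
            pc <- psd_set$puncta[match(cand$id_b, psd_set$puncta$id), ]
            d2 <- (pc$centroid_row - ncs$centroid_row[i])^2 +
                  (pc$centroid_col - ncs$centroid_col[i])^2
            cand <- cand[order(d2, cand$id_b), , drop = FALSE]
          }
          assigned[i] <- cand$id_b[1]
        }
      }
    }
  }
  nc_tab <- data.frame(nc_id = ncs$id, psd_id = assigned,
                       diameter_nm = ncs$eq_diameter_nm,
                       area_um2 = ncs$area_um2)
  counts <- table(factor(assigned, levels = psd_set$puncta$id))
  per_psd <- data.frame(psd_id = psd_set$puncta$id,
                        nc_count = as.integer(counts))
  structure(list(nc = nc_tab, per_psd = per_psd,
                 orphan_nc_ids = ncs$id[is.na(assigned)],
                 pixel_size_nm = nc_set$pixel_size_nm),
            class = "nano_assignment")
}

#' @export
print.nano_assignment <- function(x, ...) {
  cat(sprintf(
    "<nano_assignment> %d NCs over %d PSDs (%d orphans); mean %.2f NCs/PSD with >=1 NC\n",
    nrow(x$nc), nrow(x$per_psd), length(x$orphan_nc_ids),
    mean(x$per_psd$nc_count[x$per_psd$nc_count > 0])))
  invisible(x)
}

#' Nanocluster size metrics
#'
#' Equivalent circular diameter (`2 sqrt(area / pi)`) per NC and, per PSD,
#' the NC count and mean NC diameter.
#'
#' @param assignment a [assign_nanoclusters()] result.
#' @return List with `per_nc` and `per_psd` data frames.
#' @export
nc_metrics <- function(assignment) {
  stopifnot(inherits(assignment, "nano_assignment"))
  per_nc <- assignment$nc[, c("nc_id", "psd_id", "diameter_nm")]
  ass <- assignment$nc[!is.na(assignment$nc$psd_id), , drop = FALSE]
  if (nrow(ass)) {
    agg <- stats::aggregate(ass$diameter_nm, by = list(psd_id = ass$psd_id),
                            FUN = mean)
    per_psd <- merge(assignment$per_psd, agg, by = "psd_id", all.x = TRUE)
    names(per_psd)[names(per_psd) == "x"] <- "mean_nc_diameter_nm"
  } else {
    per_psd <- assignment$per_psd
    per_psd$mean_nc_diameter_nm <- rep(NA_real_, nrow(per_psd))
  }
  list(per_nc = per_nc, per_psd = per_psd)
}

#' Synapse subtype distribution by nanocluster count
#'
#' Bins PSDs with at least one assigned NC into the 1-NC, 2-NC and 3+NC
#' subtypes, reports subtype frequencies (summing to 1 over that
#' population), the mean NC count per PSD, and — separately — the number of
#' PSDs with no detected NC (excluded as an undetectable-NC artifact).
#'
#' @param assignment a [assign_nanoclusters()] result.
#' @return An object of class `subtype_distribution`: `counts`, `frequencies`
#'   (named `1`, `2`, `3+`), `mean_nc_per_psd`, `n_psd`, `n_zero_nc`.
#' @export
subtype_distribution <- function(assignment) {
  stopifnot(inherits(assignment, "nano_assignment"))
  k <- assignment$per_psd$nc_count
  n_zero <- sum(k == 0)
  k <- k[k > 0]
  if (!length(k)) stop("no PSDs with at least one assigned nanocluster")
  bin <- cut(k, breaks = c(0.5, 1.5, 2.5, Inf), labels = c("1", "2", "3+"))
  counts <- table(bin)
  structure(list(counts = as.integer(counts),
                 frequencies = as.numeric(counts) / length(k),
                 classes = names(counts),
                 mean_nc_per_psd = mean(k),
                 n_psd = length(k), n_zero_nc = n_zero),
            class = "subtype_distribution")
}

#' @export
print.subtype_distribution <- function(x, ...) {
  cat(sprintf(
    "<subtype_distribution> n = %d PSDs (+%d with 0 NCs excluded), mean %.2f NCs/PSD\n",
    x$n_psd, x$n_zero_nc, x$mean_nc_per_psd))
  cat(sprintf("  %s: %.1f%%", x$classes, 100 * x$frequencies), sep = "\n")
  invisible(x)
}
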