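#' Cross-channel punctum overlap map
#'
#' Object-based colocalisation on binarised masks: every pair of puncta
#' (one from each set) whose pixel masks share at least one pixel is
#' recorded with the shared-pixel count. Symmetric in its arguments up to
#' column order.
#'
#' @param a,b `puncta_set`s derived from images of identical shape and
#'   pixel size.
#' @return Data frame with columns `id_a`, `id_b`, `overlap_px`
#'   (`overlap_px >= 1` for every row).
#' @export
overlap_map <- function(a, b) {
  stopifnot(inherits(a, "puncta_set"), inherits(b, "puncta_set"))
  if (!all(a$dim == b$dim)) stop("puncta sets derive from different image shapes")
  if (!isTRUE(all.equal(a$pixel_size_nm, b$pixel_size_nm))) {
    stop("puncta sets derive from different pixel sizes")
  }
  la <- a$label_image; lb <- b$label_image
  joint <- la > 0 & lb > 0
  if (!any(joint)) {
    return(data.frame(id_a = integer(), id_b = integer(),
                      overlap_px = integer()))
  }
  key <- paste(la[joint], lb[joint])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  out <- data.frame(id_a = as.integer(parts[, 1]),
                    id_b = as.integer(parts[, 2]),
                    overlap_px = as.integer(tab))
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Classify PSD puncta into tripartite and non-tripartite synapses
#'
#' In `"triple"` mode (PSD95 + VGLUT2 + PAP marker), a PSD punctum that
#' overlaps at least one presynaptic punctum counts as a synapse; among
#' synapses, those that also overlap at least one PAP punctum are
#' tripartite, the rest non-tripartite; PSDs without presynaptic overlap
#' yield no record. In `"psd_pap"` mode (e.g. human tissue labelled for
#' PSD95 and p-Ezrin only) every PSD punctum is a synapse and is classed by
#' PAP overlap alone. All overlap matches use the >= 1 shared pixel
#' criterion; a punctum may match several partners and all matches are kept.
#'
#' @param psd `puncta_set` of the PSD95 channel.
#' @param presyn `puncta_set` of the presynaptic channel (required in
#'   triple mode, ignored otherwise).
#' @param pap `puncta_set` of the PAP-marker channel.
#' @param mode `"triple"` or `"psd_pap"`.
#' @param pap_marker name recorded in the output (`"p-Ezrin"`, `"EAAT2"`,
#'   or any other partner set such as a zDHHC2 channel).
#' @return An object of class `synapse_records`: data frame `records` (one
#'   row per synapse: `psd_id`, centroid, area, match counts and id lists,
#'   `synapse_class`) plus count summary.
#' @export
classify_synapses <- function(psd, presyn = NULL, pap,
                              mode = c("triple", "psd_pap"),
                              pap_marker = "p-Ezrin") {
  mode <- match.arg(mode)
  stopifnot(inherits(psd, "puncta_set"), inherits(pap, "puncta_set"))
  if (mode == "triple" && !inherits(presyn, "puncta_set")) {
    stop("triple mode requires a presynaptic puncta set")
  }
  ov_pap <- overlap_map(psd, pap)
  pap_by_psd <- split(ov_pap$id_b, ov_pap$id_a)
  if (mode == "triple") {
    ov_pre <- overlap_map(psd, presyn)
    pre_by_psd <- split(ov_pre$id_b, ov_pre$id_a)
    syn_ids <- sort(unique(ov_pre$id_a))
  } else {
    pre_by_psd <- list()
    syn_ids <- psd$puncta$id
  }
  join <- function(ids) paste(ids, collapse = ";")
  pre_n <- vapply(as.character(syn_ids),
                  function(k) length(pre_by_psd[[k]]), integer(1))
  pap_n <- vapply(as.character(syn_ids),
                  function(k) length(pap_by_psd[[k]]), integer(1))
  pi_ <- psd$puncta[match(syn_ids, psd$puncta$id), ]
  records <- data.frame(
    psd_id = syn_ids,
    centroid_row = pi_$centroid_row, centroid_col = pi_$centroid_col,
    area_um2 = pi_$area_um2,
    n_presyn = pre_n, n_pap = pap_n,
    matched_presyn_ids = vapply(as.character(syn_ids), function(k)
      join(pre_by_psd[[k]]), character(1)),
    matched_pap_ids = vapply(as.character(syn_ids), function(k)
      join(pap_by_psd[[k]]), character(1)),
    synapse_class = ifelse(pap_n > 0, "tripartite", "non_tripartite"),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records, mode = mode, pap_marker = pap_marker,
                 pixel_size_nm = psd$pixel_size_nm, dim = psd$dim,
                 n_synapses = nrow(records),
                 n_tripartite = sum(records$synapse_class == "tripartite"),
                 n_non_tripartite =
                   sum(records$synapse_class == "non_tripartite")),
            class = "synapse_records")
}

#' @export
print.synapse_records <- function(x, ...) {
  cat(sprintf(
    "<synapse_records> %d synapses (%s mode, PAP marker %s): %d tripartite, %d non-tripartite\n",
    x$n_synapses, x$mode, x$pap_marker, x$n_tripartite,
    x$n_non_tripartite))
  invisible(x)
}

#' Write synapse records as CSV with a per-class count summary
#' @param records a `synapse_records`.
#' @param csv_path output CSV path.
#' @param provenance optional named list for the comment header.
#' @return `csv_path`, invisibly.
#' @export
write_synapse_records <- function(records, csv_path, provenance = list()) {
  write_table_csv(records$records, csv_path, provenance = c(
    list(mode = records$mode, pap_marker = records$pap_marker,
         n_synapses = records$n_synapses,
         n_tripartite = records$n_tripartite,
         n_non_tripartite = records$n_non_tripartite), provenance))
  invisible(csv_path)
}
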