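# Shared fixture builders and independent oracles.

# Minimal image plane from a bare matrix.
img_of <- function(m, px = 100, bit = 16L, channel = "psd95") {
  image_plane(m, pixel_size_nm = px, channel = channel, bit_depth = bit)
}

# A puncta_set built directly from a label matrix (bypassing detection),
# for colocalisation / assignment tests with hand-placed masks.
pset_of <- function(label, px = 100) {
  ids <- sort(unique(label[label > 0]))
  stopifnot(identical(as.integer(ids), seq_along(ids)))  # compact ids
  if (!length(ids)) {
    return(structure(list(
      puncta = data.frame(id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_px = integer(),
                          area_um2 = numeric(), mean_intensity = numeric(),
                          eq_diameter_nm = numeric()),
      label_image = label, threshold_used = 0,
      params = detection_params(min_area_um2 = 0, max_area_um2 = Inf),
      pixel_size_nm = px, channel = "synthetic", dim = dim(label)),
      class = "puncta_set"))
  }
  idx <- which(label > 0)
  l <- label[idx]
  rr <- ((idx - 1L) %% nrow(label)) + 1L
  cc <- ((idx - 1L) %/% nrow(label)) + 1L
  area_px <- tabulate(l, nbins = length(ids))
  puncta <- data.frame(
    id = seq_along(ids),
    centroid_row = rowsum(as.numeric(rr), l)[, 1] / area_px,
    centroid_col = rowsum(as.numeric(cc), l)[, 1] / area_px,
    area_px = area_px,
    area_um2 = area_px * (px / 1000)^2,
    mean_intensity = 1,
    eq_diameter_nm = 2 * sqrt(area_px * px^2 / pi))
  structure(list(puncta = puncta, label_image = label, threshold_used = 0,
                 params = detection_params(min_area_um2 = 0,
                                           max_area_um2 = Inf),
                 pixel_size_nm = px, channel = "synthetic",
                 dim = dim(label)),
            class = "puncta_set")
}

# Random disjoint-blob label image: n discs of radius r at random centres,
# later blobs skip pixels already claimed (masks stay disjoint).
random_label_image <- function(nr, nc, n, r = 2) {
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (i in seq_len(n)) {
    cr <- sample(seq_len(nr), 1); cc <- sample(seq_len(nc), 1)
    rows <- max(1, cr - r):min(nr, cr + r)
    cols <- max(1, cc - r):min(nc, cc + r)
    disc <- outer(rows - cr, cols - cc, function(a, b) a^2 + b^2 <= r^2)
    sel <- which(disc & lab[rows, cols] == 0L)
    if (!length(sel)) next
    k <- k + 1L
    sub <- lab[rows, cols]; sub[sel] <- k
    lab[rows, cols] <- sub
  }
  lab
}

# A hand-built ground-truth scene: entities at given nm positions, each with
# nc_offsets (list of 2-col matrices relative to the PSD centre).
manual_scene <- function(params, atlas, x, y, nc_offsets = NULL,
                         has_presyn = TRUE, has_pap = FALSE,
                         amplitude = 200) {
  n <- length(x)
  if (is.null(nc_offsets)) {
    nc_offsets <- replicate(n, cbind(0, 0), simplify = FALSE)
  }
  region_of <- function(xi, yi) {
    r <- pmin(pmax(round(yi / params$pixel_size_nm + 0.5), 1),
              nrow(atlas$labels))
    c_ <- pmin(pmax(round(xi / params$pixel_size_nm + 0.5), 1),
               ncol(atlas$labels))
    atlas$region_names[atlas$labels[cbind(r, c_)]]
  }
  entities <- data.frame(
    id = seq_len(n), x_nm = x, y_nm = y, region = region_of(x, y),
    nc_count = vapply(nc_offsets, nrow, integer(1)),
    has_presyn = rep_len(has_presyn, n), has_pap = rep_len(has_pap, n),
    presyn_x_nm = x + params$presyn_offset_nm,
    presyn_y_nm = y,
    pap_x_nm = x + params$pap_offset_nm, pap_y_nm = y,
    presyn_amplitude = amplitude, pap_amplitude = amplitude)
  nc <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(entity_id = i, x_nm = x[i] + nc_offsets[[i]][, 1],
               y_nm = y[i] + nc_offsets[[i]][, 2], amplitude = amplitude)
  }))
  nc$nc_id <- seq_len(nrow(nc))
  structure(list(entities = entities, nc = nc,
                 aggregates = data.frame(x_nm = numeric(), y_nm = numeric(),
                                         diameter_um = numeric()),
                 atlas = atlas, params = params),
            class = "ground_truth_scene")
}

noise_free <- function(modality = "confocal", background = 0) {
  optics_model(modality, background_level = background,
               poisson_scale = 0, read_noise_sd = 0)
}

# Optics at a stated peak signal-to-background-noise ratio: Poisson on
# background 10 plus read noise topping total background noise SD up to
# peak / snr (default peak 200 from scene_params).
snr_optics <- function(snr, peak = 200, modality = "confocal") {
  sd_total <- peak / snr
  read_sd <- sqrt(max(sd_total^2 - 10, 0))  # Poisson var of bg 10 is 10
  optics_model(modality, background_level = 10, poisson_scale = 1,
               read_noise_sd = read_sd)
}

# Greedy 1-1 matching of detected centroids to ground-truth centres within
# tol_px; returns recall/precision and mean matched distance.
match_detections <- function(pset, scene, tol_px = 1) {
  px <- pset$pixel_size_nm
  gt_r <- scene$entities$y_nm / px + 0.5
  gt_c <- scene$entities$x_nm / px + 0.5
  det_r <- pset$puncta$centroid_row; det_c <- pset$puncta$centroid_col
  if (!length(gt_r) || !length(det_r)) {
    return(list(recall = 0, precision = 0, n_matched = 0))
  }
  d <- sqrt(outer(det_r, gt_r, "-")^2 + outer(det_c, gt_c, "-")^2)
  matched_gt <- logical(length(gt_r)); matched_det <- logical(length(det_r))
  repeat {
    d_min <- min(d[!matched_det, !matched_gt, drop = FALSE], Inf)
    if (!is.finite(d_min) || d_min > tol_px) break
    w <- which(d == d_min & outer(!matched_det, !matched_gt), arr.ind = TRUE)[1, ]
    matched_det[w[1]] <- TRUE; matched_gt[w[2]] <- TRUE
    d[w[1], ] <- Inf; d[, w[2]] <- Inf
  }
  list(recall = mean(matched_gt), precision = mean(matched_det),
       n_matched = sum(matched_gt))
}

# --- independent oracles -------------------------------------------------

# Moments threshold via an independent route: solve the three
# moment-preservation equations numerically (the two representative levels
# are roots of the quadratic whose coefficients come from solving the
# 2x2 Gram system by polyroot/solve rather than the closed form), then
# apply the shared p0-tile convention.
oracle_moments <- function(pixels, bit_depth = 8L) {
  lv <- pmin(pmax(floor(pixels), 0), 2^bit_depth - 1)
  h <- tabulate(as.integer(lv) + 1L, nbins = 2^bit_depth)
  p <- h / sum(h)
  z <- seq_along(p) - 1
  m <- vapply(1:3, function(k) sum(z^k * p), numeric(1))
  # Solve [1 m1; m1 m2] c = -[m2; m3] for the quadratic z^2 + c1 z + c0 = 0
  A <- matrix(c(1, m[1], m[1], m[2]), 2, 2)
  cvec <- solve(A, -c(m[2], m[3]))  # (c0, c1)
  roots <- sort(Re(polyroot(c(cvec[1], cvec[2], 1))))
  p0 <- (roots[2] - m[1]) / (roots[2] - roots[1])
  cum <- cumsum(p)
  z[which(cum >= p0 - 1e-9)[1]]
}

# Brute-force flood fill (8-connectivity) returning a label matrix.
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- k
      r <- ((cur - 1L) %% nrow(mask)) + 1L
      c_ <- ((cur - 1L) %/% nrow(mask)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          nx <- (cc - 1L) * nrow(mask) + rr
          if (mask[nx] && lab[nx] == 0L) stack <- c(stack, nx)
        }
      }
    }
  }
  lab
}

# Brute-force overlap pairs by explicit pixel-set intersection.
brute_overlaps <- function(la, lb) {
  out <- list()
  for (a in seq_len(max(la, 0))) {
    pa <- which(la == a)
    for (b in seq_len(max(lb, 0))) {
      ov <- length(intersect(pa, which(lb == b)))
      if (ov >= 1) out[[length(out) + 1L]] <-
          data.frame(id_a = a, id_b = b, overlap_px = ov)
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = integer(), id_b = integer(),
                      overlap_px = integer()))
  }
  do.call(rbind, out)
}
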