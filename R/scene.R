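#' Optical model for the forward renderer
#'
#' An isotropic Gaussian point-spread function with a constant background and
#' a Poisson-then-Gaussian camera noise model. The confocal default FWHM is
#' 320 nm (the lateral resolution of the mapping microscope); the STED
#' default of 70 nm is a module parameter chosen inside the usual gated-STED
#' operating range, since super-resolution instruments are specified only as
#' "sub-diffraction" rather than by a single number.
#'
#' Shot noise draws `Poisson(poisson_scale * intensity) / poisson_scale`;
#' `poisson_scale = 0` disables it, `read_noise_sd = 0` disables the additive
#' Gaussian term, giving exact noise-free renderings for oracle tests.
#'
#' @param modality `"confocal"` or `"sted"`.
#' @param psf_fwhm_nm full width at half maximum of the PSF, nm.
#' @param background_level constant background intensity.
#' @param poisson_scale photons per intensity unit (0 = no shot noise).
#' @param read_noise_sd SD of additive Gaussian read noise (0 = none).
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(modality = c("confocal", "sted"),
                         psf_fwhm_nm = NULL,
                         background_level = 10,
                         poisson_scale = 1,
                         read_noise_sd = 2) {
  modality <- match.arg(modality)
  if (is.null(psf_fwhm_nm)) {
    psf_fwhm_nm <- if (modality == "confocal") 320 else 70
  }
  stopifnot(psf_fwhm_nm > 0, background_level >= 0, poisson_scale >= 0,
            read_noise_sd >= 0)
  structure(list(modality = modality, psf_fwhm_nm = psf_fwhm_nm,
                 background_level = background_level,
                 poisson_scale = poisson_scale,
                 read_noise_sd = read_noise_sd),
            class = "optics_model")
}

#' Parameters of a synthetic synaptome scene
#'
#' Defaults describe a plausible spinal cord grey-matter field: per-lamina
#' PSD densities of 20-40 puncta per 100 um^2, a quarter of synapses
#' contacted by a perisynaptic astrocytic process (tripartite), and PSDs
#' built from 1-4 nanoclusters of 140 nm diameter spaced at least 150 nm
#' apart. Real per-lamina densities are not published for this tissue, so
#' the density defaults are order-of-magnitude placeholders; all are
#' configurable.
#'
#' @param field_size_px `(rows, cols)` of the rendered field.
#' @param pixel_size_nm physical pixel size; 100 nm suits confocal mapping,
#'   20 nm suits STED-scale fields.
#' @param psd_density puncta per 100 um^2; a single number or a vector named
#'   by region (recycled over the atlas regions).
#' @param tripartite_fraction probability that a synapse carries a PAP
#'   contact.
#' @param presyn_fraction probability that a PSD has an apposed presynaptic
#'   terminal (default 1: every generated entity is a synapse).
#' @param presyn_offset_nm distance of the presynaptic punctum centre from
#'   the PSD centre (apposed, partially overlapping at default sizes).
#' @param pap_offset_nm distance of the PAP punctum centre from the PSD
#'   centre; small enough to guarantee >= 1 px mask overlap.
#' @param nc_count_distribution probabilities over 1, 2, 3, 4 nanoclusters
#'   per PSD; must sum to 1.
#' @param nc_diameter_nm nanocluster diameter (physical structure size).
#' @param nc_spacing_nm minimum centre-to-centre distance between
#'   nanoclusters within one PSD.
#' @param presyn_diameter_nm,pap_diameter_nm physical structure sizes of the
#'   presynaptic and astrocytic puncta.
#' @param punctum_peak_intensity,punctum_peak_sd mean and SD of per-structure
#'   peak brightness (truncated normal, floor at 20% of the mean).
#' @param psd_min_spacing_nm hard minimum distance between PSD centres
#'   (0 = pure homogeneous Poisson placement, the default).
#' @param edge_margin_nm keep-out margin from the field border.
#' @param aggregate_count number of bright lipofuscin-like discs to inject.
#' @param aggregate_diameter_um disc diameter range (min, max) in um.
#' @param seed integer seed controlling every stochastic step.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(field_size_px = c(256L, 256L),
                         pixel_size_nm = 100,
                         psd_density = c("I-II" = 40, "III-IV" = 35,
                                         "V" = 30, "VI" = 30, "VII" = 25,
                                         "VIII" = 25, "IX" = 20, "X" = 20),
                         tripartite_fraction = 0.25,
                         presyn_fraction = 1,
                         presyn_offset_nm = 200,
                         pap_offset_nm = 100,
                         nc_count_distribution = c(0.45, 0.32, 0.15, 0.08),
                         nc_diameter_nm = 140,
                         nc_spacing_nm = 150,
                         presyn_diameter_nm = 300,
                         pap_diameter_nm = 250,
                         punctum_peak_intensity = 200,
                         punctum_peak_sd = 30,
                         psd_min_spacing_nm = 0,
                         edge_margin_nm = 600,
                         aggregate_count = 0,
                         aggregate_diameter_um = c(3, 6),
                         seed = 1L) {
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_nm = pixel_size_nm, psd_density = psd_density,
            tripartite_fraction = tripartite_fraction,
            presyn_fraction = presyn_fraction,
            presyn_offset_nm = presyn_offset_nm,
            pap_offset_nm = pap_offset_nm,
            nc_count_distribution = nc_count_distribution,
            nc_diameter_nm = nc_diameter_nm, nc_spacing_nm = nc_spacing_nm,
            presyn_diameter_nm = presyn_diameter_nm,
            pap_diameter_nm = pap_diameter_nm,
            punctum_peak_intensity = punctum_peak_intensity,
            punctum_peak_sd = punctum_peak_sd,
            psd_min_spacing_nm = psd_min_spacing_nm,
            edge_margin_nm = edge_margin_nm,
            aggregate_count = aggregate_count,
            aggregate_diameter_um = aggregate_diameter_um,
            seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  probs <- c(p$tripartite_fraction, p$presyn_fraction,
             p$nc_count_distribution)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p$nc_count_distribution) - 1) > 1e-8) {
    stop("nc_count_distribution must sum to 1")
  }
  if (any(p$psd_density < 0)) stop("densities must be non-negative")
  lens <- c(p$pixel_size_nm, p$nc_diameter_nm, p$nc_spacing_nm,
            p$presyn_diameter_nm, p$pap_diameter_nm)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (length(p$field_size_px) != 2 || any(p$field_size_px < 1)) {
    stop("field_size_px must be two positive integers")
  }
  invisible(p)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so that simulation never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nanocluster constellation: a regular n-gon of circumradius just large
# enough that every chord is >= spacing, randomly rotated and dilated by up
# to 25%, then recentred so the constellation mean sits at the PSD centre.
# This guarantees the minimum spacing exactly, which the resolution tests
# rely on.
place_ncs <- function(n, spacing) {
  if (n == 1) return(cbind(x = 0, y = 0))
  base_r <- spacing / (2 * sin(pi / n))
  r <- base_r * stats::runif(1, 1, 1.25)
  th <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(n) / n
  xy <- cbind(x = r * cos(th), y = r * sin(th))
  sweep(xy, 2, colMeans(xy))
}

#' Sample a ground-truthed synthetic scene
#'
#' Places PSD centres by a homogeneous spatial point process within each
#' atlas region at that region's density (counts are Poisson with mean
#' `density x area / 100`), marks each entity tripartite with probability
#' `tripartite_fraction`, draws a nanocluster count from
#' `nc_count_distribution` and lays the nanocluster centres out within the
#' PSD footprint respecting `nc_spacing_nm`. Per-structure peak amplitudes
#' are drawn here so the same structure is equally bright in paired
#' confocal/STED renderings. Deterministic given `params$seed`.
#'
#' @param params a [scene_params()].
#' @param atlas a [build_region_atlas()] result; must share `pixel_size_nm`.
#' @return An object of class `ground_truth_scene` with elements `entities`
#'   (one row per synapse: centre in nm, region, nc_count, has_presyn,
#'   has_pap, partner centres, amplitudes), `nc` (one row per nanocluster),
#'   `aggregates`, `atlas`, `params`.
#' @export
sample_scene <- function(params, atlas) {
  stopifnot(inherits(params, "scene_params"), inherits(atlas, "region_atlas"))
  if (!isTRUE(all.equal(params$pixel_size_nm, atlas$pixel_size_nm))) {
    stop("params and atlas disagree on pixel size")
  }
  if (!all(dim(atlas$labels) == params$field_size_px)) {
    stop("params and atlas disagree on field size")
  }
  with_seed(params$seed, sample_scene_impl(params, atlas))
}

sample_scene_impl <- function(params, atlas) {
  px <- params$pixel_size_nm
  nr <- params$field_size_px[1]; nc_ <- params$field_size_px[2]
  field_h_nm <- nr * px; field_w_nm <- nc_ * px
  n_reg <- length(atlas$region_names)
  dens <- rep_len(params$psd_density, n_reg)
  margin <- params$edge_margin_nm
  min_sp <- params$psd_min_spacing_nm

  ent_list <- list()
  all_x <- numeric(0); all_y <- numeric(0)  # spacing is enforced globally
  for (ri in seq_len(n_reg)) {
    lam <- dens[ri] * atlas$region_area_um2[ri] / 100
    n <- if (lam > 0) stats::rpois(1, lam) else 0L
    if (n == 0) next
    pix_idx <- which(atlas$labels == ri)  # column-major linear indices
    xs <- ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n + 200L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "placement failed in region '%s': density too high for the %s",
          atlas$region_names[ri],
          if (min_sp > 0) "minimum PSD spacing" else "usable area"))
      }
      k <- pix_idx[sample.int(length(pix_idx), 1L)]
      r0 <- ((k - 1L) %% nrow(atlas$labels)) + 1L
      c0 <- ((k - 1L) %/% nrow(atlas$labels)) + 1L
      y <- (r0 - stats::runif(1)) * px
      x <- (c0 - stats::runif(1)) * px
      if (y < margin || x < margin ||
          y > field_h_nm - margin || x > field_w_nm - margin) next
      if (min_sp > 0 && length(all_x) > 0) {
        d2 <- (all_x - x)^2 + (all_y - y)^2
        if (min(d2) < min_sp^2) next
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      all_x <- c(all_x, x); all_y <- c(all_y, y)
    }
    ent_list[[ri]] <- data.frame(x_nm = xs, y_nm = ys,
                                 region = atlas$region_names[ri],
                                 stringsAsFactors = FALSE)
  }
  entities <- if (length(ent_list)) do.call(rbind, ent_list) else
    data.frame(x_nm = numeric(), y_nm = numeric(), region = character())
  n_ent <- nrow(entities)
  rownames(entities) <- NULL

  if (n_ent > 0) {
    entities$id <- seq_len(n_ent)
    entities$nc_count <- sample.int(
      length(params$nc_count_distribution), n_ent, replace = TRUE,
      prob = params$nc_count_distribution)
    entities$has_presyn <- stats::runif(n_ent) < params$presyn_fraction
    entities$has_pap <- stats::runif(n_ent) < params$tripartite_fraction
    th_p <- stats::runif(n_ent, 0, 2 * pi)
    entities$presyn_x_nm <- entities$x_nm +
      params$presyn_offset_nm * cos(th_p)
    entities$presyn_y_nm <- entities$y_nm +
      params$presyn_offset_nm * sin(th_p)
    th_a <- stats::runif(n_ent, 0, 2 * pi)
    entities$pap_x_nm <- entities$x_nm + params$pap_offset_nm * cos(th_a)
    entities$pap_y_nm <- entities$y_nm + params$pap_offset_nm * sin(th_a)
    amp <- function(n) pmax(
      stats::rnorm(n, params$punctum_peak_intensity, params$punctum_peak_sd),
      0.2 * params$punctum_peak_intensity)
    entities$presyn_amplitude <- amp(n_ent)
    entities$pap_amplitude <- amp(n_ent)

    nc_rows <- vector("list", n_ent)
    for (i in seq_len(n_ent)) {
      xy <- place_ncs(entities$nc_count[i], params$nc_spacing_nm)
      nc_rows[[i]] <- data.frame(
        entity_id = entities$id[i],
        x_nm = entities$x_nm[i] + xy[, "x"],
        y_nm = entities$y_nm[i] + xy[, "y"],
        amplitude = amp(nrow(xy)))
    }
    nc <- do.call(rbind, nc_rows)
    nc$nc_id <- seq_len(nrow(nc))
    entities <- entities[, c("id", "x_nm", "y_nm", "region", "nc_count",
                             "has_presyn", "has_pap",
                             "presyn_x_nm", "presyn_y_nm",
                             "pap_x_nm", "pap_y_nm",
                             "presyn_amplitude", "pap_amplitude")]
  } else {
    entities <- data.frame(id = integer(), x_nm = numeric(),
                           y_nm = numeric(), region = character(),
                           nc_count = integer(), has_presyn = logical(),
                           has_pap = logical(), presyn_x_nm = numeric(),
                           presyn_y_nm = numeric(), pap_x_nm = numeric(),
                           pap_y_nm = numeric(),
                           presyn_amplitude = numeric(),
                           pap_amplitude = numeric())
    nc <- data.frame(entity_id = integer(), x_nm = numeric(),
                     y_nm = numeric(), amplitude = numeric(),
                     nc_id = integer())
  }

  n_agg <- params$aggregate_count
  if (n_agg > 0) {
    dia_um <- stats::runif(n_agg, params$aggregate_diameter_um[1],
                           params$aggregate_diameter_um[2])
    rad_nm <- dia_um * 1000 / 2
    aggregates <- data.frame(
      x_nm = stats::runif(n_agg, rad_nm, field_w_nm - rad_nm),
      y_nm = stats::runif(n_agg, rad_nm, field_h_nm - rad_nm),
      diameter_um = dia_um)
  } else {
    aggregates <- data.frame(x_nm = numeric(), y_nm = numeric(),
                             diameter_um = numeric())
  }

  structure(list(entities = entities, nc = nc, aggregates = aggregates,
                 atlas = atlas, params = params),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_scene> %d entities (%d tripartite), %d nanoclusters, %d aggregates\n",
    nrow(x$entities), sum(x$entities$has_pap), nrow(x$nc),
    nrow(x$aggregates)))
  invisible(x)
}

# Deterministic per-channel/modality seed offsets for rendering noise.
render_seed <- function(params, channel, modality) {
  ch <- match(channel, c("psd95", "vglut2", "pap"))
  md <- match(modality, c("confocal", "sted"))
  (params$seed + 7919L * ch + 104729L * md) %% .Machine$integer.max
}

# Render Gaussian spots (peaks `amps`, shared FWHM in nm) at physical
# positions (xs, ys) onto a fresh image matrix. The kernel is separable,
# evaluated on a +/- 4 sigma window; the matrix is mutated in place inside
# the loop (single local reference), which keeps rendering linear in the
# number of spots rather than in spots x pixels.
render_spots <- function(nr, nc, xs, ys, amps, fwhm_nm, px) {
  img <- matrix(0, nr, nc)
  if (!length(xs)) return(img)
  sigma_px <- fwhm_nm / (2 * sqrt(2 * log(2))) / px
  w <- ceiling(4 * sigma_px)
  two_s2 <- 2 * sigma_px^2
  r0s <- ys / px + 0.5  # 1-based pixel-centre coordinates
  c0s <- xs / px + 0.5
  for (i in seq_along(xs)) {
    r0 <- r0s[i]; c0 <- c0s[i]
    rows <- max(1, floor(r0 - w)):min(nr, ceiling(r0 + w))
    cols <- max(1, floor(c0 - w)):min(nc, ceiling(c0 + w))
    if (!length(rows) || !length(cols)) next
    gr <- exp(-(rows - r0)^2 / two_s2)
    gc <- exp(-(cols - c0)^2 / two_s2)
    img[rows, cols] <- img[rows, cols] + amps[i] * (gr %o% gc)
  }
  img
}

#' Render one channel of a scene under a given optical model
#'
#' The forward model of the measurement chain: every fluorophore site
#' (nanocluster centres for `psd95`, presynaptic/PAP punctum centres for the
#' other channels) becomes an isotropic Gaussian spot whose FWHM is the
#' larger of the PSF FWHM and the physical structure size; a constant
#' background is added, then Poisson shot noise and Gaussian read noise.
#' Under confocal optics, nanoclusters of one PSD blur into a single
#' diffraction-limited blob; under STED optics they resolve individually —
#' the dichotomy the nanostructure analysis relies on. Deterministic given
#' the scene seed.
#'
#' @param scene a [sample_scene()] result.
#' @param channel `"psd95"`, `"vglut2"` or `"pap"`.
#' @param optics an [optics_model()].
#' @return An [image_plane()] (16-bit scale) with the modality recorded in
#'   attribute `"modality"`.
#' @export
render <- function(scene, channel = c("psd95", "vglut2", "pap"), optics) {
  channel <- match.arg(channel)
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(optics, "optics_model"))
  p <- scene$params
  px <- p$pixel_size_nm

  if (channel == "psd95") {
    sites <- scene$nc
    fwhm <- max(optics$psf_fwhm_nm, p$nc_diameter_nm)
  } else if (channel == "vglut2") {
    sites <- scene$entities[scene$entities$has_presyn,
                            c("presyn_x_nm", "presyn_y_nm",
                              "presyn_amplitude")]
    names(sites) <- c("x_nm", "y_nm", "amplitude")
    fwhm <- max(optics$psf_fwhm_nm, p$presyn_diameter_nm)
  } else {
    sites <- scene$entities[scene$entities$has_pap,
                            c("pap_x_nm", "pap_y_nm", "pap_amplitude")]
    names(sites) <- c("x_nm", "y_nm", "amplitude")
    fwhm <- max(optics$psf_fwhm_nm, p$pap_diameter_nm)
  }
  img <- render_spots(p$field_size_px[1], p$field_size_px[2],
                      sites$x_nm, sites$y_nm, sites$amplitude, fwhm, px)
  img <- img + optics$background_level

  with_seed(render_seed(p, channel, optics$modality), {
    if (optics$poisson_scale > 0) {
      img[] <- stats::rpois(length(img),
                            optics$poisson_scale * pmax(img, 0)) /
        optics$poisson_scale
    }
    if (optics$read_noise_sd > 0) {
      img[] <- img + stats::rnorm(length(img), 0, optics$read_noise_sd)
    }
  })
  img[] <- pmin(pmax(img, 0), 2^16 - 1)
  out <- image_plane(img, pixel_size_nm = px, channel = channel,
                     bit_depth = 16L)
  attr(out, "modality") <- optics$modality
  out
}

#' Inject bright lipofuscin-like aggregate discs into a rendered image
#'
#' Stamps the aggregates recorded in the scene's ground truth as saturating
#' discs. Their diameters (configured well above the detection maximum size
#' filter) let tests confirm that the size filter excludes them.
#'
#' @param image an [image_plane()] rendered from `scene`.
#' @param scene the [sample_scene()] result holding the aggregate table.
#' @return The image with aggregates stamped in.
#' @export
inject_aggregates <- function(image, scene) {
  stopifnot(inherits(image, "image_plane"),
            inherits(scene, "ground_truth_scene"))
  agg <- scene$aggregates
  if (nrow(agg) == 0) return(image)
  px <- image$pixel_size_nm
  maxv <- 2^image$bit_depth - 1
  m <- image$pixels
  rr <- (row(m) - 0.5) * px
  cc <- (col(m) - 0.5) * px
  for (i in seq_len(nrow(agg))) {
    rad <- agg$diameter_um[i] * 1000 / 2
    hit <- (rr - agg$y_nm[i])^2 + (cc - agg$x_nm[i])^2 <= rad^2
    m[hit] <- maxv
  }
  image$pixels <- m
  image
}

#' Remove a fraction of tripartite entities from a scene
#'
#' Models selective tripartite synapse loss: the given fraction of
#' ground-truth tripartite entities is deleted outright (all channels);
#' non-tripartite entities are untouched. Used to build case cohorts with a
#' known planted effect.
#'
#' @param scene a [sample_scene()] result.
#' @param fraction fraction of tripartite entities to remove, in `[0, 1]`.
#' @param seed integer seed for the removal draw.
#' @return The thinned scene.
#' @export
thin_tripartite <- function(scene, fraction, seed = scene$params$seed + 1L) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0 || !nrow(scene$entities)) return(scene)
  tri_ids <- scene$entities$id[scene$entities$has_pap]
  n_drop <- round(fraction * length(tri_ids))
  if (n_drop == 0) return(scene)
  drop <- with_seed(seed, tri_ids[sample.int(length(tri_ids), n_drop)])
  scene$entities <- scene$entities[!scene$entities$id %in% drop, ]
  scene$nc <- scene$nc[!scene$nc$entity_id %in% drop, ]
  scene
}

#' Write a scene's ground truth, atlas and parameters to a directory
#'
#' Ground truth as CSV (one row per entity), nanocluster table as CSV, atlas
#' as label TIFF + region CSV, parameters echoed as YAML.
#'
#' @param scene a [sample_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scene$entities, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$nc, file.path(dir, "nanoclusters.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$aggregates, file.path(dir, "aggregates.csv"),
                   row.names = FALSE)
  write_atlas(scene$atlas, file.path(dir, "atlas.tif"))
  pars <- scene$params
  class(pars) <- NULL
  pars$psd_density <- as.list(pars$psd_density)
  yaml::write_yaml(pars, file.path(dir, "scene_params.yaml"))
  invisible(dir)
}
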