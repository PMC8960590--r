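#' Write a table as CSV with a provenance comment header
#'
#' Every output table carries `#`-prefixed header lines recording the
#' package version, the configuration hash and any extra provenance fields
#' (seed, channel, thresholds ...), so a run can be reproduced from its
#' outputs. No timestamps: identical runs must produce byte-identical
#' files.
#'
#' @param df data frame.
#' @param path output path.
#' @param provenance named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, provenance = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# synaptomap %s",
                     as.character(utils::packageVersion("synaptomap"))), con)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(format(provenance[[k]]), collapse = " ")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Load and validate a pipeline run configuration
#'
#' YAML with fields: `workflow` (`"mapping"` or `"nano"`), `seed`,
#' `n_control`, `n_case`, `tripartite_removal`, optional `scene` overrides
#' (any [scene_params()] argument), optional `optics` overrides, optional
#' `atlas` (`layout`). Validation is strict so that misconfigured runs fail
#' before any computation.
#'
#' @param path YAML file path.
#' @return An object of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg a named list with the same fields as the YAML file.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$workflow) ||
      !cfg$workflow %in% c("mapping", "nano")) {
    stop("config must set workflow: mapping or nano")
  }
  defaults <- list(seed = 1L, n_control = 5L, n_case = 5L,
                   tripartite_removal = 0.4, scene = list(),
                   optics = list(), atlas = list(layout = "bands"),
                   nc_shift = 0.3)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!is.numeric(cfg$seed)) stop("config seed must be numeric")
  bad <- setdiff(names(cfg$scene), names(formals(scene_params)))
  if (length(bad)) stop("unknown scene parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(x[order(names(x))], tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

scene_params_from <- function(overrides, seed) {
  overrides$seed <- seed
  do.call(scene_params, overrides)
}

#' Detect all three channels of a rendered scene and classify synapses
#'
#' Convenience wrapper for the mapping workflow on one subject: renders
#' psd95/vglut2/pap under the given optics, detects puncta per channel,
#' classifies synapses in triple mode and labels them with atlas regions.
#' Multi-marker tripartite data sets are the ones that typically required
#' manual thresholding, so all three channels default to manual thresholds,
#' set per channel around the ~130-unit peak a default-brightness punctum
#' reaches after PSF blur and the default 1 px smoothing. The presynaptic
#' channel uses the half-peak threshold (65): its puncta sit 200 nm from
#' the PSD centre, so generous masks are needed for genuinely apposed
#' structures to satisfy the 1-pixel overlap criterion. The PSD and PAP
#' channels use a tighter cut (100): the PAP punctum sits only 100 nm from
#' its PSD, so true contacts still overlap comfortably, while compact PSD
#' and PAP masks keep two artifacts of object-overlap colocalisation rare —
#' fusion of adjacent PSD masks, and chance PSD-PAP overlaps that would
#' relabel non-tripartite synapses as tripartite at a rate proportional to
#' PAP density (and therefore differentially between groups with different
#' astrocytic coverage, biasing class-resolved densities). Automatic
#' Moments thresholding (the `mapping` profile) remains the choice for
#' single-channel PSD95 maps.
#'
#' @param scene a [sample_scene()] result.
#' @param optics an [optics_model()] (confocal mapping optics by default).
#' @param psd_params,presyn_params,pap_params per-channel detection
#'   parameter overrides.
#' @return The region-labelled `synapse_records`.
#' @export
analyze_scene <- function(scene, optics = optics_model("confocal"),
                          psd_params = detection_params(
                            threshold_mode = "manual",
                            manual_threshold = 100),
                          presyn_params = detection_params(
                            threshold_mode = "manual",
                            manual_threshold = 65),
                          pap_params = detection_params(
                            threshold_mode = "manual",
                            manual_threshold = 100)) {
  img_psd <- render(scene, "psd95", optics)
  img_pre <- render(scene, "vglut2", optics)
  img_pap <- render(scene, "pap", optics)
  psd <- detect_puncta(img_psd, psd_params)
  pre <- detect_puncta(img_pre, presyn_params)
  pap <- detect_puncta(img_pap, pap_params)
  recs <- classify_synapses(psd, pre, pap, mode = "triple")
  assign_region(recs, scene$atlas)
}

#' Simulate a case/control mapping cohort
#'
#' Control subjects are independent scenes from the configured generator;
#' case subjects additionally lose `tripartite_removal` of their
#' ground-truth tripartite entities (non-tripartite synapses untouched) —
#' the planted selective-vulnerability effect. Each subject is pushed
#' through render -> detect -> classify -> regional stats.
#'
#' @param config a `run_config` (or list coercible via [as_run_config()]).
#' @return List with `stats` (rbind-ed `region_stats` of all subjects,
#'   genotype `control` / `case`) and `scenes` metadata.
#' @export
simulate_mapping_cohort <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  sp0 <- scene_params_from(config$scene, config$seed)
  atlas <- build_region_atlas(sp0$field_size_px, sp0$pixel_size_nm,
                              layout = config$atlas$layout)
  optics <- do.call(optics_model, c(list(modality = "confocal"),
                                    config$optics))
  all_stats <- list()
  subj <- 0L
  for (grp in c("control", "case")) {
    n <- if (grp == "control") config$n_control else config$n_case
    for (i in seq_len(n)) {
      subj <- subj + 1L
      sp <- scene_params_from(config$scene, config$seed + 1000L * subj)
      scene <- sample_scene(sp, atlas)
      if (grp == "case" && config$tripartite_removal > 0) {
        scene <- thin_tripartite(scene, config$tripartite_removal)
      }
      recs <- analyze_scene(scene, optics)
      all_stats[[subj]] <- compute_region_stats(
        recs, atlas, subject = sprintf("%s_%02d", grp, i), genotype = grp)
    }
  }
  list(stats = do.call(rbind, all_stats), atlas = atlas,
       config = config)
}

#' Run a configured pipeline end to end and write its outputs
#'
#' `workflow: mapping` simulates the configured case/control cohort, then
#' writes the long-format per-subject region statistics, the
#' percent-of-control heat-map tables (density, tripartite and
#' non-tripartite density) and the two-way ANOVA reports.
#' `workflow: nano` simulates paired confocal/STED fields for the two
#' groups (cases have `nc_shift` of their 3+NC mass moved to 1-2 NC
#' counts), writes per-group subtype distributions and the chi-squared
#' comparison. Outputs carry the config hash and seed; identical
#' config + seed gives byte-identical tables.
#'
#' @param config a `run_config`, list, or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               workflow = config$workflow)
  if (config$workflow == "mapping") {
    res <- simulate_mapping_cohort(config)
    st <- res$stats
    write_table_csv(st, file.path(out_dir, "region_stats.csv"), prov)
    ctl <- st[st$genotype == "control", ]
    cas <- st[st$genotype == "case", ]
    for (m in c("density", "tripartite_density",
                "non_tripartite_density")) {
      hm <- percent_difference(cas, ctl, m)
      write_table_csv(hm, file.path(out_dir, paste0("heatmap_", m, ".csv")),
                      prov)
    }
    for (cl in c("tripartite", "non_tripartite")) {
      sub <- st[st$class == cl, ]
      an <- two_way_anova(sub, "density_per_100um2")
      write_table_csv(an, file.path(out_dir, paste0("anova_", cl, ".csv")),
                      prov)
    }
  } else {
    res <- simulate_nano_groups(config)
    write_table_csv(res$summary, file.path(out_dir, "subtypes.csv"), prov)
    chi <- chi_squared(res$contingency)
    write_table_csv(
      data.frame(test = chi$test_name, statistic = chi$statistic,
                 df = chi$df, p = chi$p_value),
      file.path(out_dir, "chi_squared.csv"), prov)
  }
  invisible(out_dir)
}

#' Simulate paired confocal/STED groups for the nanostructure workflow
#'
#' Each subject is one STED-scale field (20 nm/px); cases draw nanocluster
#' counts from a distribution with `nc_shift` of the 3+NC mass moved into
#' the 1- and 2-NC classes, the planted contrast behind the
#' multi-nanocluster-loss comparison.
#'
#' @param config a `run_config`.
#' @return List: `summary` (per group subtype frequencies and mean NC/PSD),
#'   `contingency` (group x subtype counts), `per_subject`.
#' @export
simulate_nano_groups <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  for (k in names(nano_scene_defaults())) {
    if (is.null(config$scene[[k]])) {
      config$scene[[k]] <- nano_scene_defaults()[[k]]
    }
  }
  base_dist <- c(0.45, 0.32, 0.15, 0.08)
  hi <- base_dist[3:4]
  shift <- config$nc_shift * sum(hi)
  case_dist <- c(base_dist[1] + 0.6 * shift, base_dist[2] + 0.4 * shift,
                 base_dist[3:4] * (1 - config$nc_shift))
  counts <- matrix(0, 2, 3,
                   dimnames = list(c("control", "case"),
                                   c("1", "2", "3+")))
  per_subject <- list()
  mean_nc <- c(control = 0, case = 0)
  for (gi in 1:2) {
    grp <- c("control", "case")[gi]
    dist <- if (grp == "control") base_dist else case_dist
    n <- if (grp == "control") config$n_control else config$n_case
    means <- numeric(n)
    for (i in seq_len(n)) {
      sc <- config$scene
      sc$nc_count_distribution <- dist
      sp <- scene_params_from(sc, config$seed + 1000L * (10L * gi + i))
      atlas <- build_region_atlas(sp$field_size_px, sp$pixel_size_nm,
                                  layout = "bands")
      scene <- sample_scene(sp, atlas)
      pair <- detect_nano_pair(scene)
      sd_ <- subtype_distribution(pair$assignment)
      counts[grp, ] <- counts[grp, ] + sd_$counts
      means[i] <- sd_$mean_nc_per_psd
      per_subject[[length(per_subject) + 1L]] <-
        data.frame(group = grp, subject = i,
                   mean_nc_per_psd = sd_$mean_nc_per_psd,
                   f1 = sd_$frequencies[1], f2 = sd_$frequencies[2],
                   f3p = sd_$frequencies[3])
    }
    mean_nc[grp] <- mean(means)
  }
  freq <- counts / rowSums(counts)
  summary <- data.frame(group = rownames(counts),
                        f1 = freq[, 1], f2 = freq[, 2], f3p = freq[, 3],
                        mean_nc_per_psd = as.numeric(mean_nc))
  rownames(summary) <- NULL
  list(summary = summary, contingency = counts,
       per_subject = do.call(rbind, per_subject))
}

#' Scene parameter defaults for STED-scale nanostructure fields
#'
#' A 640 x 640 px field at 20 nm/px (12.8 x 12.8 um), modest PSD density
#' (12 per 100 um^2) with a 1 um hard minimum PSD spacing so that
#' confocal-resolved PSD masks stay disjoint, and a 220 nm nanocluster
#' spacing — comfortably above twice the STED FWHM, so that thresholding
#' the STED plane separates the nanoclusters of one PSD. Used by
#' [simulate_nano_groups()] for any scene parameter the run config leaves
#' unset.
#'
#' @return Named list of [scene_params()] overrides.
#' @export
nano_scene_defaults <- function() {
  list(field_size_px = c(640L, 640L), pixel_size_nm = 20,
       psd_density = 12, psd_min_spacing_nm = 1000,
       edge_margin_nm = 500, nc_spacing_nm = 220)
}

#' Detect a paired confocal/STED rendering of one scene
#'
#' Renders the PSD95 channel under confocal and STED optics, detects whole
#' PSDs on the confocal plane and nanoclusters on the STED plane, and
#' assigns NCs to PSDs.
#'
#' @param scene a [sample_scene()] result (STED-scale pixels recommended).
#' @param confocal_optics,sted_optics optics models.
#' @param confocal_params,sted_params detection parameters.
#' @return List: `psd`, `nc` (puncta sets), `assignment`.
#' @export
detect_nano_pair <- function(scene,
                             confocal_optics = optics_model("confocal"),
                             sted_optics = optics_model("sted"),
                             confocal_params =
                               detection_profile("confocal_nano"),
                             sted_params = detection_profile("sted")) {
  img_conf <- render(scene, "psd95", confocal_optics)
  img_sted <- render(scene, "psd95", sted_optics)
  psd <- detect_puncta(img_conf, confocal_params)
  nc <- detect_puncta(img_sted, sted_params)
  list(psd = psd, nc = nc, assignment = assign_nanoclusters(psd, nc))
}
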