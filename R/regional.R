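#' Label puncta or synapse records with their atlas region
#'
#' Each object is assigned the region of the atlas pixel containing its
#' centroid (pixel ownership decides boundary cases); objects whose centroid
#' falls on an unlabelled pixel get region `"outside"` and are excluded from
#' downstream statistics.
#'
#' @param x a `puncta_set` or `synapse_records`.
#' @param atlas a `region_atlas` sharing the image shape.
#' @return `x` with a `region` column added to its table.
#' @export
assign_region <- function(x, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  tab <- if (inherits(x, "puncta_set")) x$puncta
         else if (inherits(x, "synapse_records")) x$records
         else stop("x must be a puncta_set or synapse_records")
  if (!all(x$dim == dim(atlas$labels))) {
    stop("atlas and puncta derive from different image shapes")
  }
  if (nrow(tab) == 0) {
    tab$region <- character(0)
  } else {
    r <- pmin(pmax(round(tab$centroid_row), 1), nrow(atlas$labels))
    c_ <- pmin(pmax(round(tab$centroid_col), 1), ncol(atlas$labels))
    lab <- atlas$labels[cbind(r, c_)]
    tab$region <- ifelse(lab > 0, atlas$region_names[pmax(lab, 1)],
                         "outside")
  }
  if (inherits(x, "puncta_set")) x$puncta <- tab else x$records <- tab
  x
}

#' Per-region density and size statistics
#'
#' Aggregates region-labelled puncta or synapse records into per-region
#' counts, densities (per 100 um^2) and mean areas. Synapse records are
#' additionally broken out by class (`all`, `tripartite`,
#' `non_tripartite`); plain puncta get class `all`. Empty regions report
#' count 0, density 0 and a missing mean area. Subject metadata is attached
#' to every row.
#'
#' @param x a region-labelled `puncta_set` or `synapse_records`
#'   (see [assign_region()]).
#' @param atlas the `region_atlas` used for labelling.
#' @param subject,genotype,sex,age_group optional metadata.
#' @return A long-format data frame of class `region_stats`: one row per
#'   region x class with `n`, `density_per_100um2`, `mean_area_um2`.
#' @export
compute_region_stats <- function(x, atlas, subject = NA, genotype = NA,
                                 sex = NA, age_group = NA) {
  stopifnot(inherits(atlas, "region_atlas"))
  tab <- if (inherits(x, "puncta_set")) x$puncta
         else if (inherits(x, "synapse_records")) x$records
         else stop("x must be a puncta_set or synapse_records")
  if (!"region" %in% names(tab)) {
    stop("run assign_region() first: no region labels present")
  }
  tab <- tab[tab$region != "outside", , drop = FALSE]
  classes <- if (inherits(x, "synapse_records")) {
    c("all", "tripartite", "non_tripartite")
  } else "all"
  rows <- list()
  for (cl in classes) {
    sub <- if (cl == "all") tab else tab[tab$synapse_class == cl, ,
                                         drop = FALSE]
    for (ri in seq_along(atlas$region_names)) {
      reg <- atlas$region_names[ri]
      s <- sub[sub$region == reg, , drop = FALSE]
      area <- atlas$region_area_um2[ri]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, genotype = genotype, sex = sex,
        age_group = age_group, region = reg, class = cl, n = nrow(s),
        density_per_100um2 = nrow(s) / area * 100,
        mean_area_um2 = if (nrow(s) > 0) mean(s$area_um2) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Percent-of-control heat-map table
#'
#' For each region, `(mean over case subjects - mean over control subjects)
#' / control mean x 100` of the chosen measure — the statistic behind the
#' case-versus-control heat maps. Subject means are the analysis unit.
#' Regions whose control mean is zero report an undefined (NA) value.
#'
#' @param case,control `region_stats` tables (rows from several subjects
#'   may simply be rbind-ed together).
#' @param measure `"density"`, `"mean_area"`, `"tripartite_density"` or
#'   `"non_tripartite_density"`.
#' @return A data frame of class `heatmap_table`: `region`, `control_mean`,
#'   `case_mean`, `percent_difference`.
#' @export
percent_difference <- function(case, control,
                               measure = c("density", "mean_area",
                                           "tripartite_density",
                                           "non_tripartite_density")) {
  measure <- match.arg(measure)
  sel <- switch(measure,
    density = list(class = "all", col = "density_per_100um2"),
    mean_area = list(class = "all", col = "mean_area_um2"),
    tripartite_density = list(class = "tripartite",
                              col = "density_per_100um2"),
    non_tripartite_density = list(class = "non_tripartite",
                                  col = "density_per_100um2"))
  subject_means <- function(df) {
    df <- df[df$class == sel$class, , drop = FALSE]
    if (nrow(df) == 0) stop("no rows for class '", sel$class, "'")
    stats::aggregate(df[[sel$col]],
                     by = list(region = df$region), FUN = mean,
                     na.rm = TRUE)
  }
  ca <- subject_means(case); co <- subject_means(control)
  regions <- union(co$region, ca$region)
  cm <- co$x[match(regions, co$region)]
  xm <- ca$x[match(regions, ca$region)]
  pd <- ifelse(!is.na(cm) & cm != 0, (xm - cm) / cm * 100, NA_real_)
  out <- data.frame(region = regions, control_mean = cm, case_mean = xm,
                    percent_difference = pd, measure = measure,
                    stringsAsFactors = FALSE)
  class(out) <- c("heatmap_table", "data.frame")
  out
}

#' Correlate astrocytic contact fraction with regional tripartite loss
#'
#' Per region, x is the control percentage of synapses classified
#' tripartite (the fraction of synapses contacted by the PAP marker,
#' averaged over control subjects) and y is the signed percent difference
#' in tripartite synapse density between case and control. Returns the
#' Pearson correlation over regions with a two-sided p-value.
#'
#' @param case,control `region_stats` tables carrying synapse classes.
#' @return A list of class `contact_loss_cor`: `r`, `p`, `n_regions`,
#'   per-region `table`, and the underlying `stat_result`.
#' @export
contact_loss_correlation <- function(case, control) {
  frac_tab <- function(df) {
    syn <- df[df$class == "all", c("subject", "region", "n")]
    tri <- df[df$class == "tripartite", c("subject", "region", "n")]
    m <- merge(syn, tri, by = c("subject", "region"),
               suffixes = c("_syn", "_tri"))
    m <- m[m$n_syn > 0, , drop = FALSE]
    m$frac <- m$n_tri / m$n_syn * 100
    stats::aggregate(m$frac, by = list(region = m$region), FUN = mean)
  }
  contact <- frac_tab(control)
  loss <- percent_difference(case, control, "tripartite_density")
  tab <- merge(contact, loss[, c("region", "percent_difference")],
               by = "region")
  names(tab)[names(tab) == "x"] <- "control_contact_pct"
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3) {
    stop("contact/loss correlation needs >= 3 regions with defined values")
  }
  res <- pearson_correlation(tab$control_contact_pct,
                             tab$percent_difference)
  structure(list(r = res$statistic_aux, p = res$p_value,
                 n_regions = nrow(tab), table = tab, stat = res),
            class = "contact_loss_cor")
}

#' @export
print.contact_loss_cor <- function(x, ...) {
  cat(sprintf(
    "<contact_loss_cor> r = %.3f, p = %.4g over %d regions\n",
    x$r, x$p, x$n_regions))
  invisible(x)
}
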