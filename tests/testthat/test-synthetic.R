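make_atlas_100um2 <- function() build_region_atlas(c(100L, 100L), 100, "bands")

test_that("scene parameter validation enforces the documented invariants", {
  expect_error(scene_params(tripartite_fraction = 1.2), "probabilities")
  expect_error(scene_params(nc_count_distribution = c(0.5, 0.4)), "sum to 1")
  expect_error(scene_params(psd_density = -1), "non-negative")
  expect_error(scene_params(nc_diameter_nm = 0), "positive")
})

test_that("zero density gives an empty scene; sampling is deterministic", {
  atlas <- make_atlas_100um2()
  sp0 <- scene_params(field_size_px = c(100L, 100L), psd_density = 0)
  expect_equal(nrow(sample_scene(sp0, atlas)$entities), 0)

  sp <- scene_params(field_size_px = c(100L, 100L), seed = 11L)
  s1 <- sample_scene(sp, atlas); s2 <- sample_scene(sp, atlas)
  expect_identical(s1$entities, s2$entities)
  expect_identical(s1$nc, s2$nc)
})

test_that("entity counts follow the density x area Poisson expectation", {
  # whole-field density 50 per 100 um^2 on a 100 um^2 field: expected
  # total count 50; mean over 400 seeds within 3 Poisson standard errors
  atlas <- make_atlas_100um2()
  n_seeds <- 400
  counts <- vapply(seq_len(n_seeds), function(s) {
    sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 50,
                       edge_margin_nm = 0, seed = s)
    nrow(sample_scene(sp, atlas)$entities)
  }, numeric(1))
  se <- sqrt(50 / n_seeds)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("ground-truth tripartite proportion matches tripartite_fraction", {
  atlas <- make_atlas_100um2()
  tot <- 0; tri <- 0
  for (s in 1:60) {
    sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 180,
                       tripartite_fraction = 0.25, edge_margin_nm = 0,
                       seed = 100 + s)
    sc <- sample_scene(sp, atlas)
    tot <- tot + nrow(sc$entities); tri <- tri + sum(sc$entities$has_pap)
  }
  expect_gt(tot, 10000)
  se <- sqrt(0.25 * 0.75 / tot)
  expect_lt(abs(tri / tot - 0.25), 3 * se)
})

test_that("nanocluster layout respects counts, spacing and field bounds", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 100,
                     nc_count_distribution = c(0.1, 0.2, 0.3, 0.4),
                     seed = 5L)
  sc <- sample_scene(sp, atlas)
  expect_equal(
    as.integer(table(sc$nc$entity_id)[as.character(sc$entities$id)]),
    as.integer(sc$entities$nc_count))
  # pairwise NC spacing within each PSD
  for (id in sc$entities$id[sc$entities$nc_count > 1]) {
    xy <- as.matrix(sc$nc[sc$nc$entity_id == id, c("x_nm", "y_nm")])
    expect_gte(min(stats::dist(xy)), sp$nc_spacing_nm - 1e-9)
  }
  fs_nm <- sp$field_size_px * sp$pixel_size_nm
  expect_true(all(sc$entities$x_nm > 0 & sc$entities$x_nm < fs_nm[2]))
  expect_true(all(sc$entities$y_nm > 0 & sc$entities$y_nm < fs_nm[1]))
})

test_that("impossible minimum-spacing placement errors and names the region", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 500,
                     psd_min_spacing_nm = 2000, seed = 2L)
  expect_error(sample_scene(sp, atlas), "region 'I-II'")
})

test_that("rendering is deterministic and reproduces the background model", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 0,
                     seed = 3L)
  empty <- sample_scene(sp, atlas)
  opt <- optics_model("confocal", background_level = 10, poisson_scale = 1,
                      read_noise_sd = 2)
  img <- render(empty, "psd95", opt)
  expect_equal(mean(img$pixels), 10, tolerance = 0.02)
  # Poisson(10) var + read var: 10 + 4
  expect_equal(stats::var(as.vector(img$pixels)), 14, tolerance = 0.1)
  img2 <- render(empty, "psd95", opt)
  expect_identical(img$pixels, img2$pixels)
  expect_error(render(empty, "nonsense", opt))
})

test_that("a rendered single-nanocluster spot has the PSF's width", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), seed = 1L,
                     nc_diameter_nm = 100)  # below the confocal PSF
  sc <- manual_scene(sp, atlas, x = 5000, y = 5000)
  img <- render(sc, "psd95", noise_free("confocal"))
  # fit a Gaussian to the central row profile
  prof <- img$pixels[50, ]
  fit <- stats::nls(y ~ a * exp(-(x - m)^2 / (2 * s^2)),
                    data = data.frame(x = seq_along(prof) * 100, y = prof),
                    start = list(a = max(prof), m = 5000, s = 150))
  fwhm <- 2 * sqrt(2 * log(2)) * coef(fit)[["s"]]
  expect_lt(abs(fwhm - 320) / 320, 0.1)
})

test_that("tripartite entities emit in all channels, others not in PAP", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), seed = 8L)
  sc <- manual_scene(sp, atlas, x = c(2500, 7500), y = c(5000, 5000),
                     has_pap = c(TRUE, FALSE))
  at_px <- function(img, x, y) img$pixels[round(y / 100 + .5),
                                          round(x / 100 + .5)]
  for (ch in c("psd95", "vglut2", "pap")) {
    img <- render(sc, ch, noise_free())
    cx <- switch(ch, psd95 = sc$entities$x_nm,
                 vglut2 = sc$entities$presyn_x_nm,
                 pap = sc$entities$pap_x_nm)
    cy <- switch(ch, psd95 = sc$entities$y_nm,
                 vglut2 = sc$entities$presyn_y_nm,
                 pap = sc$entities$pap_y_nm)
    v1 <- at_px(img, cx[1], cy[1]); v2 <- at_px(img, cx[2], cy[2])
    if (ch == "pap") {
      expect_gt(v1, 100); expect_lt(v2, 1)
    } else {
      expect_gt(v1, 100); expect_gt(v2, 100)
    }
  }
})

test_that("STED optics resolve what confocal optics merge", {
  # small (point-like) emitters isolate the optics: pairs at d = 2 x STED
  # FWHM resolve under STED and pairs at d = 0.5 x confocal FWHM merge
  # under confocal, in >= 95% of entities (noise off)
  px <- 20
  atlas <- build_region_atlas(c(250L, 250L), px, "bands")
  sp <- scene_params(field_size_px = c(250L, 250L), pixel_size_nm = px,
                     nc_diameter_nm = 40, seed = 4L)
  place <- function(d_nm) {
    xs <- rep(seq(750, 4250, by = 700), 5)
    ys <- rep(seq(750, 3550, by = 700), each = 6)
    manual_scene(sp, atlas, x = xs, y = ys,
                 nc_offsets = replicate(length(xs),
                   rbind(c(-d_nm / 2, 0), c(d_nm / 2, 0)), simplify = FALSE))
  }
  count_objects <- function(scene, optics, thr = 100) {
    img <- render(scene, "psd95", optics)
    pr <- gaussian_smooth(img, 0.5)
    ps <- segment_puncta(pr, thr, detection_params(min_area_um2 = 1e-4,
                                                   max_area_um2 = Inf))
    m <- match_detections(ps, scene, tol_px = 300 / px)
    # per-entity resolved count: match each detection to nearest entity
    det <- ps$puncta
    ent <- scene$entities
    near <- apply(cbind(det$centroid_row, det$centroid_col), 1, function(rc) {
      which.min((ent$y_nm / px + .5 - rc[1])^2 +
                (ent$x_nm / px + .5 - rc[2])^2)
    })
    tabulate(near, nbins = nrow(ent))
  }
  sted_counts <- count_objects(place(2 * 70), noise_free("sted"))
  expect_gte(mean(sted_counts == 2), 0.95)
  conf_counts <- count_objects(place(0.5 * 320), noise_free("confocal"))
  expect_gte(mean(conf_counts == 1), 0.95)
})

test_that("aggregate injection is a no-op at zero count and bookkeeps discs", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 10,
                     seed = 6L)
  sc <- sample_scene(sp, atlas)
  img <- render(sc, "psd95", noise_free())
  expect_identical(inject_aggregates(img, sc)$pixels, img$pixels)

  sp3 <- scene_params(field_size_px = c(100L, 100L), psd_density = 10,
                      aggregate_count = 3,
                      aggregate_diameter_um = c(5, 5), seed = 6L)
  sc3 <- sample_scene(sp3, atlas)
  expect_equal(nrow(sc3$aggregates), 3)
  expect_equal(sc3$aggregates$diameter_um, rep(5, 3))
  img3 <- inject_aggregates(render(sc3, "psd95", noise_free()), sc3)
  expect_equal(max(img3$pixels), 2^16 - 1)
})

test_that("thin_tripartite removes only tripartite entities", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 150,
                     tripartite_fraction = 0.5, seed = 9L)
  sc <- sample_scene(sp, atlas)
  n_tri <- sum(sc$entities$has_pap)
  n_non <- sum(!sc$entities$has_pap)
  th <- thin_tripartite(sc, 0.4)
  expect_equal(sum(!th$entities$has_pap), n_non)
  expect_equal(sum(th$entities$has_pap), n_tri - round(0.4 * n_tri))
  expect_true(all(th$nc$entity_id %in% th$entities$id))
})

test_that("scene export writes ground truth, atlas and params", {
  atlas <- make_atlas_100um2()
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 20,
                     seed = 10L)
  sc <- sample_scene(sp, atlas)
  tmp <- withr::local_tempdir()
  write_scene(sc, tmp)
  gt <- utils::read.csv(file.path(tmp, "ground_truth.csv"))
  expect_equal(nrow(gt), nrow(sc$entities))
  pars <- yaml::read_yaml(file.path(tmp, "scene_params.yaml"))
  expect_equal(pars$seed, 10L)
})
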