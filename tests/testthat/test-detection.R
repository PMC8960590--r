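test_that("background subtraction removes flat fields and keeps spikes", {
  flat <- img_of(matrix(37, 32, 32))
  expect_true(all(subtract_background(flat, 5)$pixels == 0))

  spiked <- matrix(20, 64, 64); spiked[30, 30] <- 150
  out <- subtract_background(img_of(spiked), 10)
  expect_equal(out$pixels[30, 30], 130)
  expect_lt(max(out$pixels[-((29:31)), ]), 1e-9)
  expect_true(all(out$pixels >= 0))
  expect_error(subtract_background(flat, -1), "positive")
})

test_that("background subtraction matches a morphological-opening oracle", {
  withr::local_seed(21)
  n <- 32; rad <- 3
  m <- matrix(stats::runif(n * n, 0, 50), n)
  brush <- EBImage::makeBrush(2 * rad + 1, "disc")
  off <- which(brush > 0, arr.ind = TRUE) - (rad + 1)
  # brute-force grayscale opening: erosion then dilation by the disc,
  # skipping out-of-image offsets
  morph <- function(x, f) {
    out <- matrix(NA_real_, n, n)
    for (r in 1:n) for (c_ in 1:n) {
      rr <- r + off[, 1]; cc <- c_ + off[, 2]
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      out[r, c_] <- f(x[cbind(rr[ok], cc[ok])])
    }
    out
  }
  op <- morph(morph(m, min), max)
  got <- subtract_background(img_of(m), rad)$pixels
  want <- pmax(m - op, 0)
  inner <- (rad + 1):(n - rad)  # border conventions may differ
  expect_equal(got[inner, inner], want[inner, inner], tolerance = 1e-9)
})

test_that("gaussian smoothing conserves mass and never raises the maximum", {
  const <- img_of(matrix(12, 32, 32))
  expect_equal(gaussian_smooth(const, 2)$pixels, matrix(12, 32, 32),
               tolerance = 1e-9)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sm <- gaussian_smooth(img_of(imp), 2)$pixels
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # matches the directly evaluated normalised kernel
  d2 <- (row(imp) - 17)^2 + (col(imp) - 17)^2
  ker <- exp(-d2 / (2 * 2^2)); ker <- ker / sum(ker)
  expect_lt(max(abs(sm - ker)), 1e-3)
  withr::local_seed(3)
  noisy <- matrix(stats::runif(1024, 0, 100), 32)
  expect_lte(max(gaussian_smooth(img_of(noisy), 1.5)$pixels), max(noisy))
  expect_error(gaussian_smooth(const, 0), "positive")
})

test_that("segmentation arithmetic: a 5-pixel blob is one 0.05 um^2 punctum", {
  m <- matrix(0, 16, 16)
  m[8, 7:9] <- 100; m[7, 8] <- 100; m[9, 8] <- 100  # 5-px plus sign
  ps <- segment_puncta(img_of(m, px = 100), 50,
                       detection_params(min_area_um2 = 0.02,
                                        max_area_um2 = 2))
  expect_equal(nrow(ps$puncta), 1)
  expect_equal(ps$puncta$area_um2, 0.05)
  expect_equal(ps$puncta$centroid_row, 8)
  expect_equal(ps$puncta$centroid_col, 8)
  expect_equal(ps$puncta$mean_intensity, 100)

  expect_equal(nrow(segment_puncta(img_of(matrix(0, 16, 16)), 10,
                                   detection_params())$puncta), 0)
})

test_that("labelling matches a brute-force 8-connected flood fill", {
  withr::local_seed(13)
  for (i in 1:25) {
    mask <- matrix(stats::runif(32 * 32) < 0.25, 32)
    img <- img_of(matrix(as.numeric(mask) * 100, 32))
    ps <- segment_puncta(img, 50, detection_params(min_area_um2 = 0,
                                                   max_area_um2 = Inf))
    oracle <- flood_label(mask)
    # same partition: component pixel sets agree up to label permutation
    expect_equal(max(ps$label_image), max(oracle))
    key_pkg <- split(which(ps$label_image > 0),
                     ps$label_image[ps$label_image > 0])
    key_or <- split(which(oracle > 0), oracle[oracle > 0])
    norm <- function(k) unname(k[order(vapply(k, min, numeric(1)))])
    expect_identical(norm(key_pkg), norm(key_or))
  }
})

test_that("size filters and manual thresholds behave monotonically", {
  withr::local_seed(31)
  m <- matrix(0, 64, 64)
  for (i in 1:12) {
    r <- sample(5:60, 1); c_ <- sample(5:60, 1); rad <- sample(1:3, 1)
    m[pmax(1, r - rad):pmin(64, r + rad),
      pmax(1, c_ - rad):pmin(64, c_ + rad)] <- stats::runif(1, 80, 200)
  }
  img <- img_of(m)
  n_at <- function(minA, maxA) nrow(segment_puncta(
    img, 50, detection_params(min_area_um2 = minA,
                              max_area_um2 = maxA))$puncta)
  mins <- c(0, 0.02, 0.05, 0.1, 0.3)
  expect_true(all(diff(sapply(mins, n_at, maxA = Inf)) <= 0))
  maxs <- c(Inf, 1, 0.5, 0.2, 0.05)
  expect_true(all(diff(sapply(maxs, function(mx) n_at(0, mx))) <= 0))

  fg_area <- function(thr) sum(segment_puncta(
    img, thr, detection_params(min_area_um2 = 0,
                               max_area_um2 = Inf))$puncta$area_px)
  expect_true(all(diff(sapply(c(10, 50, 90, 150), fg_area)) <= 0))

  # disjointness: union of masks equals summed punctum areas
  ps <- segment_puncta(img, 50, detection_params(min_area_um2 = 0,
                                                 max_area_um2 = Inf))
  expect_equal(sum(ps$label_image > 0), sum(ps$puncta$area_px))
})

test_that("detect_puncta is deterministic and manual mode can empty a field", {
  atlas <- build_region_atlas(c(100L, 100L), 100, "bands")
  sp <- scene_params(field_size_px = c(100L, 100L), psd_density = 30,
                     seed = 12L)
  img <- render(sample_scene(sp, atlas), "psd95", snr_optics(10))
  p1 <- detect_puncta(img, detection_profile("immuno"))
  p2 <- detect_puncta(img, detection_profile("immuno"))
  expect_identical(p1$puncta, p2$puncta)
  expect_equal(p1$threshold_used, 60)

  hi <- detect_puncta(img, detection_params(threshold_mode = "manual",
                                            manual_threshold = 70000,
                                            max_area_um2 = Inf))
  expect_equal(nrow(hi$puncta), 0)
})

test_that("noise-free scenes are recovered perfectly; SNR 10 nearly so", {
  atlas <- build_region_atlas(c(256L, 256L), 100, "bands")
  sp <- scene_params(field_size_px = c(256L, 256L), psd_density = 25,
                     nc_count_distribution = c(1, 0, 0, 0),
                     psd_min_spacing_nm = 1200, seed = 77L)
  scene <- sample_scene(sp, atlas)
  expect_gt(nrow(scene$entities), 50)

  clean <- detect_puncta(render(scene, "psd95", noise_free()),
                         detection_profile("immuno"))
  m <- match_detections(clean, scene, tol_px = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  noisy <- detect_puncta(render(scene, "psd95", snr_optics(10)),
                         detection_profile("immuno"))
  mn <- match_detections(noisy, scene, tol_px = 1)
  expect_gte(mn$recall, 0.9)
  expect_gte(mn$precision, 0.9)
})

test_that("detected punctum size recovers the rendered structure width", {
  # noise-free mapping rendering: eq diameter at the half-peak threshold
  # should sit within one pixel of the confocal FWHM
  atlas <- build_region_atlas(c(256L, 256L), 100, "bands")
  sp <- scene_params(field_size_px = c(256L, 256L), psd_density = 15,
                     nc_count_distribution = c(1, 0, 0, 0),
                     punctum_peak_sd = 0, psd_min_spacing_nm = 1500,
                     seed = 21L)
  scene <- sample_scene(sp, atlas)
  img <- render(scene, "psd95", noise_free())
  # half of the smoothed peak: sigma_total^2 = psf sigma^2 + smooth sigma^2
  sm <- gaussian_smooth(img, 1)
  peak <- max(sm$pixels)
  ps <- segment_puncta(sm, peak / 2, detection_params(min_area_um2 = 0.01,
                                                      max_area_um2 = 2))
  sig_tot <- sqrt((320 / 2.355)^2 + 100^2)
  expect_equal(nrow(ps$puncta), nrow(scene$entities))
  expect_lt(abs(mean(ps$puncta$eq_diameter_nm) - 2.355 * sig_tot), 100)
})
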