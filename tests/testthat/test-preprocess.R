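# Calibration, ExGR, Otsu thresholding and canopy segmentation.

dn_image <- function(fill, panel_fill, nr = 20, nc = 20, side = 4) {
  pr <- list(row0 = 1L, row1 = side, col0 = 1L, col1 = side)
  bands <- lapply(1:5, function(i) {
    m <- matrix(fill, nr, nc)
    m[pr$row0:pr$row1, pr$col0:pr$col1] <- panel_fill
    m
  })
  names(bands) <- c("B", "G", "R", "RE", "NIR")
  list(img = multispectral_image(bands, domain = "DN", panel_region = pr),
       panel = panel_reference(pr, rep(0.5, 5)))
}

test_that("calibration satisfies the panel identity and is linear in DN", {
  # DN equal to the panel mean everywhere -> reflectance = Rs everywhere
  x <- dn_image(fill = 100, panel_fill = 100)
  cal <- calibrate_reflectance(x$img, x$panel)
  expect_equal(cal$domain, "reflectance")
  for (b in names(cal$bands)) expect_true(all(cal$bands[[b]] == 0.5))

  # DN = 2 x panel mean, Rs = 0.5 -> reflectance 1.0
  x2 <- dn_image(fill = 200, panel_fill = 100)
  cal2 <- calibrate_reflectance(x2$img, x2$panel)
  expect_true(all(cal2$bands$NIR[5:20, 5:20] == 1.0))

  # linearity: scaling the scene DN (panel fixed) scales the reflectance
  x3 <- dn_image(fill = 70, panel_fill = 100)
  x3b <- dn_image(fill = 3 * 70, panel_fill = 100)
  c3 <- calibrate_reflectance(x3$img, x3$panel)
  c3b <- calibrate_reflectance(x3b$img, x3$panel)
  expect_equal(c3b$bands$G[10, 10], 3 * c3$bands$G[10, 10], tolerance = 1e-12)
})

test_that("synthetic panel pixels calibrate to their known reflectance", {
  spec <- tiny_spec(pixel_noise_sd = 0, within_class_sd = 0)
  g <- generate_image(spec, 1, seed = 9)
  cal <- calibrate_generated(g, spec)
  idx <- teaspec:::panel_index(cal$panel_region, dim(cal))
  for (b in names(cal$bands))
    expect_lt(abs(mean(cal$bands[[b]][idx]) - spec$panel_reflectance[[b]]), 1e-6)
})

test_that("degenerate calibration inputs are rejected", {
  x <- dn_image(fill = 100, panel_fill = 0)
  expect_error(calibrate_reflectance(x$img, x$panel), "panel DN")
  cal <- calibrate_reflectance(dn_image(100, 100)$img, x$panel)
  expect_error(calibrate_reflectance(cal, x$panel), "already calibrated")
  bands <- list(B = matrix(1, 4, 4), G = matrix(1, 4, 4), R = matrix(1, 4, 4),
                RE = matrix(1, 4, 4), NIR = matrix(1, 5, 5))
  expect_error(multispectral_image(bands, "DN"), "dimensions")
})

test_that("ExGR follows its algebraic form", {
  img <- flat_image(c(0.3, 0.3, 0.3, 0.1, 0.5))     # R = G = B = 0.3
  expect_equal(compute_exgr(img)[1, 1], -0.4 * 0.3, tolerance = 1e-12)
  img0 <- flat_image(c(0, 0, 0, 0, 0))
  expect_equal(compute_exgr(img0)[1, 1], 0)
  img1 <- flat_image(c(0, 1, 0, 0, 0))              # G = 1, R = B = 0
  expect_equal(compute_exgr(img1)[1, 1], 3)

  # elementwise equivalence with the unsimplified two-term form
  set.seed(31)
  bands <- lapply(1:5, function(i) matrix(runif(64), 8, 8))
  names(bands) <- c("B", "G", "R", "RE", "NIR")
  img2 <- multispectral_image(bands, domain = "reflectance")
  ref <- (2 * bands$G - bands$R - bands$B) - (1.4 * bands$R - bands$G)
  expect_equal(compute_exgr(img2), ref, tolerance = 1e-14)
})


test_that("Otsu equals the exhaustive cut-point search", {
  set.seed(17)
  cases <- list(c(rep(0, 50), rep(1, 50)),
                c(rnorm(5000, -3, 0.5), rnorm(5000, 3, 0.5)),
                runif(400),
                c(rnorm(200, 0, 1), rnorm(100, 6, 2)))
  for (v in cases)
    expect_equal(otsu_threshold(v), otsu_brute(v), tolerance = 1e-12)

  thr_binary <- otsu_threshold(c(rep(0, 50), rep(1, 50)))
  expect_gt(thr_binary, 0); expect_lt(thr_binary, 1)
  thr_gauss <- otsu_threshold(c(rnorm(5000, -3, 0.5), rnorm(5000, 3, 0.5)))
  expect_gt(thr_gauss, -1); expect_lt(thr_gauss, 1)
  expect_error(otsu_threshold(rep(2, 10)), "constant")
})

test_that("segmentation recovers the true canopy on noise-free imagery", {
  for (s in c(11, 12, 13)) {
    spec <- tiny_spec(pixel_noise_sd = 0, within_class_sd = 0,
                      illumination_jitter_sd = 0, background_fraction = 0.4)
    g <- generate_image(spec, 1 + (s %% 3), seed = s)
    cal <- calibrate_generated(g, spec)
    mask <- segment_canopy(cal)
    expect_gte(mean(mask$grid == g$truth_mask), 0.99)
  }
})

test_that("background-free images segment to near-full coverage", {
  spec <- tiny_spec(background_fraction = 0, pixel_noise_sd = 0,
                    within_class_sd = 0)
  g <- generate_image(spec, 1, seed = 2)
  cal <- calibrate_generated(g, spec)
  mask <- segment_canopy(cal)
  pr <- cal$panel_region
  non_panel <- prod(dim(cal)) - (pr$row1 - pr$row0 + 1) * (pr$col1 - pr$col0 + 1)
  expect_gte(sum(mask$grid) / non_panel, 0.95)
})

test_that("swapping vegetation and soil spectra inverts the mask", {
  soil_like <- matrix(rep(c(0.100, 0.170, 0.180, 0.240, 0.300), each = 3), 3, 5)
  spec <- tiny_spec(band_means = soil_like,
                    soil_reflectance = c(0.04, 0.09, 0.05, 0.30, 0.50),
                    background_fraction = 0.5, shadow_fraction = 0,
                    pixel_noise_sd = 0, within_class_sd = 0,
                    texture_params = data.frame(scale = rep(3, 3),
                                                eccentricity = 1.5,
                                                orientation = 0, density = 12,
                                                amplitude = 0.05))
  g <- generate_image(spec, 1, seed = 6)
  cal <- calibrate_generated(g, spec)
  mask <- segment_canopy(cal)
  pr <- cal$panel_region
  keep <- matrix(TRUE, nrow(mask$grid), ncol(mask$grid))
  keep[pr$row0:pr$row1, pr$col0:pr$col1] <- FALSE
  expect_gte(mean((mask$grid == !g$truth_mask)[keep]), 0.99)
})

test_that("a fixed zero threshold is available for ExGR practice", {
  # shadow shares the canopy's spectral shape, so the zero-threshold rule is
  # only exact on shadow-free scenes
  spec <- tiny_spec(background_fraction = 0.4, shadow_fraction = 0,
                    pixel_noise_sd = 0, within_class_sd = 0)
  g <- generate_image(spec, 1, seed = 3)
  cal <- calibrate_generated(g, spec)
  mask <- segment_canopy(cal, threshold = 0)
  expect_gte(mean(mask$grid == g$truth_mask), 0.95)
})
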