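# The 86-indicator registry: colour, GLCM, LBP, band and vegetation-index
# features, each checked against algebraic identities and independent
# brute-force oracles.

test_that("the registry holds exactly 86 uniquely named indicators", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 86)
  expect_equal(anyDuplicated(reg$name), 0)
  expect_equal(as.vector(table(factor(reg$group,
    c("color_value", "color_index", "glcm", "lbp", "band", "vi")))),
    c(9, 7, 8, 7, 5, 50))
})

test_that("pseudo-RGB is the clipped stack of the R, G, B reflectances", {
  img <- flat_image(c(0.5, 0.5, 0.5, 0.2, 0.9))
  rgb <- compose_pseudo_rgb(img)
  expect_equal(rgb$r[1, 1], 0.5); expect_equal(rgb$g[3, 3], 0.5)
  img_hot <- flat_image(c(1.2, 0.4, 1.2, 0.2, 0.9))
  rgb_hot <- compose_pseudo_rgb(img_hot)
  expect_true(all(rgb_hot$b == 1.0)); expect_true(all(rgb_hot$r == 1.0))

  set.seed(8)
  bands <- lapply(1:5, function(i) matrix(runif(36, -0.1, 1.3), 6, 6))
  names(bands) <- c("B", "G", "R", "RE", "NIR")
  img_r <- multispectral_image(bands, domain = "reflectance")
  rgb_r <- compose_pseudo_rgb(img_r)
  expect_equal(rgb_r$g, pmin(pmax(bands$G, 0), 1), tolerance = 1e-15)
})

test_that("colour features match HSV and CIELab reference points", {
  mask <- matrix(TRUE, 12, 12)
  red <- color_features(flat_image(c(0, 0, 1, 0.2, 0.5)), mask)
  expect_equal(unname(red[c("h", "s", "v")]), c(0, 1, 1), tolerance = 1e-12)

  white <- color_features(flat_image(c(1, 1, 1, 0.2, 0.5)), mask)
  expect_equal(unname(white["L"]), 100, tolerance = 1e-6)
  expect_lt(abs(white[["a_star"]]), 1e-6)
  expect_lt(abs(white[["b_star"]]), 1e-6)
  expect_equal(unname(white["LI"]), 100, tolerance = 1e-5)

  # neutral grey: a* = b* = 0, so the normalised-difference indices
  # collapse to the NaN-policy value
  grey <- color_features(flat_image(c(0.5, 0.5, 0.5, 0.2, 0.5)), mask)
  expect_equal(unname(grey["NDABI"]), 0)
  # and the Lab index algebra holds on the reported means
  expect_equal(unname(grey["LI"]), grey[["L"]] - grey[["b_star"]],
               tolerance = 1e-10)
  expect_equal(unname(grey["AI"]), grey[["b_star"]] - grey[["a_star"]],
               tolerance = 1e-10)
})

test_that("the empty mask is rejected", {
  img <- flat_image(c(0.2, 0.4, 0.1, 0.3, 0.6))
  expect_error(color_features(img, matrix(FALSE, 12, 12)), "empty mask")
  expect_error(band_means(img, matrix(FALSE, 12, 12)), "empty mask")
})


test_that("the GLCM matches exhaustive pair enumeration", {
  # the 2x2 toy grid [[0,1],[0,1]]
  g <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  cfg <- texture_config(gray_levels = 2)
  P <- glcm(g, matrix(TRUE, 2, 2), cfg)
  expect_equal(P, glcm_brute(g, matrix(TRUE, 2, 2), 2), tolerance = 1e-15)
  expect_equal(P, matrix(c(2, 4, 4, 2) / 12, 2, 2), tolerance = 1e-15)

  # random grids with masked-out pixels
  set.seed(12)
  for (i in 1:3) {
    g <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    m <- matrix(runif(100) > 0.2, 10, 10)
    P <- glcm(g, m, texture_config(gray_levels = 8))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-15)
    expect_equal(P, glcm_brute(g, m, 8), tolerance = 1e-14)
  }
})

test_that("constant images give the degenerate GLCM statistics", {
  g <- matrix(3L, 6, 6)
  P <- glcm(g, matrix(TRUE, 6, 6), texture_config(gray_levels = 8))
  expect_equal(P[4, 4], 1)
  f <- glcm_features(P)
  expect_equal(unname(f[c("Asm", "Ent", "Con", "Hom", "Dis")]),
               c(1, 0, 0, 1, 0))
  N <- 4
  f_u <- glcm_features(matrix(1 / N^2, N, N))
  expect_equal(unname(f_u["Asm"]), 1 / N^2, tolerance = 1e-15)
})


test_that("GLCM statistics equal the naive double-loop implementation", {
  set.seed(23)
  for (i in 1:5) {
    M <- matrix(runif(16), 4, 4)
    M <- (M + t(M)) / 2
    P <- M / sum(M)
    expect_equal(glcm_features(P), glcm_features_brute(P), tolerance = 1e-12)
  }
})


test_that("LBP statistics match a naive per-pixel reimplementation", {
  set.seed(5)
  for (i in 1:3) {
    g <- matrix(runif(256), 16, 16)
    m <- matrix(runif(256) > 0.15, 16, 16)
    expect_equal(lbp_features(g, m), lbp_brute(g, m), tolerance = 1e-12)
  }
})

test_that("constant images give the single-bin LBP statistics", {
  f <- lbp_features(matrix(0.4, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(unname(f[c("G_lbp", "E", "sigma", "Rs")]), c(1, 0, 0, 0))
  # under the >= rule all neighbours tie-break to bit 1 (code 255)
  codes <- lbp_codes(matrix(0.4, 8, 8), matrix(TRUE, 8, 8))
  expect_true(all(codes == 255L))
})

test_that("band means are masked averages", {
  img <- flat_image(c(0.1, 0.2, 0.3, 0.35, 0.4))
  bm <- band_means(img, matrix(TRUE, 12, 12))
  expect_equal(unname(bm), c(0.1, 0.2, 0.3, 0.35, 0.4), tolerance = 1e-15)

  half <- matrix(0.2, 10, 10); half[, 6:10] <- 0.6
  bands <- list(B = half, G = half, R = half, RE = half, NIR = half)
  img2 <- multispectral_image(bands, domain = "reflectance")
  expect_equal(unname(band_means(img2, matrix(TRUE, 10, 10))["NIR"]), 0.4)

  set.seed(77)
  m <- matrix(runif(100) > 0.4, 10, 10)
  expect_equal(unname(band_means(img2, m)["G"]), mean(half[m]),
               tolerance = 1e-12)
})


test_that("vegetation indices satisfy their algebraic identities", {
  v <- c(B = 0.1, G = 0.2, R = 0.4, RE = 0.3, NIR = 0.4)   # NIR = R
  vi <- vegetation_indices(v)
  expect_equal(unname(vi[c("NDVI", "DVI", "RVI", "SR")]), c(0, 0, 1, 1))

  v2 <- c(B = 0.1, G = 0.15, R = 0.2, RE = 0.5, NIR = 0.8)
  vi2 <- vegetation_indices(v2)
  expect_equal(unname(vi2["NDVI"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(vi2["DVI"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(vi2["RVI"]), 4, tolerance = 1e-12)
})

test_that("all 50 indices match an independently coded formula table", {
  set.seed(44)
  for (i in 1:100) {
    v <- stats::setNames(runif(5, 0.02, 0.95), c("B", "G", "R", "RE", "NIR"))
    expect_equal(vegetation_indices(v), vi_brute(unname(v)),
                 tolerance = 1e-10)
  }
})

test_that("duplicate-formula indices agree exactly", {
  set.seed(45)
  for (i in 1:20) {
    v <- stats::setNames(runif(5, 0.05, 0.9), c("B", "G", "R", "RE", "NIR"))
    vi <- vegetation_indices(v)
    expect_identical(vi[["RVI"]], vi[["SR"]])
    expect_identical(vi[["PGR"]], vi[["RGI"]])
    expect_identical(vi[["GRVI"]], vi[["NGRDI"]])
  }
})

test_that("extract_all returns the registry in order, deterministically, and
           ignores pixels outside the mask", {
  spec <- tiny_spec()
  g <- generate_image(spec, 1, seed = 19)
  cal <- calibrate_generated(g, spec)
  mask <- canopy_mask(g$truth_mask)
  fv <- extract_all(cal, mask)
  expect_length(fv, 86)
  expect_identical(names(fv), feature_registry()$name)
  expect_identical(fv, extract_all(cal, mask))

  # scribble over everything outside the mask: features must not move
  cal2 <- cal
  out <- !g$truth_mask
  set.seed(50)
  for (b in names(cal2$bands)) cal2$bands[[b]][out] <- runif(sum(out))
  expect_identical(extract_all(cal2, mask), fv)
})

test_that("class structure shows up in NDVI between/within variance", {
  ft <- shared_features()
  fit <- stats::aov(NDVI ~ cultivar, data = as.data.frame(ft))
  f_ratio <- summary(fit)[[1]][["F value"]][1]
  expect_gt(f_ratio, 10)
})
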