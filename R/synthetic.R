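# Seeded synthetic multispectral canopy generator.
#
# Emulates five-band canopy acquisitions over a tea garden: per-cultivar
# reflectance spectra with germination-stage structure, leaf-blob texture,
# soil/shadow background, an in-scene reference panel and multiplicative
# illumination jitter.  Every stage of the analysis is testable against the
# generator's recorded ground truth.

# The 18 oolong cultivars and their germination stage (5 early, 5 mesophytic,
# 8 late).
OOLONG_CULTIVARS <- c(
  Baxian = "early", `Yellow Rose` = "early", Huangyan = "early",
  Dangui = "early", Jinmudan = "early",
  Baijiguan = "mesophytic", Beidou = "mesophytic", Benshan = "mesophytic",
  Maoxie = "mesophytic", Foshou = "mesophytic",
  Shuixian = "late", Rougui = "late", Jiulongpao = "late", Qilan = "late",
  Ruixiang = "late", Dahongpao = "late", Tieluohan = "late", Tieguanyin = "late")

GERMINATION_STAGES <- c("early", "mesophytic", "late")

# Reference vegetation spectrum (healthy tea canopy) and soil spectrum
# (bright, red-heavy, weak NIR contrast), reflectance units.  The soil
# spectrum keeps ExGR slightly negative, so soil and shadow fall on one side
# of the vegetation/background split that ExGR + Otsu recovers.
VEGETATION_SPECTRUM <- c(B = 0.040, G = 0.090, R = 0.050, RE = 0.300, NIR = 0.500)
SOIL_SPECTRUM <- c(B = 0.100, G = 0.170, R = 0.180, RE = 0.240, NIR = 0.300)

# Germination-stage spectral multipliers: earlier-flushing cultivars carry a
# denser young canopy (higher NIR/red-edge, slightly greener); late cultivars
# the opposite.  These stage-level shifts are what the germination
# discriminant analysis later recovers.
STAGE_BAND_MULT <- rbind(
  early      = c(B = 0.97, G = 1.04, R = 0.96, RE = 1.05, NIR = 1.07),
  mesophytic = c(B = 1.00, G = 1.00, R = 1.00, RE = 1.00, NIR = 1.00),
  late       = c(B = 1.03, G = 0.96, R = 1.04, RE = 0.95, NIR = 0.93))

# Fixed library of per-cultivar spectral offsets (fractional, in [-1, 1]):
# a frozen draw so that the default band means are reproducible constants.
cultivar_offsets <- function(n) {
  with_seed(771220, matrix(stats::runif(n * 5, -1, 1), n, 5,
                           dimnames = list(NULL, BAND_NAMES)))
}

default_band_means <- function(cultivars, assignment, offset_amplitude = 0.10) {
  n <- length(cultivars)
  off <- cultivar_offsets(n)
  bm <- matrix(NA_real_, n, 5, dimnames = list(cultivars, BAND_NAMES))
  for (i in seq_len(n)) {
    stage <- assignment[[cultivars[i]]]
    bm[i, ] <- VEGETATION_SPECTRUM * STAGE_BAND_MULT[stage, ] *
      (1 + offset_amplitude * off[i, ])
  }
  bm
}

default_texture_params <- function(n) {
  # leaf-blob kernels: per-cultivar scale (px), eccentricity, orientation,
  # density (blobs per 1000 px) and modulation amplitude; spread so second-
  # order texture statistics differ across cultivars.
  ord <- with_seed(771221, sample.int(n))
  data.frame(
    scale = seq(2.0, 5.0, length.out = n),
    eccentricity = seq(1.0, 3.0, length.out = n)[ord],
    orientation = seq(0, pi * (n - 1) / n, length.out = n),
    density = rep(12, n),
    amplitude = seq(0.10, 0.30, length.out = n)[rev(ord)])
}

#' Specification of a synthetic multispectral canopy dataset
#'
#' Defines the study conditions the generator emulates: 18 oolong tea
#' cultivars (5 early-, 5 mesophytic- and 8 late-germinating) with
#' class-specific five-band reflectance, leaf-blob canopy texture, soil and
#' shadow background, an in-scene reference panel, and multiplicative
#' illumination jitter between acquisitions.
#'
#' @param n_cultivars number of cultivar classes (default 18).
#' @param images_per_cultivar images generated per cultivar.
#' @param cultivar_names optional class names; defaults to the 18 oolong
#'   cultivar names when `n_cultivars == 18`.
#' @param germination_assignment named character vector cultivar -> stage
#'   (`early`/`mesophytic`/`late`); default is the 5/5/8 oolong grouping.
#' @param band_means `n_cultivars x 5` matrix of mean canopy reflectance per
#'   band (B,G,R,RE,NIR), each entry in `[0, 1]`.  Default: a vegetation
#'   spectrum with germination-stage multipliers and fixed per-cultivar
#'   offsets.
#' @param within_class_sd sd (reflectance units) of the per-image canopy
#'   spectral deviation — biological variation between plants of one
#'   cultivar, which calibration cannot remove.
#' @param pixel_noise_sd per-pixel additive sensor noise sd (reflectance
#'   units, before DN quantisation).
#' @param texture_params data.frame with one row per cultivar: `scale`,
#'   `eccentricity`, `orientation`, `density`, `amplitude`.
#' @param background_fraction fraction of non-panel pixels that are
#'   background (soil + shadow), in `[0, 1)`.
#' @param shadow_fraction fraction of the background that is shadow.
#' @param shadow_factor shadow spectrum = canopy spectrum x this factor.
#' @param soil_reflectance 5-vector soil reflectance.
#' @param illumination_jitter_sd sd of the log illumination factor
#'   (multiplicative, applied to DN before quantisation).
#' @param panel_reflectance 5-vector reference-panel reflectance in (0, 1].
#' @param panel_frac side of the square panel as a fraction of the shorter
#'   image side.
#' @param image_size integer `(rows, cols)`, at least 16 x 16.
#' @param seed master seed for [generate_dataset()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cultivars = 18,
                           images_per_cultivar = 10,
                           cultivar_names = NULL,
                           germination_assignment = NULL,
                           band_means = NULL,
                           within_class_sd = 0.002,
                           pixel_noise_sd = 0.004,
                           texture_params = NULL,
                           background_fraction = 0.35,
                           shadow_fraction = 0.3,
                           shadow_factor = 0.3,
                           soil_reflectance = SOIL_SPECTRUM,
                           illumination_jitter_sd = 0.05,
                           panel_reflectance = rep(0.5, 5),
                           panel_frac = 0.12,
                           image_size = c(64, 64),
                           seed = 1L) {
  stopifnot(n_cultivars >= 1, images_per_cultivar >= 1,
            within_class_sd >= 0, pixel_noise_sd >= 0,
            background_fraction >= 0, background_fraction < 1,
            illumination_jitter_sd >= 0,
            length(image_size) == 2, all(image_size >= 16))
  if (is.null(cultivar_names)) {
    cultivar_names <- if (n_cultivars == 18) names(OOLONG_CULTIVARS)
      else sprintf("cultivar_%02d", seq_len(n_cultivars))
  }
  stopifnot(length(cultivar_names) == n_cultivars)
  if (is.null(germination_assignment)) {
    germination_assignment <- if (n_cultivars == 18) OOLONG_CULTIVARS else
      stats::setNames(rep_len(GERMINATION_STAGES, n_cultivars), cultivar_names)
    names(germination_assignment) <- cultivar_names
  }
  if (!all(cultivar_names %in% names(germination_assignment)))
    stopf("germination_assignment must cover every cultivar")
  if (!all(germination_assignment %in% GERMINATION_STAGES))
    stopf("germination stages must be one of %s",
          paste(GERMINATION_STAGES, collapse = ", "))
  if (is.null(band_means))
    band_means <- default_band_means(cultivar_names, germination_assignment)
  band_means <- as.matrix(band_means)
  stopifnot(nrow(band_means) == n_cultivars, ncol(band_means) == 5,
            all(band_means >= 0), all(band_means <= 1))
  rownames(band_means) <- cultivar_names
  colnames(band_means) <- BAND_NAMES
  if (is.null(texture_params)) texture_params <- default_texture_params(n_cultivars)
  panel_reflectance <- stats::setNames(as.numeric(panel_reflectance), BAND_NAMES)
  stopifnot(all(panel_reflectance > 0), all(panel_reflectance <= 1))
  soil_reflectance <- stats::setNames(as.numeric(soil_reflectance), BAND_NAMES)
  structure(list(
    n_cultivars = n_cultivars, images_per_cultivar = images_per_cultivar,
    cultivar_names = cultivar_names,
    germination_assignment = germination_assignment[cultivar_names],
    band_means = band_means, within_class_sd = within_class_sd,
    pixel_noise_sd = pixel_noise_sd, texture_params = texture_params,
    background_fraction = background_fraction,
    shadow_fraction = shadow_fraction, shadow_factor = shadow_factor,
    soil_reflectance = soil_reflectance,
    illumination_jitter_sd = illumination_jitter_sd,
    panel_reflectance = panel_reflectance, panel_frac = panel_frac,
    image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> %d cultivars x %d images, %dx%d px, ",
                     "background %.0f%%, seed %d\n"),
              x$n_cultivars, x$images_per_cultivar, x$image_size[1],
              x$image_size[2], 100 * x$background_fraction, x$seed))
  invisible(x)
}

# Smooth random field in [0,1]: bilinear upsampling of a coarse uniform grid.
smooth_field <- function(nr, nc, coarse, rng) {
  g <- matrix(rng$runif((coarse + 1)^2), coarse + 1, coarse + 1)
  ri <- seq(1, coarse + 1 - 1e-9, length.out = nr)
  ci <- seq(1, coarse + 1 - 1e-9, length.out = nc)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- g[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  cc <- g[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  d <- g[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  w <- matrix(a * (1 - fr) * rep(1 - fc, each = nr) +
              b * fr * rep(1 - fc, each = nr) +
              cc * (1 - fr) * rep(fc, each = nr) +
              d * fr * rep(fc, each = nr), nr, nc)
  w
}

# Leaf-blob texture: sum of anisotropic Gaussian kernels at random centres;
# standardised to mean 0 / sd 1 so the multiplicative modulation is unbiased.
texture_field <- function(nr, nc, tp, rng) {
  k <- max(1L, round(tp$density * nr * nc / 1000))
  cy <- rng$runif(k) * nr
  cx <- rng$runif(k) * nc
  co <- cos(tp$orientation); si <- sin(tp$orientation)
  sy <- tp$scale; sx <- tp$scale * tp$eccentricity
  Y <- matrix(seq_len(nr), nr, nc)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (i in seq_len(k)) {
    dy <- Y - cy[i]; dx <- X - cx[i]
    u <- co * dx + si * dy
    v <- -si * dx + co * dy
    f <- f + exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  }
  s <- stats::sd(f)
  if (s < 1e-12) matrix(0, nr, nc) else (f - mean(f)) / s
}

panel_region_for <- function(spec) {
  side <- max(4L, round(spec$panel_frac * min(spec$image_size)))
  list(row0 = 1L, row1 = as.integer(side), col0 = 1L, col1 = as.integer(side))
}

#' Generate one synthetic canopy image
#'
#' Draws canopy reflectance around the cultivar's band means (with a
#' per-image spectral deviation of sd `within_class_sd` and multiplicative
#' leaf-blob texture), composites soil and shadow background and the
#' reference panel, applies an illumination factor, and quantises to digital
#' numbers (reflectance 1.0 -> DN 10000, 16-bit ceiling).
#'
#' @param spec a [synthetic_spec()].
#' @param cultivar cultivar name or index.
#' @param seed RNG seed for this image (default: the spec seed).
#' @return list with `image` (a DN-domain [multispectral_image()] whose
#'   `panel_region` is set), `truth_mask` (logical canopy grid, panel
#'   excluded), `cultivar`, `illumination` (the applied factor) and
#'   `effective_band_means` (the per-image canopy means actually used).
#' @export
generate_image <- function(spec, cultivar, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.numeric(cultivar)) cultivar <- spec$cultivar_names[cultivar]
  ci <- match(cultivar, spec$cultivar_names)
  if (is.na(ci)) stopf("unknown cultivar id: %s", as.character(cultivar))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  rng <- local_rng(seed)

  illum <- exp(rng$rnorm(1, 0, spec$illumination_jitter_sd))
  eff <- pmin(pmax(spec$band_means[ci, ] + rng$rnorm(5, 0, spec$within_class_sd),
                   0.001), 1)

  # background layout: thresholded smooth field, shadow inside background
  bg <- matrix(FALSE, nr, nc)
  shadow <- matrix(FALSE, nr, nc)
  if (spec$background_fraction > 0) {
    f <- smooth_field(nr, nc, coarse = 6, rng)
    bg <- f < stats::quantile(f, spec$background_fraction)
    if (spec$shadow_fraction > 0) {
      f2 <- smooth_field(nr, nc, coarse = 6, rng)
      thr <- stats::quantile(f2[bg], spec$shadow_fraction)
      shadow <- bg & (f2 < thr)
    }
  }
  tex <- 1 + spec$texture_params$amplitude[ci] *
    texture_field(nr, nc, spec$texture_params[ci, ], rng)
  tex <- pmax(tex, 0.05)

  pr <- panel_region_for(spec)
  pidx <- panel_index(pr, c(nr, nc))

  bands <- stats::setNames(vector("list", 5), BAND_NAMES)
  for (b in BAND_NAMES) {
    refl <- eff[[b]] * tex
    refl[shadow] <- eff[[b]] * spec$shadow_factor
    refl[bg & !shadow] <- spec$soil_reflectance[[b]]
    if (spec$pixel_noise_sd > 0)
      refl <- refl + matrix(rng$rnorm(nr * nc, 0, spec$pixel_noise_sd), nr, nc)
    refl[pidx] <- spec$panel_reflectance[[b]]  # panel: noise- and texture-free
    dn <- round(pmax(refl, 0) * illum * DN_PER_REFLECTANCE)
    bands[[b]] <- matrix(pmin(dn, DN_MAX), nr, nc)
  }
  truth <- !bg
  truth[pidx] <- FALSE
  list(image = multispectral_image(bands, domain = "DN", panel_region = pr),
       truth_mask = truth, cultivar = spec$cultivar_names[ci],
       illumination = illum, effective_band_means = eff)
}

#' Generate a full synthetic dataset
#'
#' `images_per_cultivar` images for every cultivar, with per-image seeds
#' derived from the spec's master seed (bit-identical across calls).
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: lists `images`,
#'   `truth_masks`, vectors `labels` and `germination_labels`, the `panel`
#'   ([panel_reference()]) and the `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  master <- local_rng(spec$seed)
  n <- spec$n_cultivars * spec$images_per_cultivar
  images <- vector("list", n)
  masks <- vector("list", n)
  labels <- character(n)
  illum <- numeric(n)
  eff <- matrix(NA_real_, n, 5, dimnames = list(NULL, BAND_NAMES))
  i <- 0L
  for (cv in spec$cultivar_names) {
    for (j in seq_len(spec$images_per_cultivar)) {
      i <- i + 1L
      g <- generate_image(spec, cv, seed = master$child_seed())
      images[[i]] <- g$image
      masks[[i]] <- g$truth_mask
      labels[i] <- cv
      illum[i] <- g$illumination
      eff[i, ] <- g$effective_band_means
    }
  }
  structure(list(
    images = images, truth_masks = masks, labels = labels,
    germination_labels = unname(spec$germination_assignment[labels]),
    illumination = illum, effective_band_means = eff,
    panel = panel_reference(panel_region_for(spec), spec$panel_reflectance),
    spec = spec), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d images, %d cultivars (%s stages)\n",
              length(x$images), length(unique(x$labels)),
              paste(table(factor(x$germination_labels, GERMINATION_STAGES))[
                GERMINATION_STAGES], collapse = "/")))
  invisible(x)
}

#' Generate a labelled feature-space dataset
#'
#' Bypasses imaging: informative features are class-specific Gaussians with
#' unit within-class sd whose class centres are rescaled so the *minimum*
#' pairwise between-class distance equals `class_separation`; noise features
#' are class-independent standard Gaussians.  Ground truth (informative vs
#' noise) is stored in `attr(, "informative")`.
#'
#' @param n_classes,n_per_class,n_features,n_noise_features positive counts
#'   (`n_features` informative columns, `n_noise_features` pure-noise
#'   columns).
#' @param class_separation nonnegative; 0 means no class signal at all.
#' @param seed RNG seed.
#' @return a [feature_table()] with columns `inf_*` then `noise_*`.
#' @export
generate_feature_table <- function(n_classes, n_per_class, n_features,
                                   class_separation, n_noise_features = 0,
                                   seed = 1L) {
  stopifnot(n_classes >= 1, n_per_class >= 1, n_features >= 1,
            class_separation >= 0, n_noise_features >= 0)
  rng <- local_rng(seed)
  # per feature: class means on a permuted unit grid (plus +/-20% jitter to
  # break collinearity between features), scaled by class_separation, so
  # every informative feature individually separates the classes
  centers <- matrix(0, n_classes, n_features)
  if (n_classes > 1 && class_separation > 0) {
    for (f in seq_len(n_features)) {
      grid <- rng$sample_int(n_classes) - (n_classes + 1) / 2
      jitter <- rng$runif(n_classes) * 0.4 - 0.2
      centers[, f] <- class_separation * (grid + jitter)
    }
  }
  n <- n_classes * n_per_class
  lab <- rep(sprintf("class_%02d", seq_len(n_classes)), each = n_per_class)
  X <- centers[rep(seq_len(n_classes), each = n_per_class), , drop = FALSE] +
    matrix(rng$rnorm(n * n_features), n, n_features)
  colnames(X) <- sprintf("inf_%02d", seq_len(n_features))
  if (n_noise_features > 0) {
    Z <- matrix(rng$rnorm(n * n_noise_features), n, n_noise_features)
    colnames(Z) <- sprintf("noise_%02d", seq_len(n_noise_features))
    X <- cbind(X, Z)
  }
  out <- feature_table(X, lab)
  attr(out, "informative") <- stats::setNames(
    c(rep(TRUE, n_features), rep(FALSE, n_noise_features)), colnames(X))
  out
}

#' Write a synthetic dataset as multi-band TIFF plus a CSV manifest
#'
#' Each image becomes a five-page 16-bit TIFF (band order B,G,R,RE,NIR); the
#' manifest records filename, cultivar, germination stage and panel
#' coordinates.  Requires the `tiff` package.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("write_dataset requires the 'tiff' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- dataset$panel$region
  rows <- lapply(seq_along(dataset$images), function(i) {
    fn <- sprintf("img_%04d.tif", i)
    img <- dataset$images[[i]]
    pages <- lapply(img$bands, function(m) m / DN_MAX)  # tiff wants [0,1]
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 16L)
    data.frame(filename = fn, cultivar = dataset$labels[i],
               germination = dataset$germination_labels[i],
               seed = dataset$spec$seed,
               panel_row0 = pr$row0, panel_row1 = pr$row1,
               panel_col0 = pr$col0, panel_col1 = pr$col1)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a multi-band TIFF written by [write_dataset()]
#' @param path TIFF path.
#' @param panel_region optional panel rectangle to attach.
#' @return a DN-domain [multispectral_image()].
#' @export
read_multispectral_tiff <- function(path, panel_region = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("read_multispectral_tiff requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 5) stopf("expected 5 bands, found %d", length(pages))
  bands <- stats::setNames(lapply(pages, function(m) round(m * DN_MAX)), BAND_NAMES)
  multispectral_image(bands, domain = "DN", panel_region = panel_region)
}
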