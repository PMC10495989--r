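# Radiometric calibration, vegetation-index contrast enhancement and
# canopy segmentation for five-band multispectral canopy images.

BAND_NAMES <- c("B", "G", "R", "RE", "NIR")
BAND_WAVELENGTHS_NM <- c(B = 475, G = 560, R = 668, RE = 717, NIR = 840)

# Digital-number convention for the synthetic sensor: reflectance 1.0 maps to
# DN 10000 on a 16-bit scale, leaving headroom for illumination above unity.
DN_PER_REFLECTANCE <- 10000
DN_MAX <- 65535

#' Construct a five-band multispectral image
#'
#' Container for co-registered canopy imagery from a five-band camera
#' (blue 475 nm, green 560 nm, red 668 nm, red edge 717 nm, NIR 840 nm).
#' Values are either raw digital numbers (`domain = "DN"`) or calibrated
#' reflectance (`domain = "reflectance"`).
#'
#' @param bands named list of five numeric matrices, keys `B, G, R, RE, NIR`,
#'   all with identical dimensions.
#' @param domain `"DN"` or `"reflectance"`.
#' @param panel_region optional reference-panel rectangle, a list with integer
#'   fields `row0, row1, col0, col1` (inclusive pixel bounds).
#' @return an object of class `multispectral_image`.
#' @export
multispectral_image <- function(bands, domain = c("DN", "reflectance"),
                                panel_region = NULL) {
  domain <- match.arg(domain)
  if (!is.list(bands) || !setequal(names(bands), BAND_NAMES))
    stopf("bands must be a named list with keys %s",
          paste(BAND_NAMES, collapse = ", "))
  bands <- bands[BAND_NAMES]
  dims <- lapply(bands, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("every band must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("all bands must share dimensions")
  if (!is.null(panel_region)) {
    d <- dim(bands[[1]])
    pr <- panel_region
    ok <- all(c(pr$row0, pr$col0) >= 1) && pr$row1 <= d[1] && pr$col1 <= d[2] &&
      pr$row0 <= pr$row1 && pr$col0 <= pr$col1
    if (!ok) stopf("panel_region outside image bounds")
  }
  structure(list(bands = bands,
                 wavelengths_nm = BAND_WAVELENGTHS_NM,
                 domain = domain,
                 panel_region = panel_region),
            class = "multispectral_image")
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<multispectral_image> %d x %d, 5 bands (%s), domain=%s%s\n",
              d[1], d[2], paste(BAND_NAMES, collapse = ","), x$domain,
              if (is.null(x$panel_region)) "" else ", panel present"))
  invisible(x)
}

#' @export
dim.multispectral_image <- function(x) dim(x$bands[[1]])

#' Reference panel of known reflectance
#'
#' Describes the in-scene calibration board: its pixel rectangle and its
#' known per-band reflectance \eqn{R_s}.
#'
#' @param region rectangle list (`row0,row1,col0,col1`, inclusive).
#' @param Rs numeric length-5 per-band reflectance in (0, 1], order B,G,R,RE,NIR.
#' @return an object of class `panel_reference`.
#' @export
panel_reference <- function(region, Rs) {
  Rs <- as.numeric(Rs)
  if (length(Rs) != 5 || any(!is.finite(Rs)) || any(Rs <= 0))
    stopf("Rs must be 5 finite positive reflectances")
  names(Rs) <- BAND_NAMES
  structure(list(region = region, Rs = Rs), class = "panel_reference")
}

panel_index <- function(region, d) {
  rows <- region$row0:region$row1
  cols <- region$col0:region$col1
  as.vector(outer(rows, (cols - 1) * d[1], `+`))
}

#' Calibrate digital numbers to reflectance with a reference panel
#'
#' Per band, \eqn{R_i = DN_i \times R_s / \overline{DN_s}}, where
#' \eqn{\overline{DN_s}} is the arithmetic mean digital number over the panel
#' region and \eqn{R_s} the panel's known reflectance in that band.  The
#' mapping is linear in DN, so a uniform illumination change (which scales the
#' panel and the scene alike) cancels exactly.
#'
#' @param img a `multispectral_image` in the DN domain.
#' @param panel a [panel_reference()].
#' @return the image in the reflectance domain (panel region preserved).
#' @export
calibrate_reflectance <- function(img, panel) {
  stopifnot(inherits(img, "multispectral_image"), inherits(panel, "panel_reference"))
  if (img$domain != "DN") stopf("image already calibrated (domain=%s)", img$domain)
  d <- dim(img)
  pr <- panel$region
  if (pr$row1 > d[1] || pr$col1 > d[2] || pr$row0 < 1 || pr$col0 < 1)
    stopf("panel region outside image (image %dx%d)", d[1], d[2])
  idx <- panel_index(pr, d)
  out <- img
  for (b in BAND_NAMES) {
    dn_s <- mean(img$bands[[b]][idx])
    if (!is.finite(dn_s) || dn_s <= 0)
      stopf("mean panel DN in band %s is %g; cannot calibrate", b, dn_s)
    out$bands[[b]] <- img$bands[[b]] * (panel$Rs[[b]] / dn_s)
  }
  out$domain <- "reflectance"
  out$panel_region <- pr
  out
}

#' Band co-registration hook
#'
#' Field imagery needs feature-based band-to-band registration before fusion;
#' the synthetic generator emits bands already co-registered, so this hook
#' only asserts equal dimensions and returns its input unchanged.  It is the
#' place a geometric registration step would plug in.
#'
#' @param img a `multispectral_image`.
#' @return `img`, unchanged.
#' @export
register_bands <- function(img) {
  stopifnot(inherits(img, "multispectral_image"))
  img  # constructor already enforces equal dimensions
}

#' Excess-green-minus-excess-red (ExGR) grid
#'
#' Computes per pixel \eqn{ExGR = (2G - R - B) - (1.4R - G) = 3G - 2.4R - B}
#' from the green, red and blue bands.  Vegetation is bright in G and dark in
#' R/B, so ExGR is strongly positive over canopy and near or below zero over
#' soil and shadow, which is what makes it a good segmentation contrast.
#'
#' @param img a `multispectral_image` (reflectance domain recommended: it
#'   removes the illumination dependence before thresholding).
#' @return numeric matrix of ExGR values.
#' @export
compute_exgr <- function(img) {
  stopifnot(inherits(img, "multispectral_image"))
  3 * img$bands$G - 2.4 * img$bands$R - img$bands$B
}

#' Otsu's threshold
#'
#' Histogram threshold maximising the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} over all cut points of an `n_bins`
#' equal-width histogram.  When several cuts tie (a plateau across empty
#' bins between well-separated modes), the middle of the plateau is taken —
#' the cut halfway between the modes.
#'
#' @param values numeric vector (at least two distinct finite values).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, a bin edge; pixels strictly above it form the
#'   foreground class.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2 || rng[1] == rng[2])
    stopf("Otsu threshold undefined: input is constant (degenerate histogram)")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[n_bins]
  w1 <- 1 - w0
  # between-class variance at each cut after bin k
  num <- (mt * w0 - m0)^2
  bcv <- num / (w0 * w1)
  bcv[!is.finite(bcv)] <- -Inf
  bcv <- bcv[-n_bins]
  mx <- max(bcv)
  ties <- which(bcv >= mx - 1e-12 * max(1, abs(mx)))
  k <- ties[ceiling(length(ties) / 2)]
  edges[k + 1]
}

#' Canopy mask
#'
#' @param grid logical matrix, TRUE on canopy.
#' @return object of class `canopy_mask` with fields `grid` and `coverage`.
#' @export
canopy_mask <- function(grid) {
  stopifnot(is.logical(grid), is.matrix(grid))
  structure(list(grid = grid, coverage = mean(grid)), class = "canopy_mask")
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("<canopy_mask> %d x %d, coverage %.1f%%\n",
              nrow(x$grid), ncol(x$grid), 100 * x$coverage))
  invisible(x)
}

#' Segment the tea canopy from soil and shadow
#'
#' Thresholds the ExGR grid with Otsu's method (`threshold = "otsu"`) or at a
#' fixed value (common ExGR practice uses 0); pixels above the threshold are
#' canopy.  Otsu assumes a canopy/background mixture: if the class below its
#' cut still has positive mean ExGR — i.e. the "background" is spectrally
#' vegetation, as in a background-free scene — the rule falls back to the
#' physical zero threshold rather than splitting the canopy in two.  The
#' reference-panel region, if recorded on the image, is always excluded from
#' the mask.
#'
#' @param img a calibrated `multispectral_image`.
#' @param threshold `"otsu"` or a numeric cut value.
#' @param n_bins histogram bins for Otsu.
#' @return a [canopy_mask()].
#' @export
segment_canopy <- function(img, threshold = "otsu", n_bins = 256) {
  stopifnot(inherits(img, "multispectral_image"))
  if (img$domain != "reflectance")
    stopf("segment_canopy expects a calibrated (reflectance) image")
  exgr <- compute_exgr(img)
  d <- dim(exgr)
  keep <- rep(TRUE, length(exgr))
  if (!is.null(img$panel_region))
    keep[panel_index(img$panel_region, d)] <- FALSE
  thr <- if (identical(threshold, "otsu")) {
    t_otsu <- otsu_threshold(exgr[keep], n_bins = n_bins)
    below <- exgr[keep][exgr[keep] <= t_otsu]
    if (length(below) && mean(below) > 0) 0 else t_otsu
  } else as.numeric(threshold)
  grid <- exgr > thr
  grid[!keep] <- FALSE
  if (!any(grid))
    stopf("segmentation produced an empty canopy mask; check calibration and input")
  canopy_mask(grid)
}
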