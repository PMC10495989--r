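# The 86-indicator registry: 9 colour values + 7 colour indices, 8 GLCM +
# 7 LBP texture statistics, 5 band reflectances + 50 vegetation indices,
# all computed over the canopy mask of a calibrated image.

COLOR_VALUE_NAMES <- c("r", "g", "b", "h", "s", "v", "L", "a_star", "b_star")
COLOR_INDEX_NAMES <- c("LI", "AI", "AL", "AB", "NDLBI", "NDALI", "NDABI")
GLCM_NAMES <- c("Asm", "Ent", "Con", "Cor", "Mea", "Var", "Hom", "Dis")
LBP_NAMES <- c("mu", "sigma", "S", "K", "G_lbp", "E", "Rs")
VI_NAMES <- c("NDVI", "RVI", "DVI", "EVI", "VOG", "MTCI", "GNDVI", "RDVI",
              "OSAVI", "NLI", "TGI", "ExG", "VARI", "NDRE", "WDRVI", "GRVI",
              "PSRI", "PGR", "CCCI", "MCARI", "BGI", "BI", "GI", "SIPI",
              "PVI", "SAVI", "SR", "GDVI", "RI", "RGI", "BRI", "GMR", "NRI",
              "NGI", "INT", "NBI", "NDI", "WI", "ExR", "ExGR", "CIVE",
              "NGRDI", "VEG", "COM1", "COM2", "RGBVI", "MGRVI", "MExG",
              "NDYI", "GLI")

#' The 86-indicator feature registry
#'
#' Ordered catalogue of every indicator the pipeline computes per sample:
#' 9 colour values (mean r,g,b; h,s,v; CIELab L*,a*,b* — named `L`,
#' `a_star`, `b_star`), 7 colour indices derived from the mean Lab values,
#' 8 GLCM and 7 LBP texture statistics (the LBP energy and smoothness are
#' named `G_lbp` and `Rs` to keep registry names unique against the band
#' means), the 5 band reflectance means (`B,G,R,RE,NIR`) and 50 vegetation
#' indices.
#'
#' @return data.frame with columns `name` and `group`
#'   (`color_value`, `color_index`, `glcm`, `lbp`, `band`, `vi`); 86 rows.
#' @export
feature_registry <- function() {
  data.frame(
    name = c(COLOR_VALUE_NAMES, COLOR_INDEX_NAMES, GLCM_NAMES, LBP_NAMES,
             BAND_NAMES, VI_NAMES),
    group = rep(c("color_value", "color_index", "glcm", "lbp", "band", "vi"),
                c(9, 7, 8, 7, 5, 50)),
    stringsAsFactors = FALSE)
}

#' GLCM / LBP texture configuration
#'
#' @param gray_levels GLCM quantisation levels (>= 2; default 64).
#' @param distance GLCM pixel-pair offset distance (default 1).
#' @param lbp_radius,lbp_neighbors LBP neighbourhood (8 neighbours, radius 1).
#' @return object of class `texture_config`.  The four GLCM angles are fixed
#'   at 0, 45, 90 and 135 degrees.
#' @export
texture_config <- function(gray_levels = 64, distance = 1,
                           lbp_radius = 1, lbp_neighbors = 8) {
  stopifnot(gray_levels >= 2, distance >= 1, lbp_radius == 1, lbp_neighbors == 8)
  structure(list(gray_levels = as.integer(gray_levels),
                 distance = as.integer(distance),
                 angles_deg = c(0, 45, 90, 135),
                 lbp_radius = 1L, lbp_neighbors = 8L),
            class = "texture_config")
}

#' Pseudo-RGB composite of a calibrated image
#'
#' Per-pixel `(r, g, b)` = the R-, G- and B-band reflectances clipped to
#' `[0, 1]`, the colour-space input for HSV and CIELab conversion.
#'
#' @param img a calibrated `multispectral_image`.
#' @return list of matrices `r`, `g`, `b` in `[0, 1]`.
#' @export
compose_pseudo_rgb <- function(img) {
  stopifnot(inherits(img, "multispectral_image"))
  if (img$domain != "reflectance") stopf("pseudo-RGB needs a calibrated image")
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  list(r = clip01(img$bands$R), g = clip01(img$bands$G), b = clip01(img$bands$B))
}

#' Colour features: 9 mean colour values and 7 colour indices
#'
#' Means over the canopy mask of r,g,b (pseudo-RGB), h,s,v (per-pixel HSV,
#' each scaled to `[0,1]`) and CIELab L*,a*,b* (per-pixel conversion treating
#' pseudo-RGB as sRGB with D65 white).  The 7 indices are computed from the
#' *mean* L*,a*,b*: `LI = L-b*`, `AI = b*-a*`, `AL = a*/L`, `AB = a*/(L-b*)`,
#' `NDLBI = (L-b*)/(L+b*)`, `NDALI = (a*-L)/(a*+L)`, `NDABI = (a*-b*)/(a*+b*)`.
#'
#' @param img calibrated `multispectral_image`.
#' @param mask a [canopy_mask()] (or logical matrix).
#' @return named numeric vector of 16 colour features.
#' @export
color_features <- function(img, mask) {
  m <- mask_grid(mask, dim(img))
  if (!any(m)) stopf("empty mask: no canopy pixels for colour features")
  rgb <- compose_pseudo_rgb(img)
  r <- rgb$r[m]; g <- rgb$g[m]; b <- rgb$b[m]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  lab <- grDevices::convertColor(cbind(r, g, b), from = "sRGB", to = "Lab")
  L <- mean(lab[, 1]); a_star <- mean(lab[, 2]); b_star <- mean(lab[, 3])
  vals <- c(r = mean(r), g = mean(g), b = mean(b),
            h = mean(hsv["h", ]), s = mean(hsv["s", ]), v = mean(hsv["v", ]),
            L = L, a_star = a_star, b_star = b_star)
  idx <- c(LI = L - b_star,
           AI = b_star - a_star,
           AL = safe_div(a_star, L, what = "AL"),
           AB = safe_div(a_star, L - b_star, what = "AB"),
           NDLBI = safe_div(L - b_star, L + b_star, what = "NDLBI"),
           NDALI = safe_div(a_star - L, a_star + L, what = "NDALI"),
           NDABI = safe_div(a_star - b_star, a_star + b_star, what = "NDABI"))
  c(vals, idx)
}

mask_grid <- function(mask, d) {
  g <- if (inherits(mask, "canopy_mask")) mask$grid else mask
  stopifnot(is.logical(g))
  if (!is.null(d) && !all(dim(g) == d)) stopf("mask dimensions do not match image")
  g
}

# Grayscale texture channel: luminance of the pseudo-RGB composite.
texture_gray <- function(img) {
  rgb <- compose_pseudo_rgb(img)
  0.299 * rgb$r + 0.587 * rgb$g + 0.114 * rgb$b
}

#' Quantise a grayscale grid for GLCM
#'
#' Equal-width quantisation of `[0, 1]` luminance into `gray_levels` integer
#' levels `0 .. gray_levels-1`.
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param gray_levels number of levels.
#' @return integer matrix of levels.
#' @export
quantize_gray <- function(gray, gray_levels = 64) {
  q <- floor(pmin(pmax(gray, 0), 1) * gray_levels)
  q[q == gray_levels] <- gray_levels - 1L
  storage.mode(q) <- "integer"
  q
}

# offsets (drow, dcol) for the four GLCM angles at distance d
glcm_offsets <- function(d) {
  list(`0` = c(0L, d), `45` = c(-d, d), `90` = c(-d, 0L), `135` = c(-d, -d))
}

#' Grey-level co-occurrence matrix
#'
#' Joint distribution of quantised gray levels for pixel pairs at distance
#' `cfg$distance` along the four angles 0/45/90/135 degrees, accumulated
#' symmetrically (both pair directions) over all angles and normalised to sum
#' 1.  Only pairs with both pixels inside the mask are counted.
#'
#' @param gray integer matrix of levels in `0 .. gray_levels-1`
#'   (see [quantize_gray()]).
#' @param mask logical matrix or [canopy_mask()].
#' @param cfg a [texture_config()].
#' @return `gray_levels x gray_levels` matrix summing to 1.
#' @export
glcm <- function(gray, mask, cfg = texture_config()) {
  L <- cfg$gray_levels
  if (any(gray < 0 | gray >= L)) stopf("gray levels must lie in 0..%d", L - 1)
  m <- mask_grid(mask, dim(gray))
  nr <- nrow(gray); nc <- ncol(gray)
  counts <- matrix(0, L, L)
  for (off in glcm_offsets(cfg$distance)) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- gray[r1, c1, drop = FALSE]
    bq <- gray[r1 + dr, c1 + dc, drop = FALSE]
    ok <- m[r1, c1, drop = FALSE] & m[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    idx <- a[ok] * L + bq[ok] + 1L
    tab <- tabulate(idx, nbins = L * L)
    counts <- counts + matrix(tab, L, L, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetric accumulation (both directions)
  tot <- sum(counts)
  if (tot == 0) stopf("mask admits no valid pixel pairs for the GLCM")
  counts / tot
}

#' Eight GLCM texture statistics
#'
#' For a normalised co-occurrence matrix `P` over levels `i, j = 0..N-1`:
#' angular second moment `Asm`, entropy `Ent` (natural log, 0 log 0 = 0),
#' contrast `Con`, correlation `Cor`, mean `Mea`, variance `Var`,
#' homogeneity `Hom` and dissimilarity `Dis`.
#'
#' @param P normalised GLCM (square, sums to 1).
#' @return named numeric vector of the 8 statistics.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stopf("GLCM must be normalised (sum 1)")
  N <- nrow(P)
  i <- matrix(0:(N - 1), N, N)        # row level
  j <- t(i)                            # col level
  asm <- sum(P^2)
  ent <- -sum(ifelse(P > 0, P * log(P), 0))
  con <- sum(P * (i - j)^2)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum(P * (i - mu_i)^2); var_j <- sum(P * (j - mu_j)^2)
  cor_den <- sqrt(var_i) * sqrt(var_j)
  cor <- if (cor_den < 1e-12) 0 else (sum(i * j * P) - mu_i * mu_j) / cor_den
  hom <- sum(P / (1 + (i - j)^2))
  dis <- sum(P * abs(i - j))
  c(Asm = asm, Ent = ent, Con = con, Cor = cor, Mea = mu_i, Var = var_i,
    Hom = hom, Dis = dis)
}

#' LBP codes of a grayscale grid
#'
#' Classic 8-neighbour, radius-1 local binary pattern: bit `p` is 1 when the
#' p-th neighbour's intensity is greater than or equal to the centre.
#' Codes are produced only for pixels whose full 3x3 neighbourhood lies
#' inside the mask (so values outside the mask can never influence the
#' histogram).
#'
#' @param gray numeric matrix.
#' @param mask logical matrix or [canopy_mask()].
#' @return integer vector of codes in `0..255` (one per eligible pixel).
#' @export
lbp_codes <- function(gray, mask) {
  m <- mask_grid(mask, dim(gray))
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr < 3 || nc < 3) stopf("image too small for radius-1 LBP")
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  center <- gray[ri, ci]
  # neighbours clockwise from east; weight 2^(p-1)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  code <- matrix(0L, length(ri), length(ci))
  valid <- m[ri, ci]
  for (p in seq_along(offs)) {
    dr <- offs[[p]][1]; dc <- offs[[p]][2]
    nb <- gray[ri + dr, ci + dc]
    code <- code + bitwShiftL(as.integer(nb >= center), p - 1L)
    valid <- valid & m[ri + dr, ci + dc]
  }
  as.integer(code[valid])
}

#' Seven LBP histogram statistics
#'
#' From the normalised 256-bin LBP code histogram `P(g)`: mean `mu`,
#' standard deviation `sigma`, third central moment `S`, kurtosis
#' `K = sigma^-4 * sum((g-mu)^4 P)`, energy `G_lbp = sum P^2`, entropy
#' `E = -sum P log2 P` (bits) and relative smoothness
#' `Rs = 1 - 1/(1+sigma^2)`.
#'
#' @param gray numeric matrix (unquantised grayscale).
#' @param mask logical matrix or [canopy_mask()].
#' @return named numeric vector of the 7 statistics.
#' @export
lbp_features <- function(gray, mask) {
  codes <- lbp_codes(gray, mask)
  if (length(codes) == 0) stopf("mask admits no interior pixels for LBP")
  P <- tabulate(codes + 1L, nbins = 256) / length(codes)
  g <- 0:255
  mu <- sum(g * P)
  v <- sum((g - mu)^2 * P)
  sigma <- sqrt(v)
  S <- sum((g - mu)^3 * P)
  K <- if (sigma < 1e-12) 0 else sum((g - mu)^4 * P) / sigma^4
  G <- sum(P^2)
  E <- -sum(ifelse(P > 0, P * log2(P), 0))
  Rs <- 1 - 1 / (1 + v)
  c(mu = mu, sigma = sigma, S = S, K = K, G_lbp = G, E = E, Rs = Rs)
}

#' Masked mean reflectance per band
#'
#' @param img calibrated `multispectral_image`.
#' @param mask logical matrix or [canopy_mask()].
#' @return named numeric vector, order B,G,R,RE,NIR.
#' @export
band_means <- function(img, mask) {
  m <- mask_grid(mask, dim(img))
  if (!any(m)) stopf("empty mask: no canopy pixels for band means")
  vapply(img$bands, function(bnd) mean(bnd[m]), numeric(1))
}

#' The 50 vegetation indices
#'
#' Evaluates the registry's vegetation-index formulas from the five masked
#' mean band reflectances (B,G,R,RE,NIR).  Indices with vanishing
#' denominators are set to 0 under the NaN policy.
#'
#' @param bandvals named numeric length-5 vector (B,G,R,RE,NIR).
#' @return named numeric vector of 50 indices.
#' @export
vegetation_indices <- function(bandvals) {
  stopifnot(all(BAND_NAMES %in% names(bandvals)))
  B <- bandvals[["B"]]; G <- bandvals[["G"]]; R <- bandvals[["R"]]
  RE <- bandvals[["RE"]]; NIR <- bandvals[["NIR"]]
  sd_ <- function(n, d, w) safe_div(n, d, what = w)
  ExG <- 2 * G - R - B
  ExR <- 1.4 * R - G
  CIVE <- 0.441 * R - 0.811 * G + 0.385 * B + 18.78745
  VEG <- sd_(G, R^(2 / 3) * B^(1 / 3), "VEG")
  NDVIv <- sd_(NIR - R, NIR + R, "NDVI")
  NDREv <- sd_(NIR - RE, NIR + RE, "NDRE")
  out <- c(
    NDVI = NDVIv,
    RVI = sd_(NIR, R, "RVI"),
    DVI = NIR - R,
    EVI = sd_(2.5 * (B - G), B + 6 * G - 7.5 * R + 1, "EVI"),
    VOG = sd_(B - G, R + RE, "VOG"),
    MTCI = sd_(B - G, R - RE, "MTCI"),
    GNDVI = sd_(NIR - G, NIR + G, "GNDVI"),
    RDVI = sd_(NIR - RE, NIR + RE, "RDVI"),
    OSAVI = sd_(1.16 * (NIR - RE), NIR + RE + 0.16, "OSAVI"),
    NLI = sd_(NIR^2 - RE, NIR^2 + RE, "NLI"),
    TGI = G - 0.39 * R - 0.61 * B,
    ExG = ExG,
    VARI = sd_(R - G, G + R - B, "VARI"),
    NDRE = NDREv,
    WDRVI = sd_(0.1 * NIR - R, 0.1 * NIR + R, "WDRVI"),
    GRVI = sd_(G - R, G + R, "GRVI"),
    PSRI = sd_(R - G, RE, "PSRI"),
    PGR = sd_(R, G, "PGR"),
    CCCI = sd_(NDREv, NDVIv, "CCCI"),
    MCARI = sd_((RE - R - 0.2 * (RE - G)) * RE, R, "MCARI"),
    BGI = sd_(B, G, "BGI"),
    BI = (NIR + R + G) / sqrt(3),
    GI = sd_(G, R, "GI"),
    SIPI = sd_(NIR - B, NIR + R, "SIPI"),
    PVI = (1 / sqrt(1.17^2 + 1)) * (NIR - 1.17 * R - 3.37),
    SAVI = sd_((NIR - R) * 1.5, NIR + R + 0.5, "SAVI"),
    SR = sd_(NIR, R, "SR"),
    GDVI = NIR - G,
    RI = sd_(RE, R, "RI"),
    RGI = sd_(R, G, "RGI"),
    BRI = sd_(B, R, "BRI"),
    GMR = G - R,
    NRI = sd_(R, R + G + B, "NRI"),
    NGI = sd_(G, R + G + B, "NGI"),
    INT = (R + G + B) / 3,
    NBI = sd_(B, R + G + B, "NBI"),
    NDI = sd_(128 * (G - R), R + G, "NDI"),
    WI = sd_(G - B, abs(R - G), "WI"),
    ExR = ExR,
    ExGR = ExG - ExR,
    CIVE = CIVE,
    NGRDI = sd_(G - R, G + R, "NGRDI"),
    VEG = VEG,
    COM1 = ExG + CIVE + (ExG - ExR) + VEG,
    COM2 = 0.36 * ExG + 0.47 * CIVE + 0.17 * VEG,
    RGBVI = sd_(G^2 - R * B, G^2 + R * B, "RGBVI"),
    MGRVI = sd_(G^2 - R^2, G^2 + R^2, "MGRVI"),
    MExG = 1.262 * G - 0.884 * R - 0.311 * B,
    NDYI = sd_(G - B, G + B, "NDYI"),
    GLI = sd_(2 * G - R - B, 2 * G + R + B, "GLI"))
  out[VI_NAMES]
}

#' Extract all 86 indicators for one masked image
#'
#' Computes, in registry order: the 16 colour features, the 8 GLCM statistics
#' (on luminance quantised to `cfg$gray_levels`), the 7 LBP statistics (on
#' unquantised luminance), the 5 band reflectance means and the 50 vegetation
#' indices (from the band means).  Deterministic; only pixels inside the mask
#' influence the result.
#'
#' @param img calibrated `multispectral_image`.
#' @param mask a [canopy_mask()] or logical matrix.
#' @param cfg a [texture_config()].
#' @return named numeric vector of length 86 (registry order).
#' @export
extract_all <- function(img, mask, cfg = texture_config()) {
  gray <- texture_gray(img)
  P <- glcm(quantize_gray(gray, cfg$gray_levels), mask, cfg)
  bm <- band_means(img, mask)
  out <- c(color_features(img, mask),
           glcm_features(P),
           lbp_features(gray, mask),
           bm,
           vegetation_indices(bm))
  reg <- feature_registry()$name
  stopifnot(identical(names(out), reg))
  out
}

#' Extract the feature table of a whole dataset
#'
#' Calibrates each image against the reference panel, segments the canopy
#' (ExGR + Otsu) and extracts the 86 indicators.  With
#' `use_truth_masks = TRUE` the generator's ground-truth masks are used
#' instead of segmentation.
#'
#' @param dataset a `synthetic_dataset` (or list with `images`, `labels`,
#'   `germination_labels`, `panel`).
#' @param cfg a [texture_config()].
#' @param use_truth_masks logical.
#' @param threshold segmentation threshold rule (see [segment_canopy()]).
#' @return a [feature_table()] with 86 indicator columns.
#' @export
extract_features <- function(dataset, cfg = texture_config(),
                             use_truth_masks = FALSE, threshold = "otsu") {
  n <- length(dataset$images)
  reg <- feature_registry()$name
  M <- matrix(NA_real_, n, length(reg), dimnames = list(NULL, reg))
  for (i in seq_len(n)) {
    img <- calibrate_reflectance(register_bands(dataset$images[[i]]),
                                 dataset$panel)
    mask <- if (use_truth_masks) canopy_mask(dataset$truth_masks[[i]])
      else segment_canopy(img, threshold = threshold)
    M[i, ] <- extract_all(img, mask, cfg)
  }
  feature_table(M, dataset$labels, dataset$germination_labels %||% NA)
}
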