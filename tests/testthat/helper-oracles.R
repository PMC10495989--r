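# Independent brute-force oracles and constructed fixtures shared across
# test files.  Each oracle is a naive reimplementation, kept deliberately
# separate from the package's code paths.

# naive exhaustive scan over every histogram cut (independent oracle)
otsu_brute <- function(values, n_bins = 256) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  bcv <- rep(-Inf, n_bins - 1)
  for (k in 1:(n_bins - 1)) {
    lo <- bin <= k
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- mean(centers[bin[lo]]); m1 <- mean(centers[bin[!lo]])
    bcv[k] <- w0 * w1 * (m0 - m1)^2
  }
  mx <- max(bcv)
  ties <- which(bcv >= mx - 1e-12 * max(1, abs(mx)))
  edges[ties[ceiling(length(ties) / 2)] + 1]
}

# brute-force GLCM: enumerate every pixel pair at the four offsets
glcm_brute <- function(gray, mask, L, d = 1) {
  counts <- matrix(0, L, L)
  offs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  nr <- nrow(gray); nc <- ncol(gray)
  for (off in offs) for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, cc] || !mask[r2, c2]) next
    i <- gray[r, cc] + 1; j <- gray[r2, c2] + 1
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1   # symmetric accumulation
  }
  counts / sum(counts)
}

# naive double-loop GLCM statistics (0-based levels)
glcm_features_brute <- function(P) {
  N <- nrow(P)
  asm <- ent <- con <- mea <- hom <- dis <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    asm <- asm + p^2
    if (p > 0) ent <- ent - p * log(p)
    con <- con + p * (i - j)^2
    mea <- mea + i * p
    hom <- hom + p / (1 + (i - j)^2)
    dis <- dis + p * abs(i - j)
  }
  mu_i <- mu_j <- v_i <- v_j <- cr <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]; mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    v_i <- v_i + p * (i - mu_i)^2; v_j <- v_j + p * (j - mu_j)^2
    cr <- cr + i * j * p
  }
  c(Asm = asm, Ent = ent, Con = con,
    Cor = (cr - mu_i * mu_j) / (sqrt(v_i) * sqrt(v_j)),
    Mea = mu_i, Var = v_i, Hom = hom, Dis = dis)
}

# naive LBP: per-pixel code then histogram statistics
lbp_brute <- function(gray, mask) {
  nr <- nrow(gray); nc <- ncol(gray)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  codes <- integer(0)
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1)) {
    ok <- mask[r, cc]
    code <- 0L
    for (p in 1:8) {
      r2 <- r + offs[[p]][1]; c2 <- cc + offs[[p]][2]
      ok <- ok && mask[r2, c2]
      if (gray[r2, c2] >= gray[r, cc]) code <- code + 2L^(p - 1L)
    }
    if (ok) codes <- c(codes, code)
  }
  P <- tabulate(codes + 1L, nbins = 256) / length(codes)
  g <- 0:255
  mu <- sum(g * P); v <- sum((g - mu)^2 * P); sigma <- sqrt(v)
  c(mu = mu, sigma = sigma, S = sum((g - mu)^3 * P),
    K = if (sigma == 0) 0 else sum((g - mu)^4 * P) / sigma^4,
    G_lbp = sum(P^2),
    E = -sum(ifelse(P > 0, P * log2(P), 0)),
    Rs = 1 - 1 / (1 + v))
}

# independently coded vegetation-index table (same printed formulas,
# written from scratch for redundancy)
vi_brute <- function(v) {
  B <- v[1]; G <- v[2]; R <- v[3]; RE <- v[4]; NIR <- v[5]
  dv <- function(n, d) if (abs(d) < 1e-12) 0 else n / d
  ExG <- 2 * G - R - B; ExR <- 1.4 * R - G
  CIVE <- 0.441 * R - 0.811 * G + 0.385 * B + 18.78745
  VEG <- dv(G, R^(2 / 3) * B^(1 / 3))
  ndvi <- dv(NIR - R, NIR + R); ndre <- dv(NIR - RE, NIR + RE)
  c(NDVI = ndvi, RVI = dv(NIR, R), DVI = NIR - R,
    EVI = dv(2.5 * (B - G), B + 6 * G - 7.5 * R + 1),
    VOG = dv(B - G, R + RE), MTCI = dv(B - G, R - RE),
    GNDVI = dv(NIR - G, NIR + G), RDVI = dv(NIR - RE, NIR + RE),
    OSAVI = dv(1.16 * (NIR - RE), NIR + RE + 0.16),
    NLI = dv(NIR^2 - RE, NIR^2 + RE), TGI = G - 0.39 * R - 0.61 * B,
    ExG = ExG, VARI = dv(R - G, G + R - B), NDRE = ndre,
    WDRVI = dv(0.1 * NIR - R, 0.1 * NIR + R), GRVI = dv(G - R, G + R),
    PSRI = dv(R - G, RE), PGR = dv(R, G), CCCI = dv(ndre, ndvi),
    MCARI = dv((RE - R - 0.2 * (RE - G)) * RE, R), BGI = dv(B, G),
    BI = (NIR + R + G) / sqrt(3), GI = dv(G, R),
    SIPI = dv(NIR - B, NIR + R),
    PVI = (1 / sqrt(1.17^2 + 1)) * (NIR - 1.17 * R - 3.37),
    SAVI = dv((NIR - R) * 1.5, NIR + R + 0.5), SR = dv(NIR, R),
    GDVI = NIR - G, RI = dv(RE, R), RGI = dv(R, G), BRI = dv(B, R),
    GMR = G - R, NRI = dv(R, R + G + B), NGI = dv(G, R + G + B),
    INT = (R + G + B) / 3, NBI = dv(B, R + G + B),
    NDI = dv(128 * (G - R), R + G), WI = dv(G - B, abs(R - G)),
    ExR = ExR, ExGR = ExG - ExR, CIVE = CIVE,
    NGRDI = dv(G - R, G + R), VEG = VEG,
    COM1 = ExG + CIVE + (ExG - ExR) + VEG,
    COM2 = 0.36 * ExG + 0.47 * CIVE + 0.17 * VEG,
    RGBVI = dv(G^2 - R * B, G^2 + R * B), MGRVI = dv(G^2 - R^2, G^2 + R^2),
    MExG = 1.262 * G - 0.884 * R - 0.311 * B, NDYI = dv(G - B, G + B),
    GLI = dv(2 * G - R - B, 2 * G + R + B))
}

# stage-structured cultivar-mean fixture: 18 cultivars (5/5/8), stage
# centres spaced `spacing` within-stage sds apart in a 15-variable space
stage_means_fixture <- function(spacing = 6, sd_within = 1, seed = 1) {
  vars <- printed_germination_model()$variables
  stages <- rep(c("early", "mesophytic", "late"), c(5, 5, 8))
  set.seed(seed)
  centers <- matrix(rnorm(3 * length(vars)), 3, length(vars))
  centers <- centers / min(dist(centers)) * spacing * sd_within
  X <- centers[match(stages, c("early", "mesophytic", "late")), ] +
    matrix(rnorm(18 * length(vars), 0, sd_within), 18)
  colnames(X) <- vars
  rownames(X) <- sprintf("cv%02d", 1:18)
  list(X = X, stages = stages)
}
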