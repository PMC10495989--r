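# Feature screening: uninformative variable elimination (UVE) driven by
# PLS2 regression-coefficient reliability, LASSO with cross-validated
# lambda, the UVE -> LASSO cascade, and VIP importance scores.

# ---- PLS2 (SIMPLS, de Jong 1993) -------------------------------------------
# Multi-response partial least squares on autoscaled X and centred Y.
# Returns projection weights R (p x A), loadings, scores and the coefficient
# matrix B on the autoscaled/centred scale.
pls2_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  sx[sx < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- colMeans(Y)
  Ys <- sweep(Y, 2, my)
  A <- min(ncomp, p, n - 1)
  S <- crossprod(Xs, Ys)
  Rw <- matrix(0, p, A); TT <- matrix(0, n, A)
  P <- matrix(0, p, A); Q <- matrix(0, K, A); V <- matrix(0, p, A)
  for (a in seq_len(A)) {
    r <- svd(S, nu = 1, nv = 0)$u[, 1]
    t_ <- Xs %*% r
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    if (nt < 1e-12) { A <- a - 1L; break }
    t_ <- t_ / nt; r <- r / nt
    p_ <- crossprod(Xs, t_)
    q_ <- crossprod(Ys, t_)
    v <- p_
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    Rw[, a] <- r; TT[, a] <- t_; P[, a] <- p_; Q[, a] <- q_; V[, a] <- v
  }
  if (A < 1) stopf("PLS fit degenerate: no usable components")
  Rw <- Rw[, 1:A, drop = FALSE]; TT <- TT[, 1:A, drop = FALSE]
  P <- P[, 1:A, drop = FALSE]; Q <- Q[, 1:A, drop = FALSE]
  B <- Rw %*% t(Q)   # coefficients on the autoscaled-X / centred-Y scale
  list(ncomp = A, weights = Rw, scores = TT, x_loadings = P, y_loadings = Q,
       coef = B, x_center = mx, x_scale = sx, y_center = my)
}

pls2_predict <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$x_center), 2, fit$x_scale, "/")
  sweep(Xs %*% fit$coef, 2, fit$y_center, "+")
}

one_hot <- function(labels) {
  f <- factor(labels)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL; attr(Y, "contrasts") <- NULL
  Y
}

# Cross-validated choice of the PLS component count (mean squared Y error),
# capped at `max_comp`.
pls2_choose_ncomp <- function(X, Y, max_comp = 10, k = 5, seed = 1) {
  n <- nrow(X)
  max_comp <- min(max_comp, ncol(X), n - 2)
  folds <- stratified_folds(max.col(Y), k, seed)
  err <- numeric(max_comp)
  for (fold in seq_len(k)) {
    te <- folds == fold
    if (!any(te) || sum(!te) < 3) next
    fit <- pls2_fit(X[!te, , drop = FALSE], Y[!te, , drop = FALSE], max_comp)
    Xs <- sweep(sweep(X[te, , drop = FALSE], 2, fit$x_center), 2, fit$x_scale, "/")
    for (a in seq_len(max_comp)) {
      aa <- min(a, fit$ncomp)
      Ba <- fit$weights[, 1:aa, drop = FALSE] %*%
        t(fit$y_loadings[, 1:aa, drop = FALSE])
      pred <- sweep(Xs %*% Ba, 2, fit$y_center, "+")
      err[a] <- err[a] + sum((Y[te, , drop = FALSE] - pred)^2)
    }
  }
  which.min(err)
}

#' Uninformative variable elimination (UVE)
#'
#' Appends one standard-Gaussian noise variable per real variable, fits PLS2
#' (one-hot class response) on resampled subsets (leave-one-out when
#' `n <= 200`, otherwise 20 repeats of 5-fold Monte-Carlo subsets), and
#' scores each variable by the reliability of its regression coefficient,
#' \eqn{c_j = mean(b_j)/sd(b_j)} over resamples (the maximum absolute value
#' over response columns).  Real variables whose |reliability| exceeds the
#' largest |reliability| among the noise variables are retained.
#'
#' @param table a [feature_table()] with >= 2 classes.
#' @param n_components PLS components; `NULL` selects by 5-fold CV (cap 10).
#' @param n_splits Monte-Carlo repeats when `n > 200` (ignored for LOO).
#' @param seed RNG seed (noise draw + resampling).
#' @param cutoff_multiplier retain variables with
#'   `|reliability| > cutoff_multiplier * max |noise reliability|`.
#' @return object of class `uve_result`: `reliability`, `cutoff`, `retained`,
#'   `n_components`, `n_noise`.
#' @export
uve_select <- function(table, n_components = NULL, n_splits = 20, seed = 1L,
                       cutoff_multiplier = 1) {
  X <- feature_matrix(table)
  labels <- table$cultivar
  if (length(unique(labels)) < 2) stopf("UVE needs at least 2 classes")
  Y <- one_hot(labels)
  n <- nrow(X); p <- ncol(X)
  rng <- local_rng(seed)
  noise <- matrix(rng$rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf(".uve_noise_%03d", seq_len(p))))
  Xa <- cbind(X, noise)
  if (is.null(n_components))
    n_components <- pls2_choose_ncomp(Xa, Y, max_comp = 10, k = 5,
                                      seed = rng$child_seed())
  n_components <- min(n_components, ncol(Xa) - 1, n - 2)

  resamples <- if (n <= 200) {
    lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  } else {
    lapply(seq_len(n_splits), function(i) {
      keep <- rng$sample_int(n, size = ceiling(0.8 * n))
      sort(keep)
    })
  }
  K <- ncol(Y)
  coefs <- array(NA_real_, c(length(resamples), ncol(Xa), K))
  for (i in seq_along(resamples)) {
    idx <- resamples[[i]]
    fit <- pls2_fit(Xa[idx, , drop = FALSE], Y[idx, , drop = FALSE], n_components)
    coefs[i, , ] <- fit$coef
  }
  mean_b <- apply(coefs, c(2, 3), mean)
  sd_b <- apply(coefs, c(2, 3), stats::sd)
  rel <- mean_b / sd_b
  zero_sd <- sd_b < 1e-300
  if (any(zero_sd)) {
    warning("zero coefficient spread for some variables; reliability set to +Inf",
            call. = FALSE)
    rel[zero_sd] <- sign(mean_b[zero_sd]) * Inf
  }
  reliability <- apply(abs(rel), 1, max)
  names(reliability) <- colnames(Xa)
  real <- seq_len(p)
  cutoff <- cutoff_multiplier * max(reliability[-real])
  retained <- colnames(X)[reliability[real] > cutoff]
  structure(list(reliability = reliability[real], cutoff = cutoff,
                 noise_reliability = reliability[-real],
                 retained = retained, n_components = n_components,
                 n_noise = p, seed = seed),
            class = "uve_result")
}

#' @export
print.uve_result <- function(x, ...) {
  cat(sprintf("<uve_result> %d/%d variables retained (cutoff %.3f, %d comps)\n",
              length(x$retained), length(x$reliability), x$cutoff,
              x$n_components))
  invisible(x)
}

#' LASSO variable selection with cross-validated lambda
#'
#' Multi-response (one-hot class indicator) LASSO on internally standardised
#' features over a log-spaced lambda path descending three decades from
#' the smallest lambda that zeroes every coefficient; the optimal lambda
#' minimises the mean cross-validated squared error (`rule = "min"`; the
#' one-standard-error rule is available).  Retained variables are those with
#' a nonzero coefficient in any response column at the optimum.
#'
#' @param table a [feature_table()].
#' @param n_folds CV folds (>= 2).
#' @param seed RNG seed (fold assignment).
#' @param rule `"min"` or `"1se"`.
#' @param standardize standardise features inside the fit (default TRUE;
#'   FALSE only makes sense for pre-scaled designs, e.g. orthonormal test
#'   fixtures).
#' @param lambda optional explicit descending lambda grid (default: 100
#'   log-spaced values descending three decades from lambda_max).
#' @param thresh coordinate-descent convergence threshold (tighten for
#'   closed-form comparisons).
#' @return object of class `lasso_result`: `lambda_grid`, `coef_path`
#'   (list of p x K matrices), `cv_error` (mean, sd), `lambda_opt`,
#'   `retained`.
#' @details Two-class tables are fit with a single 0/1 gaussian response (a
#'   two-column one-hot indicator is collinear); three or more classes use
#'   glmnet's multi-response gaussian family, and a variable is retained if
#'   any response column keeps a nonzero coefficient at the optimum.
#' @export
lasso_select <- function(table, n_folds = 5, seed = 1L, rule = c("min", "1se"),
                         standardize = TRUE, lambda = NULL, thresh = 1e-7) {
  rule <- match.arg(rule)
  if (n_folds < 2) stopf("n_folds must be >= 2")
  X <- feature_matrix(table)
  classes <- sort(unique(table$cultivar))
  two_class <- length(classes) == 2
  Y <- if (two_class) as.numeric(table$cultivar == classes[2])
    else one_hot(table$cultivar)
  foldid <- stratified_folds(table$cultivar, n_folds, seed)
  fam <- if (two_class) "gaussian" else "mgaussian"
  args <- list(x = X, y = Y, family = fam, alpha = 1,
               standardize = standardize, foldid = foldid, thresh = thresh)
  if (is.null(lambda)) {
    args$nlambda <- 100; args$lambda.min.ratio <- 1e-3
  } else args$lambda <- lambda
  cvfit <- do.call(glmnet::cv.glmnet, args)
  lambda_opt <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  cf <- stats::coef(cvfit, s = lambda_opt)
  coef_at <- if (two_class) as.matrix(cf)[-1, , drop = FALSE]
    else do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1, 1]))
  retained <- rownames(coef_at)[rowSums(abs(coef_at) > 0) > 0]
  beta <- cvfit$glmnet.fit$beta
  path <- lapply(seq_along(cvfit$lambda), function(i) {
    if (two_class) as.matrix(beta[, i, drop = FALSE])
    else do.call(cbind, lapply(beta, function(b) as.matrix(b[, i, drop = FALSE])))
  })
  structure(list(lambda_grid = cvfit$lambda, coef_path = path,
                 cv_error = list(mean = cvfit$cvm, sd = cvfit$cvsd),
                 lambda_opt = lambda_opt, coef_opt = coef_at,
                 retained = retained, rule = rule, seed = seed,
                 fit = cvfit, x = X, y = Y),
            class = "lasso_result")
}

#' Coefficients of a LASSO path at an arbitrary lambda
#'
#' @param result a `lasso_result`.
#' @param lambda penalty value (the model is re-solved exactly at this
#'   lambda, not interpolated).
#' @return p x K coefficient matrix (no intercept row).
#' @export
lasso_coef_at <- function(result, lambda) {
  cf <- stats::coef(result$fit$glmnet.fit, s = lambda, exact = TRUE,
                    x = result$x, y = result$y)
  if (is.list(cf)) do.call(cbind, lapply(cf, function(m) as.matrix(m)[-1, 1]))
  else as.matrix(cf)[-1, , drop = FALSE]
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> %d variables at lambda = %.4g (%s rule)\n",
              length(x$retained), x$lambda_opt, x$rule))
  invisible(x)
}

#' UVE -> LASSO cascade with VIP scores
#'
#' Runs [uve_select()], restricts the table to the UVE survivors, runs
#' [lasso_select()] on them, and scores the final variables with
#' [vip_scores()].  The report records the full cascade of counts
#' (input -> after UVE -> after LASSO).
#'
#' @param table a [feature_table()].
#' @param n_components,n_splits,cutoff_multiplier passed to [uve_select()].
#' @param n_folds,rule passed to [lasso_select()].
#' @param seed master seed (children derived for each stage).
#' @return object of class `selection_report`: `n_input`, `n_after_uve`,
#'   `n_after_lasso`, `final_names`, `vip`, plus the two stage results.
#' @export
uve_lasso <- function(table, n_components = NULL, n_splits = 20, n_folds = 5,
                      cutoff_multiplier = 1, rule = "min", seed = 1L) {
  rng <- local_rng(seed)
  uve <- uve_select(table, n_components = n_components, n_splits = n_splits,
                    seed = rng$child_seed(),
                    cutoff_multiplier = cutoff_multiplier)
  if (length(uve$retained) == 0)
    stopf(paste("UVE eliminated every variable; relax the cutoff",
                "(cutoff_multiplier < 1) or check the data"))
  sub <- select_features(table, uve$retained)
  las <- lasso_select(sub, n_folds = n_folds, seed = rng$child_seed(),
                      rule = rule)
  final <- las$retained
  vip <- if (length(final) >= 1)
    vip_scores(table, final, n_components = min(length(final) - 1L, 10L))
    else numeric(0)
  structure(list(n_input = length(feature_names(table)),
                 n_after_uve = length(uve$retained),
                 n_after_lasso = length(final),
                 final_names = final, vip = vip,
                 uve = uve, lasso = las, seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> cascade %d -> %d -> %d indicators\n",
              x$n_input, x$n_after_uve, x$n_after_lasso))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Fits PLS2 (one-hot class response) on the listed variables and scores each
#' as \eqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}},
#' where \eqn{SS_a} is the Y variance explained by component a.  By
#' construction the squared scores average to 1 over variables.
#'
#' @param table a [feature_table()].
#' @param variables indicator names to score.
#' @param n_components PLS components (>= 1).
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(table, variables = feature_names(table),
                       n_components = 2) {
  X <- feature_matrix(table, variables)
  Y <- one_hot(table$cultivar)
  n_components <- max(1L, min(n_components, ncol(X), nrow(X) - 2L))
  fit <- pls2_fit(X, Y, n_components)
  W <- fit$weights
  ss <- colSums(fit$y_loadings^2)   # scores are unit-norm: SS_a = ||q_a||^2
  w2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- ncol(X)
  vip <- sqrt(p * as.vector(w2 %*% ss) / sum(ss))
  stats::setNames(vip, colnames(X))
}
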