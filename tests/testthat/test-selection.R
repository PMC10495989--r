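# UVE-PLS screening, LASSO with cross-validated lambda, the cascade and
# VIP importance scores.

test_that("UVE keeps planted signal and discards appended noise", {
  for (s in 1:2) {
    tab <- generate_feature_table(3, 50, 10, class_separation = 6,
                                  n_noise_features = 40, seed = s)
    res <- uve_select(tab, seed = s)
    informative <- names(which(attr(tab, "informative")))
    expect_true(all(informative %in% res$retained))
    noise_kept <- sum(!(res$retained %in% informative))
    expect_lte(noise_kept, 4)    # >= 90% of the 40 noise columns eliminated
    expect_true(all(res$reliability[res$retained] > res$cutoff))
  }
})

test_that("UVE on pure noise retains (almost) nothing", {
  tab <- generate_feature_table(3, 40, 10, class_separation = 0,
                                n_noise_features = 40, seed = 9)
  res <- uve_select(tab, n_components = 3, seed = 9)
  expect_lte(length(res$retained), ceiling(0.05 * 50))
})

test_that("duplicating a retained variable keeps both copies", {
  tab <- generate_feature_table(3, 40, 5, class_separation = 6,
                                n_noise_features = 10, seed = 3)
  X <- feature_matrix(tab)
  X2 <- cbind(X, inf_copy = X[, "inf_01"])
  tab2 <- feature_table(X2, tab$cultivar)
  res <- uve_select(tab2, n_components = 4, seed = 3)
  expect_true(all(c("inf_01", "inf_copy") %in% res$retained))
})

test_that("UVE is deterministic under its seed", {
  tab <- generate_feature_table(3, 30, 5, 4, 10, seed = 6)
  r1 <- uve_select(tab, n_components = 3, seed = 11)
  r2 <- uve_select(tab, n_components = 3, seed = 11)
  expect_identical(r1$reliability, r2$reliability)
  expect_identical(r1$retained, r2$retained)
})

# orthonormal design with zero-mean columns: Helmert contrasts rescaled so
# that crossprod(X) = n * I
orthonormal_design <- function(n, p) {
  H <- stats::contr.helmert(n)[, 1:p, drop = FALSE]
  sweep(H, 2, sqrt(colSums(H^2) / n), "/")
}

test_that("LASSO matches the soft-threshold closed form on orthonormal designs", {
  n <- 40; p <- 6
  X <- orthonormal_design(n, p)
  colnames(X) <- sprintf("x%02d", 1:p)
  set.seed(2)
  y <- as.numeric(runif(n) > 0.5)
  y[1] <- 0; y[2] <- 1                      # both classes present
  tab <- feature_table(X, ifelse(y > 0, "b", "a"))  # class "b" = y 1
  res <- lasso_select(tab, n_folds = 4, seed = 2, standardize = FALSE,
                      thresh = 1e-12)
  z <- crossprod(X, y - mean(y)) / n
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  for (l in c(0.5, 0.2, 0.05) * max(abs(z))) {
    got <- lasso_coef_at(res, l)
    expect_equal(unname(got[, 1]), unname(soft(z, l)[, 1]), tolerance = 1e-6)
  }
  # support is nested along the path
  supports <- lapply(res$coef_path, function(B) which(rowSums(abs(B)) > 0))
  for (i in seq_along(supports)[-1])
    expect_true(all(supports[[i - 1]] %in% supports[[i]]))
})

test_that("at and above lambda_max every coefficient is zero", {
  tab <- generate_feature_table(3, 30, 5, 4, 5, seed = 8)
  res <- lasso_select(tab, seed = 8)
  expect_true(all(res$coef_path[[1]] == 0))
  expect_equal(res$lambda_grid, sort(res$lambda_grid, decreasing = TRUE))
})

test_that("the penalty-free limit recovers least squares", {
  n <- 50; p <- 4
  set.seed(14)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- as.numeric(X[, 1] - X[, 2] + rnorm(n, 0, 0.3) > 0)
  y[1:2] <- c(0, 1)
  tab <- feature_table(X, ifelse(y > 0, "b", "a"))
  grid <- c(10^seq(0, -4, length.out = 40), 0)
  res <- lasso_select(tab, seed = 14, lambda = grid, thresh = 1e-12)
  got <- lasso_coef_at(res, 0)
  ols <- stats::coef(stats::lm(y ~ X))[-1]
  expect_equal(unname(got[, 1]), unname(ols), tolerance = 1e-6)
})

test_that("the UVE -> LASSO cascade is monotone and recovers the signal", {
  for (s in 1:3) {
    # 12 classes: the class-mean space has rank >= the 10 informative
    # features, so none of them is linearly redundant for the LASSO
    tab <- generate_feature_table(12, 20, 10, class_separation = 6,
                                  n_noise_features = 40, seed = s)
    rep <- uve_lasso(tab, seed = s)
    expect_lte(rep$n_after_lasso, rep$n_after_uve)
    expect_lte(rep$n_after_uve, rep$n_input)
    informative <- names(which(attr(tab, "informative")))
    expect_gte(sum(informative %in% rep$final_names), length(informative) - 1)
    expect_lte(sum(!(rep$final_names %in% informative)), 2)
  }
})

test_that("an 86-column table yields a strictly decreasing cascade", {
  ft <- shared_features()
  rep <- uve_lasso(ft, seed = 7)
  expect_equal(rep$n_input, 86)
  expect_lt(rep$n_after_uve, rep$n_input)
  expect_lt(rep$n_after_lasso, rep$n_after_uve)
  expect_gte(rep$n_after_lasso, 1)
  .fixtures$selection <- rep   # reused by the end-to-end checks
})

test_that("VIP scores satisfy the unit mean-square identity", {
  tab <- generate_feature_table(3, 30, 6, 4, 6, seed = 4)
  v <- vip_scores(tab, n_components = 4)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)

  # a single informative variable among noise attains the maximum VIP
  tab1 <- generate_feature_table(3, 40, 1, class_separation = 8,
                                 n_noise_features = 12, seed = 5)
  v1 <- vip_scores(tab1, n_components = 2)
  expect_equal(names(which.max(v1)), "inf_01")
  expect_gt(max(v1), 1)
})

test_that("VIP is invariant to sample order", {
  tab <- generate_feature_table(3, 30, 5, 4, 5, seed = 13)
  v <- vip_scores(tab, n_components = 3)
  df <- as.data.frame(tab)
  set.seed(1); perm <- sample(nrow(df))
  tab_p <- feature_table(df[perm, feature_names(tab)], df$cultivar[perm])
  v_p <- vip_scores(tab_p, n_components = 3)
  expect_equal(v, v_p, tolerance = 1e-10)
})
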