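# Stratified splitting, SVM training/evaluation and the ablation studies.

test_that("stratified splits honour the ratios with largest-remainder
           rounding", {
  tab <- generate_feature_table(1, 100, 3, 0, seed = 1)
  sp <- stratified_split(tab, c(6, 2, 2), seed = 1)
  expect_equal(as.vector(table(sp$assignment)), c(60, 20, 20))

  tab18 <- generate_feature_table(18, 10, 3, 0, seed = 2)
  sp18 <- stratified_split(tab18, c(6, 2, 2), seed = 2)
  expect_true(all(sp18$counts == matrix(c(6, 2, 2), 18, 3, byrow = TRUE)))
  # disjoint and exhaustive by construction of the factor
  expect_false(anyNA(sp18$assignment))

  sp18b <- stratified_split(tab18, c(6, 2, 2), seed = 2)
  expect_identical(sp18$assignment, sp18b$assignment)

  small <- generate_feature_table(2, 4, 3, 0, seed = 3)
  expect_error(stratified_split(small), "only 4 samples")
})

test_that("odd class sizes follow largest-remainder rounding", {
  # 7 x (0.6, 0.2, 0.2) = (4.2, 1.4, 1.4): the spare sample goes to the
  # largest remainder (test wins the remainder tie over validation)
  tab <- generate_feature_table(1, 7, 2, 0, seed = 4)
  sp <- stratified_split(tab, c(6, 2, 2), seed = 4, min_per_class = 5)
  expect_equal(as.vector(table(sp$assignment)), c(4, 2, 1))
})

test_that("a separable toy problem trains to perfect accuracy", {
  tab <- generate_feature_table(2, 20, 2, class_separation = 10, seed = 5)
  model <- train_svm(tab, c = 10)
  pred <- predict(model, tab)
  expect_equal(mean(pred == tab$cultivar), 1.0)
})

test_that("duplicating every training sample leaves predictions unchanged", {
  tab <- generate_feature_table(2, 20, 2, class_separation = 8, seed = 6)
  df <- as.data.frame(tab)
  dup <- feature_table(rbind(df[, feature_names(tab)], df[, feature_names(tab)]),
                       c(df$cultivar, df$cultivar))
  m1 <- train_svm(tab, c = 5)
  m2 <- train_svm(dup, c = 5)
  set.seed(7)
  probe <- matrix(rnorm(200), 100, 2,
                  dimnames = list(NULL, feature_names(tab)))
  expect_equal(as.character(predict(m1, probe)),
               as.character(predict(m2, probe)))
})

test_that("feature scaling is absorbed by standardisation", {
  tab <- generate_feature_table(3, 15, 4, class_separation = 5, seed = 7)
  df <- as.data.frame(tab)
  scaled <- df[, feature_names(tab)]
  scaled[, 1] <- scaled[, 1] * 1000
  scaled[, 3] <- scaled[, 3] / 500
  tab_s <- feature_table(scaled, df$cultivar)
  m <- train_svm(tab, c = 2, g = 0.3)
  ms <- train_svm(tab_s, c = 2, g = 0.3)
  expect_equal(as.character(predict(m, tab)), as.character(predict(ms, tab_s)))
})

test_that("evaluation reports coherent accuracies and confusion matrices", {
  tab <- generate_feature_table(3, 20, 3, class_separation = 10, seed = 8)
  sp <- stratified_split(tab, c(6, 2, 2), seed = 8)
  model <- train_svm(subset_tab <- teaspec:::subset_table(tab, sp$assignment == "train"),
                     c = 10)
  rep <- evaluate_classifier(model, tab, sp)
  for (s in c("train", "test", "validation")) {
    cm <- rep$confusion[[s]]
    expect_equal(sum(diag(cm)) / sum(cm), rep$accuracy[[s]])
    expect_equal(as.vector(rowSums(cm)),
                 as.vector(table(tab$cultivar[sp$assignment == s])))
  }
  # fully separable: diagonal confusion and perfect accuracy everywhere
  expect_true(all(unlist(rep$accuracy) == 1))
  expect_true(all(rep$confusion$test[upper.tri(rep$confusion$test)] == 0))
})

test_that("dataset-scale ablation reports one row per fraction and split and
           reproduces the full-data pipeline at fraction one", {
  tab <- generate_feature_table(3, 20, 4, class_separation = 4, seed = 9)
  res <- dataset_scale_ablation(tab, fractions = c(0.5, 1), ratios = c(3, 1, 1),
                                optimizer = "none", seed = 9)
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$split), c("train", "test", "validation"))
  full_seed <- res$seed[res$fraction == 1][1]
  direct <- tuned_svm_pipeline(tab, optimizer = "none", ratios = c(3, 1, 1),
                               seed = full_seed)
  expect_equal(res$accuracy[res$fraction == 1 & res$split == "test"],
               direct$report$accuracy$test)
})

test_that("more data does not hurt on the learning curve", {
  ft <- shared_features()
  res <- dataset_scale_ablation(ft, fractions = c(0.4, 1), ratios = c(3, 1, 1),
                                optimizer = "none", seed = 11)
  a_small <- res$accuracy[res$fraction == 0.4 & res$split == "test"]
  a_full <- res$accuracy[res$fraction == 1 & res$split == "test"]
  expect_lte(a_small, a_full + 0.02)
})

test_that("per-class reduction stops before exhausting a class and tracks
           the baseline", {
  tab <- generate_feature_table(3, 20, 4, class_separation = 4, seed = 10)
  res <- per_class_reduction_ablation(tab, step = 10, ratios = c(3, 1, 1),
                                      optimizer = "none", seed = 10)
  expect_setequal(unique(res$removed_per_class), c(0, 10))
  expect_true(all(res$n_samples[res$removed_per_class == 10] == 30))
  base <- res$accuracy[res$removed_per_class == 0 & res$split == "validation"]
  red <- res$accuracy[res$removed_per_class == 10 & res$split == "validation"]
  expect_lte(red, base + 0.1)
})
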