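# Data splitting, RBF-SVM training and evaluation, per-cultivar accuracy
# and confusion matrices, and the dataset-scale / per-class-reduction
# ablation studies.

#' Stratified train/test/validation split
#'
#' Partitions every class at the given ratios (default 6:2:2) with
#' largest-remainder rounding; ties in the remainders resolve in
#' train > test > validation order.  Deterministic under `seed`.
#'
#' @param table a [feature_table()] (every class needs >= 5 samples by
#'   default; relax with `min_per_class`).
#' @param ratios length-3 positive weights for train/test/validation.
#' @param seed RNG seed.
#' @param min_per_class smallest admissible class size.
#' @return object of class `split_assignment`: factor `assignment`
#'   (`train`/`test`/`validation` per row), `ratios`, `seed`, per-class
#'   count table.
#' @export
stratified_split <- function(table, ratios = c(6, 2, 2), seed = 1L,
                             min_per_class = 5L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  sets <- c("train", "test", "validation")
  labels <- table$cultivar
  tab <- base::table(labels)
  if (any(tab < min_per_class))
    stopf("class '%s' has only %d samples (need >= %d)",
          names(tab)[which.min(tab)], min(tab), min_per_class)
  rng <- local_rng(seed)
  assignment <- character(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_int(length(idx))]
    n <- length(idx)
    exact <- n * ratios / sum(ratios)
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      order_rem <- order(exact - base, -seq_along(exact), decreasing = TRUE)
      base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
    }
    assignment[idx] <- rep(sets, base)
  }
  structure(list(assignment = factor(assignment, levels = sets),
                 ratios = ratios, seed = seed,
                 counts = base::table(labels, factor(assignment, levels = sets))),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %s (ratios %s, seed %d)\n",
              paste(table(x$assignment), collapse = "/"),
              paste(x$ratios, collapse = ":"), x$seed))
  invisible(x)
}

#' Train a multi-class RBF SVM
#'
#' Z-score standardisation is fit on the training rows and frozen into the
#' model; the classifier is a soft-margin SVM with RBF kernel
#' \eqn{K(x,y)=\exp(-g\|x-y\|^2)} and one-vs-one voting for multi-class.
#'
#' @param train a [feature_table()] with >= 2 classes.
#' @param c,g positive hyperparameters (penalty and kernel width).
#' @param variables optional subset of indicators to train on.
#' @return object of class `trained_classifier`.
#' @export
train_svm <- function(train, c = 1, g = NULL, variables = NULL) {
  X <- feature_matrix(train, variables)
  if (any(!is.finite(X))) stopf("non-finite feature values in training data")
  y <- factor(train$cultivar)
  if (nlevels(y) < 2) stopf("training data must contain >= 2 classes")
  if (is.null(g)) g <- 1 / ncol(X)
  stopifnot(c > 0, g > 0)
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  fit <- e1071::svm(Z, y, type = "C-classification", kernel = "radial",
                    cost = c, gamma = g, scale = FALSE)
  structure(list(model = fit, c = c, g = g,
                 center = mu, scale = sg,
                 features = colnames(X), levels = levels(y)),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> RBF SVM, c=%.4g g=%.4g, %d features, %d classes\n",
              x$c, x$g, length(x$features), length(x$levels)))
  invisible(x)
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table") || is.data.frame(newdata))
    feature_matrix(newdata, object$features)
  else as.matrix(newdata)[, object$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  stats::predict(object$model, Z)
}

confusion_matrix <- function(actual, predicted, levels) {
  table(actual = factor(actual, levels), predicted = factor(predicted, levels))
}

#' Evaluate a classifier on the three splits
#'
#' Per split: overall accuracy (trace/total), per-class accuracy (recall,
#' diagonal over row sum) and the actual-by-predicted confusion matrix.
#'
#' @param model a `trained_classifier`.
#' @param table the full [feature_table()].
#' @param splits a [stratified_split()] over the same rows.
#' @return object of class `eval_report`: lists `accuracy`,
#'   `per_class_accuracy`, `confusion` keyed by split name.
#' @export
evaluate_classifier <- function(model, table, splits) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(splits, "split_assignment"),
            length(splits$assignment) == nrow(table))
  out <- list(accuracy = list(), per_class_accuracy = list(), confusion = list())
  for (s in levels(splits$assignment)) {
    rows <- splits$assignment == s
    if (!any(rows)) stopf("split '%s' is empty", s)
    sub <- as.data.frame(table)[rows, , drop = FALSE]
    pred <- predict(model, sub)
    cm <- confusion_matrix(sub$cultivar, pred, model$levels)
    out$accuracy[[s]] <- sum(diag(cm)) / sum(cm)
    rs <- rowSums(cm)
    out$per_class_accuracy[[s]] <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
    out$confusion[[s]] <- cm
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  acc <- unlist(x$accuracy)
  cat(sprintf("<eval_report> accuracy: %s\n",
              paste(sprintf("%s %.2f%%", names(acc), 100 * acc), collapse = ", ")))
  invisible(x)
}

subset_table <- function(table, rows) {
  df <- as.data.frame(table)[rows, , drop = FALSE]
  feature_table(df[, feature_names(table), drop = FALSE],
                df$cultivar, df$germination, df$sample_id)
}

#' One tuned train/evaluate pass
#'
#' Splits the table, tunes `(c, g)` on the training split with the chosen
#' optimizer (or uses the plain baseline `c = 1`, `g = 1/p` when
#' `optimizer = "none"`), trains, and evaluates all three splits.
#'
#' @param table a [feature_table()].
#' @param optimizer `"gwo"`, `"pso"`, `"ga"`, `"grid"` or `"none"`.
#' @param ratios split ratios.
#' @param seed master seed (split, folds, optimizer).
#' @param space a [search_space()].
#' @param agents,iters optimizer budget.
#' @param k_folds CV folds for the tuning fitness.
#' @param variables optional indicator subset.
#' @return list with `split`, `run` (`NULL` for the baseline), `model`,
#'   `report`.
#' @export
tuned_svm_pipeline <- function(table, optimizer = c("gwo", "pso", "ga", "grid", "none"),
                               ratios = c(6, 2, 2), seed = 1L,
                               space = search_space(), agents = 20, iters = 50,
                               k_folds = 5, variables = NULL) {
  optimizer <- match.arg(optimizer)
  rng <- local_rng(seed)
  split_seed <- rng$child_seed()
  fold_seed <- rng$child_seed()
  opt_seed <- rng$child_seed()
  splits <- stratified_split(table, ratios = ratios, seed = split_seed)
  train <- subset_table(table, splits$assignment == "train")
  if (!is.null(variables)) train <- select_features(train, variables)
  run <- NULL
  if (optimizer == "none") {
    cg <- c(1, 1 / length(feature_names(train)))
  } else {
    fit_fun <- svm_fitness(train, k_folds = k_folds, seed = fold_seed)
    run <- switch(optimizer,
      gwo = gwo_optimize(fit_fun, space, wolves = agents, iters = iters,
                         seed = opt_seed),
      pso = pso_optimize(fit_fun, space, particles = agents, iters = iters,
                         seed = opt_seed),
      ga = ga_optimize(fit_fun, space, pop = agents, gens = iters,
                       seed = opt_seed),
      grid = grid_search(fit_fun, space, n = agents))
    cg <- c(run$best_c, run$best_g)
  }
  model <- train_svm(train, c = cg[1], g = cg[2])
  tab_eval <- if (is.null(variables)) table else
    select_features(table, variables)
  report <- evaluate_classifier(model, tab_eval, splits)
  list(split = splits, run = run, model = model, report = report)
}

#' Dataset-scale ablation
#'
#' Re-runs the tuned pipeline on nested per-class subsamples of the data
#' (fractions 1/5 .. 5/5 by default) at 3:1:1 split ratios, mirroring a
#' learning-curve study of how dataset size drives accuracy.
#'
#' @param table a [feature_table()].
#' @param fractions subsample fractions in (0, 1].
#' @param ratios split ratios (default 3:1:1).
#' @param optimizer,agents,iters,k_folds,space tuning configuration.
#' @param seed master seed.
#' @return data.frame with one row per (fraction, split): `fraction`,
#'   `n_samples`, `split`, `accuracy`, `best_c`, `best_g`.
#' @export
dataset_scale_ablation <- function(table, fractions = (1:5) / 5,
                                   ratios = c(3, 1, 1),
                                   optimizer = "gwo", agents = 10, iters = 10,
                                   k_folds = 5, space = search_space(),
                                   seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  rng <- local_rng(seed)
  sub_seed <- rng$child_seed()
  rows_list <- list()
  for (fr in fractions) {
    keep <- integer(0)
    rng_f <- local_rng(sub_seed)  # nested subsets: same permutation per class
    for (cl in unique(table$cultivar)) {
      idx <- which(table$cultivar == cl)
      n_keep <- round(fr * length(idx))
      if (n_keep < 5)
        stopf("fraction %.2f leaves class '%s' with %d samples", fr, cl, n_keep)
      keep <- c(keep, idx[rng_f$sample_int(length(idx))][seq_len(n_keep)])
    }
    sub <- subset_table(table, sort(keep))
    run_seed <- rng$child_seed()
    res <- tuned_svm_pipeline(sub, optimizer = optimizer, ratios = ratios,
                              seed = run_seed, space = space,
                              agents = agents, iters = iters, k_folds = k_folds)
    for (s in names(res$report$accuracy)) {
      rows_list[[length(rows_list) + 1L]] <- data.frame(
        fraction = fr, n_samples = nrow(sub), split = s,
        accuracy = res$report$accuracy[[s]],
        best_c = res$model$c, best_g = res$model$g, seed = run_seed)
    }
  }
  do.call(rbind, rows_list)
}

#' Per-class reduction ablation
#'
#' Iteratively removes `step` randomly chosen samples per class and re-runs
#' the tuned pipeline, stopping before any class would fall below
#' `min_per_class` samples.
#'
#' @param table a [feature_table()].
#' @param step samples removed per class per round.
#' @param ratios,optimizer,agents,iters,k_folds,space tuning configuration.
#' @param min_per_class stopping floor.
#' @param seed master seed.
#' @return data.frame with one row per (reduction, split).
#' @export
per_class_reduction_ablation <- function(table, step = 10, ratios = c(6, 2, 2),
                                         optimizer = "gwo", agents = 10,
                                         iters = 10, k_folds = 5,
                                         space = search_space(),
                                         min_per_class = 5L, seed = 1L) {
  stopifnot(step >= 1)
  rng <- local_rng(seed)
  perm_seed <- rng$child_seed()
  tab <- base::table(table$cultivar)
  max_rounds <- floor((min(tab) - min_per_class) / step)
  rows_list <- list()
  for (round_i in 0:max(0, max_rounds)) {
    removed <- round_i * step
    keep <- integer(0)
    rng_f <- local_rng(perm_seed)
    for (cl in unique(table$cultivar)) {
      idx <- which(table$cultivar == cl)
      perm <- idx[rng_f$sample_int(length(idx))]
      keep <- c(keep, perm[seq_len(length(idx) - removed)])
    }
    sub <- subset_table(table, sort(keep))
    run_seed <- rng$child_seed()
    res <- tuned_svm_pipeline(sub, optimizer = optimizer, ratios = ratios,
                              seed = run_seed, space = space,
                              agents = agents, iters = iters, k_folds = k_folds)
    for (s in names(res$report$accuracy)) {
      rows_list[[length(rows_list) + 1L]] <- data.frame(
        removed_per_class = removed, n_samples = nrow(sub), split = s,
        accuracy = res$report$accuracy[[s]], seed = run_seed)
    }
  }
  do.call(rbind, rows_list)
}
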