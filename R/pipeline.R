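# End-to-end orchestration: simulate -> calibrate/segment -> extract ->
# select -> tune -> train -> evaluate -> germination, under one master seed,
# with per-stage outputs, wall-clock and content hashes in a manifest.

#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run.  All stage seeds are derived
#' deterministically from `seed`, so one master seed fixes the whole run.
#'
#' @param spec a [synthetic_spec()] (the input dataset definition).
#' @param texture a [texture_config()].
#' @param use_truth_masks segment with ExGR+Otsu (FALSE, default) or use the
#'   generator's ground-truth masks.
#' @param selection list: `n_components`, `n_splits`, `n_folds`,
#'   `cutoff_multiplier`, `rule` (see [uve_lasso()]); or `NULL` to skip
#'   selection and classify on all 86 indicators.
#' @param optimizer `"gwo"`, `"pso"`, `"ga"` or `"none"` (baseline SVM).
#' @param agents,iters optimizer budget.
#' @param k_folds tuning CV folds.
#' @param ratios train/test/validation split ratios.
#' @param space a [search_space()].
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(spec = synthetic_spec(), texture = texture_config(),
                       use_truth_masks = FALSE,
                       selection = list(), optimizer = "gwo",
                       agents = 20, iters = 50, k_folds = 5,
                       ratios = c(6, 2, 2), space = search_space(),
                       seed = 1L) {
  structure(list(spec = spec, texture = texture,
                 use_truth_masks = isTRUE(use_truth_masks),
                 selection = selection, optimizer = optimizer,
                 agents = agents, iters = iters, k_folds = k_folds,
                 ratios = ratios, space = space, seed = as.integer(seed)),
            class = "run_config")
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes every stage in order and returns all stage outputs plus a
#' manifest (per-stage wall-clock seconds and md5 content hashes).  The
#' manifest hashes make determinism checkable: two runs of the same config
#' produce identical hashes.
#'
#' @param config a [run_config()].
#' @param out optional directory; when given, the feature table (CSV), the
#'   selection report, the evaluation report and the germination report
#'   (JSON) are written there.
#' @return object of class `run_result`: `features`, `selection`,
#'   `classification` (split/run/model/report), `germination`, `manifest`.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  rng <- local_rng(config$seed)
  data_seed <- rng$child_seed()
  sel_seed <- rng$child_seed()
  clf_seed <- rng$child_seed()
  manifest <- list(seed = config$seed, stages = list())
  tic <- function() proc.time()[["elapsed"]]
  record <- function(name, t0, obj) {
    manifest$stages[[name]] <<- list(seconds = round(tic() - t0, 3),
                                     hash = hash_object(obj))
  }

  t0 <- tic()
  spec <- config$spec
  spec$seed <- data_seed
  dataset <- generate_dataset(spec)
  record("simulate", t0, dataset)

  t0 <- tic()
  features <- extract_features(dataset, cfg = config$texture,
                               use_truth_masks = config$use_truth_masks)
  record("extract", t0, features)

  selection <- NULL
  variables <- NULL
  if (!is.null(config$selection)) {
    t0 <- tic()
    sl <- config$selection
    selection <- uve_lasso(features,
                           n_components = sl$n_components %||% NULL,
                           n_splits = sl$n_splits %||% 20,
                           n_folds = sl$n_folds %||% 5,
                           cutoff_multiplier = sl$cutoff_multiplier %||% 1,
                           rule = sl$rule %||% "min",
                           seed = sel_seed)
    variables <- selection$final_names
    record("select", t0, selection)
  }

  t0 <- tic()
  clf <- tuned_svm_pipeline(features, optimizer = config$optimizer,
                            ratios = config$ratios, seed = clf_seed,
                            space = config$space, agents = config$agents,
                            iters = config$iters, k_folds = config$k_folds,
                            variables = variables)
  record("classify", t0, list(clf$report, clf$model$c, clf$model$g))

  t0 <- tic()
  germ_vars <- intersect(GERMINATION_VARIABLES, feature_names(features))
  cm <- cultivar_means(features, germ_vars)
  fisher <- fit_fisher(cm$means, cm$stages)
  germ <- germination_report(fisher)
  record("germination", t0, germ)

  result <- structure(list(config = config, dataset_labels = dataset$labels,
                           features = features, selection = selection,
                           classification = clf,
                           germination = c(germ, list(model = fisher)),
                           manifest = manifest),
                      class = "run_result")
  if (!is.null(out)) write_run_outputs(result, out)
  result
}

write_run_outputs <- function(result, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_feature_csv(result$features, file.path(out, "features.csv"))
  rep <- result$classification$report
  jsonlite::write_json(list(
    accuracy = rep$accuracy,
    per_class_accuracy = rep$per_class_accuracy,
    best_c = result$classification$model$c,
    best_g = result$classification$model$g), file.path(out, "evaluation.json"),
    auto_unbox = TRUE, digits = NA)
  for (s in names(rep$confusion))
    utils::write.csv(as.data.frame.matrix(rep$confusion[[s]]),
                     file.path(out, sprintf("confusion_%s.csv", s)))
  if (!is.null(result$selection)) {
    sel <- result$selection
    jsonlite::write_json(list(
      cascade = c(sel$n_input, sel$n_after_uve, sel$n_after_lasso),
      final_names = sel$final_names, vip = as.list(sel$vip),
      lambda_opt = sel$lasso$lambda_opt,
      uve_cutoff = sel$uve$cutoff), file.path(out, "selection.json"),
      auto_unbox = TRUE, digits = NA)
  }
  germ <- result$germination
  jsonlite::write_json(list(
    confusion = as.data.frame.matrix(germ$confusion),
    centers = as.data.frame(germ$centers)), file.path(out, "germination.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(cultivar = rownames(germ$projection),
                              germ$projection),
                   file.path(out, "germination_scores.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.run_result <- function(x, ...) {
  acc <- unlist(x$classification$report$accuracy)
  cat(sprintf("<run_result> %s-SVM accuracy: %s\n",
              toupper(x$config$optimizer),
              paste(sprintf("%s %.2f%%", names(acc), 100 * acc),
                    collapse = ", ")))
  if (!is.null(x$selection))
    cat(sprintf("  selection cascade: %d -> %d -> %d\n", x$selection$n_input,
                x$selection$n_after_uve, x$selection$n_after_lasso))
  cat(sprintf("  germination confusion diagonal: %d/%d\n",
              sum(diag(x$germination$confusion)), sum(x$germination$confusion)))
  invisible(x)
}

#' Compare GA, PSO and GWO on identical splits
#'
#' Runs the three tuners against the same feature table, split assignment
#' and cross-validation folds (shared seeds), then trains and evaluates each
#' best (c, g).
#'
#' @param table a [feature_table()].
#' @param ratios,agents,iters,k_folds,space tuning configuration.
#' @param seed master seed (shared across algorithms).
#' @param variables optional indicator subset.
#' @return list with `comparison` (data.frame: algorithm x split accuracy,
#'   best c and g) and `runs`.
#' @export
compare_optimizers <- function(table, ratios = c(6, 2, 2), agents = 20,
                               iters = 50, k_folds = 5,
                               space = search_space(), seed = 1L,
                               variables = NULL) {
  rng <- local_rng(seed)
  split_seed <- rng$child_seed()
  fold_seed <- rng$child_seed()
  opt_seed <- rng$child_seed()
  splits <- stratified_split(table, ratios = ratios, seed = split_seed)
  tab <- if (is.null(variables)) table else select_features(table, variables)
  train <- subset_table(tab, splits$assignment == "train")
  fit_fun <- svm_fitness(train, k_folds = k_folds, seed = fold_seed)
  runs <- list(
    GA = ga_optimize(fit_fun, space, pop = agents, gens = iters, seed = opt_seed),
    PSO = pso_optimize(fit_fun, space, particles = agents, iters = iters,
                       seed = opt_seed),
    GWO = gwo_optimize(fit_fun, space, wolves = agents, iters = iters,
                       seed = opt_seed))
  rows <- lapply(names(runs), function(alg) {
    run <- runs[[alg]]
    model <- train_svm(train, c = run$best_c, g = run$best_g)
    rep <- evaluate_classifier(model, tab, splits)
    data.frame(algorithm = alg, best_c = run$best_c, best_g = run$best_g,
               cv_fitness = run$best_fitness,
               train = rep$accuracy$train, test = rep$accuracy$test,
               validation = rep$accuracy$validation)
  })
  list(comparison = do.call(rbind, rows), runs = runs, split = splits)
}
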