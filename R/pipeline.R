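#' Derive a child seed from the master seed
#'
#' One master seed deterministically derives the split / search / model
#' seeds through a fixed counter scheme, so a whole pipeline run is
#' reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param counter fixed small integer per purpose (1 = split, 2 = search,
#'   3 = model, 4 = folds).
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 1e6 * 10007 + counter * 7919) %% 2147483646 + 1)
}

#' Stratified 4:1 train/test split
#'
#' Shuffles and splits a labeled feature table into training and test
#' parts at the 4:1 ratio by stratified sampling on the labels: per class,
#' `round(n_class / 5)` rows go to the test part, so class proportions
#' match the global proportion within integer rounding. Disjoint,
#' exhaustive, deterministic per seed.
#'
#' @param features labeled feature tibble (`label` column).
#' @param seed integer seed.
#' @param test_fraction held-out fraction (default 1/5).
#' @return List with `train` and `test` tibbles.
#' @export
split_screening <- function(features, seed = 1, test_fraction = 0.2) {
  assert_labeled(features)
  set.seed(as.integer(seed))
  test_idx <- integer()
  for (cl in sort(unique(features$label))) {
    idx <- which(features$label == cl)
    idx <- idx[sample.int(length(idx))]
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, idx[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  list(train = features[-test_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

#' Fit preprocessing on the training split
#'
#' Removes exactly constant features (raw variance below `1e-12`), then
#' standardizes the remaining features to zero mean and unit variance with
#' statistics computed from the training rows only.
#'
#' @param train training feature tibble.
#' @return Preprocessing state (class `iec_preprocess`): kept feature
#'   names, per-feature train means and scales.
#' @export
preprocess_fit <- function(train) {
  cols <- feature_columns(train)
  x <- as.matrix(train[, cols, drop = FALSE])
  v <- apply(x, 2, var)
  keep <- cols[v >= 1e-12 & !is.na(v)]
  mu <- colMeans(x[, keep, drop = FALSE])
  sdev <- apply(x[, keep, drop = FALSE], 2, sd)
  structure(list(features = keep, center = mu, scale = sdev),
            class = "iec_preprocess")
}

#' Apply stored preprocessing statistics to any table
#'
#' Uses the training statistics unchanged (no re-centering on new data).
#'
#' @param state `iec_preprocess` from [preprocess_fit()].
#' @param table feature tibble containing at least the kept features.
#' @return Tibble with `ligand`/`label` carried through and standardized
#'   kept features.
#' @export
preprocess_apply <- function(state, table) {
  stopifnot(inherits(state, "iec_preprocess"))
  missing_cols <- setdiff(state$features, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("table lacks feature column(s): ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  x <- as.matrix(table[, state$features, drop = FALSE])
  x <- sweep(sweep(x, 2, state$center), 2, state$scale, "/")
  id_cols <- intersect(c("ligand", "label"), names(table))
  dplyr::bind_cols(table[, id_cols, drop = FALSE],
                   as_tibble(as.data.frame(x, check.names = FALSE)))
}

#' Hyperparameter search space
#'
#' The declared ranges per algorithm: SVM (RBF) cost `C` in `[0.1, 10]`
#' and `gamma` in `[0.001, 1]`, both uniform; random forest `n_estimators`
#' in `{100, 110, ..., 300}`, `max_depth` in `{6..100}`, `max_features`
#' in `{sqrt, log2}`, `min_samples_leaf` in `{3..10}`; gradient-boosted
#' trees share `n_estimators` and `max_depth` with the forest plus
#' `learning_rate` in `[0.1, 0.5]` and `l2_reg` in `[0.5, 3]`, uniform.
#'
#' @param algorithm `"svm"`, `"rf"` or `"xgb"`.
#' @param n number of sampled candidate settings.
#' @param seed integer seed.
#' @return Tibble of candidates, one row per setting.
#' @export
sample_space <- function(algorithm = c("svm", "rf", "xgb"), n = 100, seed = 1) {
  algorithm <- match.arg(algorithm)
  set.seed(as.integer(seed))
  if (algorithm == "svm") {
    tibble(C = runif(n, 0.1, 10), gamma = runif(n, 0.001, 1))
  } else if (algorithm == "rf") {
    tibble(n_estimators = sample(seq(100L, 300L, 10L), n, replace = TRUE),
           max_depth = sample(6:100, n, replace = TRUE),
           max_features = sample(c("sqrt", "log2"), n, replace = TRUE),
           min_samples_leaf = sample(3:10, n, replace = TRUE))
  } else {
    tibble(n_estimators = sample(seq(100L, 300L, 10L), n, replace = TRUE),
           max_depth = sample(6:100, n, replace = TRUE),
           learning_rate = runif(n, 0.1, 0.5),
           l2_reg = runif(n, 0.5, 3))
  }
}

fit_algorithm <- function(x, y, algorithm, hp, seed) {
  y <- factor(y, levels = c(0, 1))
  if (algorithm == "svm") {
    set.seed(seed)
    e1071::svm(x = x, y = y, kernel = "radial", cost = hp$C, gamma = hp$gamma,
               probability = TRUE, scale = FALSE)
  } else if (algorithm == "rf") {
    p <- ncol(x)
    mtry <- if (identical(hp$max_features, "log2")) {
      max(1L, floor(log2(p)))
    } else max(1L, floor(sqrt(p)))
    ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                   num.trees = hp$n_estimators, max.depth = hp$max_depth,
                   mtry = mtry, min.node.size = hp$min_samples_leaf,
                   seed = seed, num.threads = 1)
  } else {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(data = x, label = as.numeric(y) - 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$learning_rate, lambda = hp$l2_reg,
                    tree_method = "exact", nthread = 1, seed = seed),
      data = dtrain, nrounds = hp$n_estimators, verbose = 0)
  }
}

predict_algorithm <- function(model, x, algorithm) {
  if (algorithm == "svm") {
    pr <- attr(predict(model, x, probability = TRUE), "probabilities")
    as.numeric(pr[, "1"])
  } else if (algorithm == "rf") {
    as.numeric(predict(model, as.data.frame(x), num.threads = 1)$predictions[, "1"])
  } else {
    as.numeric(predict(model, xgboost::xgb.DMatrix(data = x)))
  }
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  fold_id
}

#' Random hyperparameter search with stratified k-fold cross-validation
#'
#' Evaluates exactly `steps` candidate settings (seeded random draws from
#' the declared space) by stratified k-fold CV on the training split,
#' scoring each by the mean F1 of the positive class at threshold 0.5,
#' and returns the argmax with the full trace.
#'
#' @param train labeled training tibble.
#' @param algorithm `"svm"`, `"rf"` or `"xgb"`.
#' @param steps number of candidates.
#' @param folds number of CV folds.
#' @param seed master seed (search and fold seeds derive from it).
#' @return List of class `iec_tune`: `best` (named list of
#'   hyperparameters), `best_score`, `trace` tibble (one row per
#'   candidate, `cv_f1` column), `algorithm`, `search` (`"random"`).
#' @export
tune <- function(train, algorithm = c("svm", "rf", "xgb"), steps = 100,
                 folds = 10, seed = 1) {
  algorithm <- match.arg(algorithm)
  assert_labeled(train)
  n_pos <- sum(train$label == 1)
  n_neg <- sum(train$label == 0)
  if (n_pos < folds || n_neg < folds) {
    abort(sprintf(paste0("too few samples per class (%d positive, %d negative) ",
                         "for %d folds; use fewer folds"), n_pos, n_neg, folds))
  }
  prep <- preprocess_fit(train)
  xt <- preprocess_apply(prep, train)
  x <- as.matrix(xt[, prep$features, drop = FALSE])
  y <- train$label
  candidates <- sample_space(algorithm, steps, derive_seed(seed, 2))
  fold_id <- stratified_folds(y, folds, derive_seed(seed, 4))
  model_seed <- derive_seed(seed, 3)
  cv_f1 <- numeric(steps)
  for (s in seq_len(steps)) {
    hp <- as.list(candidates[s, ])
    fold_scores <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- fit_algorithm(x[tr, , drop = FALSE], y[tr], algorithm, hp, model_seed)
      p <- predict_algorithm(m, x[!tr, , drop = FALSE], algorithm)
      fold_scores[f] <- f1_score(confusion_counts(
        tibble(score = p, label = y[!tr]), 0.5))
    }
    cv_f1[s] <- mean(fold_scores)
  }
  trace <- dplyr::bind_cols(tibble(step = seq_len(steps)), candidates,
                            tibble(cv_f1 = cv_f1))
  best_i <- which.max(cv_f1)
  structure(list(best = as.list(candidates[best_i, ]), best_score = cv_f1[best_i],
                 trace = trace, algorithm = algorithm, folds = folds,
                 search = "random", seed = seed),
            class = "iec_tune")
}

#' @export
print.iec_tune <- function(x, ...) {
  cat(sprintf("<iec_tune> %s, %d random steps, %d-fold CV; best F1 = %.4f\n",
              x$algorithm, nrow(x$trace), x$folds, x$best_score))
  invisible(x)
}

#' Fit the final model on the full training split
#'
#' @param train labeled training tibble.
#' @param algorithm `"svm"`, `"rf"` or `"xgb"`.
#' @param hyperparameters named list (e.g. `tune()$best`).
#' @param seed master seed.
#' @return Object of class `iec_scorer`: preprocessing state, algorithm,
#'   hyperparameters, fitted model, seed.
#' @export
train_final <- function(train, algorithm = c("svm", "rf", "xgb"),
                        hyperparameters, seed = 1) {
  algorithm <- match.arg(algorithm)
  assert_labeled(train)
  prep <- preprocess_fit(train)
  xt <- preprocess_apply(prep, train)
  x <- as.matrix(xt[, prep$features, drop = FALSE])
  model <- fit_algorithm(x, train$label, algorithm, hyperparameters,
                         derive_seed(seed, 3))
  structure(list(preprocess = prep, algorithm = algorithm,
                 hyperparameters = hyperparameters, model = model,
                 seed = seed, n_train = nrow(train)),
            class = "iec_scorer")
}

#' @export
print.iec_scorer <- function(x, ...) {
  cat(sprintf("<iec_scorer> %s on %d features (n_train = %d, seed = %s)\n",
              x$algorithm, length(x$preprocess$features), x$n_train, x$seed))
  invisible(x)
}

#' Score new ligands with a trained scorer
#'
#' @param object an `iec_scorer`.
#' @param newdata feature tibble containing the scorer's kept features.
#' @param ... unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict.iec_scorer <- function(object, newdata, ...) {
  xt <- preprocess_apply(object$preprocess, newdata)
  x <- as.matrix(xt[, object$preprocess$features, drop = FALSE])
  predict_algorithm(object$model, x, object$algorithm)
}

#' Combine scorers by voting
#'
#' @param scorers list of `iec_scorer` objects.
#' @param table feature tibble to score.
#' @param mode `"mean_probability"` (arithmetic mean of member
#'   probabilities) or `"majority"` (fraction of members predicting
#'   positive at threshold 0.5).
#' @return Numeric vector of combined scores.
#' @export
vote <- function(scorers, table, mode = c("mean_probability", "majority")) {
  mode <- match.arg(mode)
  stopifnot(length(scorers) >= 1)
  probs <- vapply(scorers, function(s) predict(s, table), numeric(nrow(table)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (mode == "mean_probability") rowMeans(probs)
  else rowMeans(probs >= 0.5)
}

#' Persist a trained scorer to a directory
#'
#' Writes a JSON manifest (algorithm, hyperparameters, seed, kept
#' features, training statistics, package version) plus the serialized
#' model object.
#'
#' @param scorer an `iec_scorer`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
save_scorer <- function(scorer, dir) {
  stopifnot(inherits(scorer, "iec_scorer"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    algorithm = scorer$algorithm,
    hyperparameters = scorer$hyperparameters,
    seed = scorer$seed,
    n_train = scorer$n_train,
    features = scorer$preprocess$features,
    center = as.list(scorer$preprocess$center),
    scale = as.list(scorer$preprocess$scale),
    package_version = as.character(utils::packageVersion("iecscore"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (scorer$algorithm == "xgb") {
    xgboost::xgb.save(scorer$model, file.path(dir, "model.ubj"))
  } else {
    saveRDS(scorer$model, file.path(dir, "model.rds"), version = 2)
  }
  invisible(dir)
}

#' Reload a scorer saved by [save_scorer()]
#'
#' @param dir directory written by [save_scorer()].
#' @return An `iec_scorer` producing identical predictions.
#' @export
load_scorer <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  model <- if (manifest$algorithm == "xgb") {
    xgboost::xgb.load(file.path(dir, "model.ubj"))
  } else {
    readRDS(file.path(dir, "model.rds"))
  }
  prep <- structure(list(features = manifest$features,
                         center = unlist(manifest$center),
                         scale = unlist(manifest$scale)),
                    class = "iec_preprocess")
  structure(list(preprocess = prep, algorithm = manifest$algorithm,
                 hyperparameters = manifest$hyperparameters, model = model,
                 seed = manifest$seed, n_train = manifest$n_train),
            class = "iec_scorer")
}

#' Run the full screening pipeline
#'
#' Convenience wrapper: stratified 4:1 split, hyperparameter search with
#' stratified k-fold CV, final fit on the training split, evaluation on
#' the held-out part.
#'
#' @param features labeled feature tibble.
#' @param algorithm `"svm"`, `"rf"` or `"xgb"`.
#' @param steps,folds search length and CV folds.
#' @param seed master seed (all child seeds derive from it).
#' @param fractions enrichment-factor fractions for the report.
#' @return List of class `iec_pipeline`: `scorer`, `tuning`, `report`,
#'   `scores` (held-out screen result tibble).
#' @export
run_pipeline <- function(features, algorithm = c("svm", "rf", "xgb"),
                         steps = 100, folds = 10, seed = 1, fractions = 0.01) {
  algorithm <- match.arg(algorithm)
  parts <- split_screening(features, derive_seed(seed, 1))
  tuning <- tune(parts$train, algorithm, steps = steps, folds = folds, seed = seed)
  scorer <- train_final(parts$train, algorithm, tuning$best, seed)
  p <- predict(scorer, parts$test)
  report <- evaluate_screen(p, parts$test$label, fractions = fractions)
  scores <- screen_result(tibble(ligand = parts$test$ligand, score = p,
                                 label = parts$test$label))
  structure(list(scorer = scorer, tuning = tuning, report = report,
                 scores = scores, seed = seed),
            class = "iec_pipeline")
}

#' @export
print.iec_pipeline <- function(x, ...) {
  cat(sprintf("<iec_pipeline> %s (seed %s)\n", x$scorer$algorithm, x$seed))
  print(x$report)
  invisible(x)
}
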