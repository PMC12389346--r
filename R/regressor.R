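# BUD regressors: linear train/test partitioning, the tree-ensemble flagship
# model and six comparator families, prediction with an ensemble standard
# error, and model persistence.

MODEL_FAMILIES <- c("decision_tree",
                    "random_forest_classifier", "random_forest_regression",
                    "tree_ensemble_classifier", "tree_ensemble_regression",
                    "gradient_boosted_trees_classifier",
                    "gradient_boosted_trees_regression")

#' The seven supported model families
#' @return Character vector of family names.
#' @export
model_families <- function() MODEL_FAMILIES

#' Linear train/test partition
#'
#' Splits rows the way a linear-sampling partitioner does: the first
#' `round(train_fraction * n)` rows (round-half-to-even) form the training
#' set, the remainder the test set. Row order is preserved on both sides.
#'
#' @param rows Data frame of feature rows.
#' @param train_fraction Proportion in (0, 1); default 0.8.
#' @return List with elements `train` and `test`.
#' @export
#' @examples
#' parts <- linear_partition(data.frame(x = 1:10), 0.8)
#' nrow(parts$train)  # 8
linear_partition <- function(rows, train_fraction = 0.8) {
  n <- nrow(rows)
  if (is.null(n) || n < 2) {
    abort("linear_partition needs at least 2 rows", class = "bud_partition_error")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1",
          class = "bud_partition_error")
  }
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train > n - 1) {
    abort(sprintf(
      "linear partition of %d rows at fraction %g leaves no %s row",
      n, train_fraction, if (n_train < 1) "training" else "test"),
      class = "bud_partition_error")
  }
  list(train = rows[seq_len(n_train), , drop = FALSE],
       test = rows[seq(n_train + 1, n), , drop = FALSE])
}

# Feature matrix in schema order; missing content encoded as sentinel -1
# (below the observed range) because the tree learners reject NA predictors.
feature_matrix <- function(rows, schema) {
  x <- as.matrix(as.data.frame(rows)[, schema, drop = FALSE])
  storage.mode(x) <- "double"
  x[is.na(x)] <- -1
  x
}

default_hyperparameters <- function() {
  list(trees = 100L, mtry = NULL, min_node = 1L, max_depth = NULL,
       learning_rate = 0.1)
}

#' Fit a BUD model
#'
#' Trains one of the seven model families on featurized rows. Regression
#' families model `bud_days` directly; classifier families treat each
#' distinct training BUD as one label and are scored on the numeric label
#' value. Fits are deterministic given `(rows, seed, hyperparameters)`.
#'
#' Family/engine mapping: `decision_tree` is a single CART regression tree
#' (rpart); `random_forest_*` use the randomForest package at its canonical
#' defaults (these families are fixed-configuration by design);
#' `tree_ensemble_*` use ranger with the configurable hyperparameters below;
#' `gradient_boosted_trees_*` use xgboost.
#'
#' @param rows Featurized training rows including the `bud_days` target
#'   (see [featurize_dataset()]).
#' @param family One of [model_families()].
#' @param seed Integer RNG seed; default 42.
#' @param trees Ensemble size for the tree-ensemble and boosted families
#'   (default 100).
#' @param mtry Features sampled per split for the tree-ensemble families;
#'   default `floor(sqrt(p))`.
#' @param min_node Minimum terminal-node size for the tree-ensemble families
#'   (default 1).
#' @param replace,sample_fraction Row-sampling rule for the tree-ensemble
#'   families; the default (`TRUE`, 1) is bootstrap sampling.
#' @param max_depth Depth limit; `NULL` (unlimited) for tree ensembles,
#'   internally 6 for the boosted families.
#' @param learning_rate Shrinkage for the boosted families (default 0.1).
#' @return A `bud_model` object.
#' @export
fit_bud_model <- function(rows, family = "tree_ensemble_regression",
                          seed = 42L, trees = 100L, mtry = NULL,
                          min_node = 1L, max_depth = NULL,
                          learning_rate = 0.1, replace = TRUE,
                          sample_fraction = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (!"bud_days" %in% names(rows)) {
    abort("training rows must include the bud_days target", class = "bud_fit_error")
  }
  if (nrow(rows) == 0) {
    abort("cannot fit on an empty training set", class = "bud_fit_error")
  }
  schema <- setdiff(names(rows), "bud_days")
  x <- feature_matrix(rows, schema)
  y <- rows$bud_days
  if (anyNA(y)) abort("bud_days must be known for all training rows",
                      class = "bud_fit_error")
  seed <- as.integer(seed)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))

  model <- list(family = family, schema = schema, seed = seed,
                hyperparameters = list(trees = as.integer(trees), mtry = mtry,
                                       min_node = as.integer(min_node),
                                       max_depth = max_depth,
                                       learning_rate = learning_rate,
                                       replace = replace,
                                       sample_fraction = sample_fraction),
                train_range = range(y))

  # Degenerate constant target: every family is the constant function.
  if (length(unique(y)) == 1L) {
    model$engine <- "constant"
    model$fit <- unique(y)
    return(structure(model, class = "bud_model"))
  }

  df <- as.data.frame(x)
  classify <- grepl("classifier", family)
  if (classify) {
    levels_num <- sort(unique(y))
    model$levels_num <- levels_num
    yf <- factor(y, levels = levels_num)
  }

  set.seed(seed)
  if (family == "decision_tree") {
    model$engine <- "rpart"
    df$.bud <- y
    model$fit <- rpart::rpart(.bud ~ ., data = df, method = "anova")
  } else if (family == "random_forest_regression") {
    model$engine <- "randomForest"
    model$fit <- randomForest::randomForest(x = df, y = y, ntree = trees)
  } else if (family == "random_forest_classifier") {
    model$engine <- "randomForest"
    model$fit <- randomForest::randomForest(x = df, y = yf, ntree = trees)
  } else if (family == "tree_ensemble_regression") {
    model$engine <- "ranger"
    df$.bud <- y
    model$fit <- ranger::ranger(
      dependent.variable.name = ".bud", data = df, num.trees = trees,
      mtry = mtry, min.node.size = min_node,
      max.depth = if (is.null(max_depth)) 0 else max_depth,
      replace = replace, sample.fraction = sample_fraction,
      seed = seed, num.threads = 1)
  } else if (family == "tree_ensemble_classifier") {
    model$engine <- "ranger"
    df$.bud <- yf
    model$fit <- ranger::ranger(
      dependent.variable.name = ".bud", data = df, num.trees = trees,
      mtry = mtry, min.node.size = min_node,
      max.depth = if (is.null(max_depth)) 0 else max_depth,
      replace = replace, sample.fraction = sample_fraction,
      seed = seed, num.threads = 1)
  } else if (family == "gradient_boosted_trees_regression") {
    model$engine <- "xgboost"
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = learning_rate,
                    max_depth = if (is.null(max_depth)) 6 else max_depth,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = trees, verbose = 0)
    model$fit <- xgboost::xgb.save.raw(booster)
  } else if (family == "gradient_boosted_trees_classifier") {
    model$engine <- "xgboost"
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softmax",
                    num_class = length(levels(yf)), eta = learning_rate,
                    max_depth = if (is.null(max_depth)) 6 else max_depth,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(yf) - 1L, nthread = 1),
      nrounds = trees, verbose = 0)
    model$fit <- xgboost::xgb.save.raw(booster)
  }
  structure(model, class = "bud_model")
}

#' @export
print.bud_model <- function(x, ...) {
  cat(sprintf("<bud_model> family=%s engine=%s trees=%d seed=%d\n",
              x$family, x$engine, x$hyperparameters$trees, x$seed))
  cat(sprintf("  %d features; training BUD range [%g, %g] days\n",
              length(x$schema), x$train_range[1], x$train_range[2]))
  invisible(x)
}

majority_label <- function(m) {
  # deterministic majority vote over a numeric per-tree matrix (ties -> the
  # smallest label among the most voted)
  apply(m, 1, function(v) {
    tab <- table(v)
    as.numeric(names(tab)[which.max(tab)])
  })
}

#' Predict BUDs with an ensemble standard error
#'
#' For averaging ensembles (the forest families) the point estimate is the
#' ensemble aggregate and `stderr_days` is the standard deviation of the
#' per-tree predictions divided by `sqrt(tree count)`. Single trees and
#' boosted (additive) models report `stderr_days = 0`.
#'
#' @param model A `bud_model`.
#' @param rows Feature rows matching the model's training schema.
#' @param per_tree If `TRUE`, attach the per-tree prediction matrix as the
#'   `per_tree` attribute of the result.
#' @return Tibble with columns `bud_days` and `stderr_days`, one row per
#'   input row.
#' @export
predict_bud <- function(model, rows, per_tree = FALSE) {
  stopifnot(inherits(model, "bud_model"))
  missing <- setdiff(model$schema, names(rows))
  extra <- setdiff(names(rows), c(model$schema, "bud_days"))
  if (length(missing) > 0 || length(extra) > 0) {
    abort(sprintf(
      "feature schema mismatch: missing [%s]; unexpected [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
      class = "bud_predict_error")
  }
  x <- feature_matrix(rows, model$schema)
  df <- as.data.frame(x)
  n <- nrow(df)
  tree_preds <- NULL

  if (model$engine == "constant") {
    est <- rep(model$fit, n)
    se <- rep(0, n)
  } else if (model$engine == "rpart") {
    est <- unname(predict(model$fit, newdata = df))
    se <- rep(0, n)
  } else if (model$engine == "randomForest") {
    pr <- predict(model$fit, newdata = df, predict.all = TRUE)
    if (model$fit$type == "classification") {
      tree_preds <- matrix(as.numeric(pr$individual), nrow = n)
      est <- majority_label(tree_preds)
    } else {
      tree_preds <- pr$individual
      est <- unname(pr$aggregate)
    }
    se <- apply(tree_preds, 1, sd) / sqrt(ncol(tree_preds))
  } else if (model$engine == "ranger") {
    pr_all <- predict(model$fit, data = df, predict.all = TRUE,
                      num.threads = 1)$predictions
    if (model$fit$treetype == "Classification") {
      lev <- as.numeric(as.character(model$fit$forest$levels))
      tree_preds <- matrix(lev[pr_all], nrow = n)
      est <- majority_label(tree_preds)
    } else {
      tree_preds <- pr_all
      est <- rowMeans(tree_preds)
    }
    se <- apply(tree_preds, 1, sd) / sqrt(ncol(tree_preds))
  } else if (model$engine == "xgboost") {
    booster <- xgboost::xgb.load.raw(model$fit)
    raw <- predict(booster, newdata = xgboost::xgb.DMatrix(x, nthread = 1))
    est <- if (grepl("classifier", model$family)) {
      model$levels_num[as.integer(raw) + 1L]
    } else {
      as.numeric(raw)
    }
    se <- rep(0, n)
  }
  out <- tibble::tibble(bud_days = as.numeric(est),
                        stderr_days = as.numeric(se))
  if (per_tree && !is.null(tree_preds)) attr(out, "per_tree") <- tree_preds
  out
}

#' Save / load a fitted BUD model
#'
#' Persists the model as a self-describing versioned RDS file (family,
#' feature schema, seed, hyperparameters, engine payload). A reloaded model
#' reproduces the original predictions exactly.
#'
#' @param model A `bud_model`.
#' @param path File path.
#' @return `save_bud_model()` invisibly returns `path`; `load_bud_model()`
#'   returns the restored `bud_model`.
#' @export
save_bud_model <- function(model, path) {
  stopifnot(inherits(model, "bud_model"))
  payload <- list(format = "budpredict-model", version = 1L,
                  model = unclass(model))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_bud_model
#' @export
load_bud_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "budpredict-model")) {
    abort("not a budpredict model file", class = "bud_io_error")
  }
  structure(payload$model, class = "bud_model")
}
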