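#' Fit the feature preprocessor on training rows
#'
#' Drops feature columns with variance strictly below `min_variance`
#' (computed on the training rows only; a column at exactly the threshold is
#' kept) and stores per-column means and standard deviations for
#' standardization. Missing values (the rank feature of crystal poses) are
#' ignored in the statistics and preserved by the transform.
#'
#' @param train_rows dataset table from [assemble_features()].
#' @param min_variance variance threshold (default 0.01).
#' @return object of class `pose_preprocessor`.
#' @export
fit_preprocessor <- function(train_rows, min_variance = 0.01) {
  fc <- feature_columns(train_rows)
  if (nrow(train_rows) < 2) stop("fit_preprocessor: need at least 2 rows")
  X <- as.matrix(train_rows[, fc, drop = FALSE])
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  keep <- fc[v >= min_variance]
  if (length(keep) == 0) stop("fit_preprocessor: all features filtered out")
  mu <- colMeans(X[, keep, drop = FALSE], na.rm = TRUE)
  sd_ <- apply(X[, keep, drop = FALSE], 2, stats::sd, na.rm = TRUE)
  structure(list(features = keep, mean = mu, sd = sd_,
                 min_variance = min_variance),
            class = "pose_preprocessor")
}

#' Apply a fitted preprocessor
#' @param pre `pose_preprocessor`.
#' @param rows dataset table.
#' @return numeric matrix of standardized kept features.
#' @export
apply_preprocessor <- function(pre, rows) {
  miss <- setdiff(pre$features, names(rows))
  if (length(miss) > 0)
    stop("apply_preprocessor: rows lack feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- as.matrix(rows[, pre$features, drop = FALSE])
  sweep(sweep(X, 2, pre$mean), 2, pre$sd, "/")
}

# documented hyperparameter search space
.search_space <- list(
  max_depth = function(u) 3L + as.integer(floor(u * 8)),  # 3..10
  eta = function(u) 10^(-3 + u * 2.5),
  nrounds = function(u) 100L + as.integer(floor(u * 901)),
  subsample = function(u) 0.5 + 0.5 * u,
  colsample_bytree = function(u) 0.5 + 0.5 * u,
  min_child_weight = function(u) 1 + 9 * u,
  gamma = function(u) 5 * u,
  lambda = function(u) 10^(-2 + 3 * u)
)

sample_config <- function() {
  u <- stats::runif(length(.search_space))
  cfg <- Map(function(f, ui) f(ui), .search_space, u)
  cfg$max_depth <- min(cfg$max_depth, 10L)
  cfg
}

# grouped fold assignment: complexes, not poses, define CV folds
grouped_folds <- function(complex_ids, k) {
  ids <- unique(complex_ids)
  shuffled <- sample(ids)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ids)), shuffled)
  unname(fold_of[complex_ids])
}

xgb_params <- function(cfg, task, seed) {
  list(objective = if (task == "classify") "binary:logistic" else "reg:squarederror",
       max_depth = cfg$max_depth, eta = cfg$eta, subsample = cfg$subsample,
       colsample_bytree = cfg$colsample_bytree,
       min_child_weight = cfg$min_child_weight, gamma = cfg$gamma,
       lambda = cfg$lambda, nthread = 1, seed = seed)
}

#' Train the boosted-tree pose model with hyperparameter search
#'
#' Preprocesses the training table (variance filter + standardization fitted
#' on training rows only), then selects hyperparameters by seeded random
#' search over a fixed documented space, scoring each configuration by
#' grouped fivefold cross-validation: folds are partitioned by complex, not
#' by pose, so poses of one complex never straddle a fold boundary. The
#' classification objective is mean CV AUROC; the regression objective
#' (`task = "regress"`, target = RMSD) is mean CV RMSE. The final model is
#' refit on all training rows with the best configuration. Seeds are fixed
#' (2399 for the booster, 123 for the tuner) so runs are reproducible.
#'
#' @param train_rows dataset table from [assemble_features()].
#' @param task "classify" (near-native probability) or "regress" (RMSD).
#' @param max_evals number of search evaluations (default 60).
#' @param cv_folds number of grouped CV folds (default 5).
#' @param model_seed,tuner_seed fixed seeds.
#' @param min_variance preprocessor variance threshold.
#' @return object of class `pose_model` with the fitted booster,
#'   preprocessor, chosen hyperparameters and tuning history.
#' @export
tune_and_train <- function(train_rows, task = c("classify", "regress"),
                           max_evals = 60L, cv_folds = 5L,
                           model_seed = 2399L, tuner_seed = 123L,
                           min_variance = 0.01) {
  task <- match.arg(task)
  y <- if (task == "classify") as.numeric(train_rows$label == "positive")
       else train_rows$rmsd
  if (task == "classify" && length(unique(y)) < 2)
    stop("tune_and_train: training data contain a single class")
  if (length(unique(train_rows$complex_id)) < cv_folds)
    stop("tune_and_train: need at least ", cv_folds, " distinct complexes")
  pre <- fit_preprocessor(train_rows, min_variance)
  X <- apply_preprocessor(pre, train_rows)
  uses_rank <- "RANK__dock_rank" %in% pre$features

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tuner_seed)
  folds <- grouped_folds(train_rows$complex_id, cv_folds)
  configs <- lapply(seq_len(max_evals), function(i) sample_config())

  cv_score <- function(cfg) {
    per_fold <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (task == "classify" && length(unique(y[te])) < 2) return(NA_real_)
      bst <- xgboost::xgb.train(params = xgb_params(cfg, task, model_seed),
                                data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                                            label = y[tr]),
                                nrounds = cfg$nrounds, verbose = 0)
      p <- stats::predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
      if (task == "classify") auroc(p, y[te] == 1)
      else -sqrt(mean((p - y[te])^2))
    }, numeric(1))
    mean(per_fold, na.rm = TRUE)
  }
  scores <- vapply(configs, cv_score, numeric(1))
  best <- which.max(scores)
  cfg <- configs[[best]]
  bst <- xgboost::xgb.train(params = xgb_params(cfg, task, model_seed),
                            data = xgboost::xgb.DMatrix(X, label = y),
                            nrounds = cfg$nrounds, verbose = 0)
  history <- cbind(data.frame(eval = seq_len(max_evals), score = scores),
                   do.call(rbind, lapply(configs, as.data.frame)))
  structure(list(booster = bst, preprocessor = pre, hyperparameters = cfg,
                 history = history, task = task, uses_rank = uses_rank,
                 seeds = c(model = model_seed, tuner = tuner_seed)),
            class = "pose_model")
}

#' Train an RMSD regressor
#' @inheritParams tune_and_train
#' @return `pose_model` with task "regress"; predictions are clipped at 0.
#' @export
train_regressor <- function(train_rows, max_evals = 60L, cv_folds = 5L,
                            model_seed = 2399L, tuner_seed = 123L) {
  tune_and_train(train_rows, task = "regress", max_evals = max_evals,
                 cv_folds = cv_folds, model_seed = model_seed,
                 tuner_seed = tuner_seed)
}

#' @export
print.pose_model <- function(x, ...) {
  cat(sprintf("pose_model (%s): %d features kept, best CV score %.4f\n",
              x$task, length(x$preprocessor$features),
              max(x$history$score, na.rm = TRUE)))
  invisible(x)
}

#' Score poses with a trained model
#'
#' Classification models return the probability that a pose is near-native
#' (higher = better pose); regression models return predicted RMSD in
#' Angstrom, clipped at 0. Models whose kept features include the docking
#' rank refuse rows with missing ranks (crystal poses, pooled multi-program
#' sets) rather than imputing silently.
#'
#' @param object `pose_model`.
#' @param rows dataset table conforming to the model schema.
#' @param ... unused.
#' @return numeric scores, one per row.
#' @export
predict.pose_model <- function(object, rows, ...) {
  if (object$uses_rank && anyNA(rows$RANK__dock_rank))
    stop("predict.pose_model: model uses the rank feature but ",
         sum(is.na(rows$RANK__dock_rank)),
         " row(s) lack a docking rank; use a rank-free model for such sets")
  X <- apply_preprocessor(object$preprocessor, rows)
  p <- stats::predict(object$booster, xgboost::xgb.DMatrix(X))
  if (object$task == "regress") pmax(p, 0) else p
}

#' Save / load a trained pose model bundle
#'
#' The bundle stores the serialized booster together with the preprocessor,
#' hyperparameters, seeds and tuning history in one file.
#'
#' @param model `pose_model`.
#' @param path output file (.rds).
#' @export
save_model <- function(model, path) {
  obj <- model
  obj$booster_raw <- xgboost::xgb.save.raw(model$booster)
  obj$booster <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return `pose_model`
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  obj$booster <- xgboost::xgb.load.raw(obj$booster_raw)
  obj$booster_raw <- NULL
  structure(obj, class = "pose_model")
}
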