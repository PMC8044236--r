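#' Default hyperparameter grids for the sub-model algorithms
#'
#' RF: number of trees x maximum depth (0 = unlimited). SVM: RBF kernel,
#' cost x kernel width, where width `"scale"` resolves to `1/p` for p
#' features. BP: one hidden layer, hidden units x L2 weight decay, trained
#' by backpropagation to a fixed iteration cap.
#'
#' @param algorithm `"rf"`, `"svm"` or `"bp"`
#' @return data.frame, one row per grid point
#' @export
default_grid <- function(algorithm = c("rf", "svm", "bp")) {
  switch(match.arg(algorithm),
    rf = expand.grid(num_trees = c(100L, 300L, 500L),
                     max_depth = c(0L, 10L, 20L)),
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c("scale", "0.01", "0.1"),
                      stringsAsFactors = FALSE),
    bp = expand.grid(size = c(32L, 64L, 128L),
                     decay = c(1e-4, 1e-3))
  )
}

#' Sub-model specification
#'
#' @param algorithm `"rf"` (random forest), `"svm"` (RBF support-vector
#'   classifier with Platt-calibrated probabilities) or `"bp"`
#'   (single-hidden-layer feed-forward network, logistic output,
#'   cross-entropy loss)
#' @param grid hyperparameter grid, one row per configuration (default
#'   [default_grid()])
#' @param cv_folds cross-validation folds (default 5)
#' @param seed integer seed; fitting is fully deterministic given it
#' @param threshold decision threshold on scores (default 0.5)
#' @param maxit iteration cap for the BP network (default 200)
#' @return a `submodel_spec`
#' @export
submodel_spec <- function(algorithm = c("rf", "svm", "bp"), grid = NULL,
                          cv_folds = 5L, seed = 1L, threshold = 0.5,
                          maxit = 200L) {
  algorithm <- match.arg(algorithm)
  grid <- grid %||% default_grid(algorithm)
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop_mutafuse("hyperparameter grid must be a non-empty data.frame",
                  "mutafuse_spec_error")
  }
  if (cv_folds < 2) {
    stop_mutafuse("cv_folds must be >= 2", "mutafuse_spec_error")
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop_mutafuse("threshold must be in (0, 1)", "mutafuse_spec_error")
  }
  spec <- list(algorithm = algorithm, grid = grid,
               cv_folds = as.integer(cv_folds), seed = as.integer(seed),
               threshold = threshold, maxit = as.integer(maxit))
  class(spec) <- "submodel_spec"
  spec
}

# Fit one configuration. Returns a model bundle carrying everything
# predict_scores needs (including the feature schema).
fit_submodel <- function(X, y, algorithm, params, seed, maxit = 200L) {
  if (length(unique(y)) < 2) {
    stop_mutafuse("labels are single-class; cannot fit",
                  "mutafuse_degenerate_label_error")
  }
  fit <- withr::with_seed(seed, switch(algorithm,
    rf = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      probability = TRUE, num.trees = params$num_trees,
      max.depth = params$max_depth, seed = seed, num.threads = 1),
    svm = e1071::svm(
      x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
      cost = params$cost, gamma = resolve_gamma(params$gamma, ncol(X)),
      probability = TRUE, scale = FALSE),
    bp = nnet::nnet(
      x = X, y = y, size = params$size, decay = params$decay,
      entropy = TRUE, maxit = maxit, trace = FALSE, MaxNWts = 200000L)
  ))
  bundle <- list(algorithm = algorithm, fit = fit, params = params,
                 feature_names = colnames(X), seed = seed)
  class(bundle) <- "mutafuse_model"
  bundle
}

resolve_gamma <- function(gamma, p) {
  if (identical(gamma, "scale")) 1 / p else as.numeric(gamma)
}

#' Predict positive-class scores in [0, 1]
#'
#' RF returns the forest's positive-class vote fraction, SVM the
#' Platt-calibrated positive-class probability, BP the logistic output
#' activation.
#'
#' @param model a fitted model bundle from [grid_search_fit()] (field
#'   `model`) or `fit_submodel`
#' @param X feature matrix with exactly the model's feature columns, in
#'   order
#' @return numeric scores in [0, 1]
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "mutafuse_model"))
  if (!identical(colnames(X), model$feature_names)) {
    stop_mutafuse("feature columns do not match the model's training schema",
                  "mutafuse_schema_error")
  }
  s <- switch(model$algorithm,
    rf = predict(model$fit, data = as.data.frame(X),
                 num.threads = 1)$predictions[, "1"],
    svm = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    bp = as.numeric(predict(model$fit, X))
  )
  pmin(pmax(unname(s), 0), 1)
}

# Stratified k-fold assignment; deterministic given seed. Callers pass data
# in canonical (compound-id-sorted) order so fold membership is row-order
# invariant. If a fold ends up single-class it is redrawn once, then errors.
make_cv_folds <- function(y, k, seed) {
  draw <- function(s) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- withr::with_seed(s, sample(idx))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  fold <- draw(seed)
  bad <- any(vapply(seq_len(k), function(f)
    length(unique(y[fold != f])) < 2 || sum(fold == f) == 0, logical(1)))
  if (bad) {
    warning("a fold was degenerate; redrawing once")
    fold <- draw(seed + 1L)
    bad <- any(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) < 2 || sum(fold == f) == 0, logical(1)))
    if (bad) {
      stop_mutafuse("cannot form cross-validation folds with both classes",
                    "mutafuse_degenerate_label_error")
    }
  }
  fold
}

#' Cross-validated accuracy Q for one configuration
#'
#' Stratified k-fold cross-validation; Q is the pooled out-of-fold accuracy
#' (the robustness criterion). Folds and all fitting are deterministic given
#' the seed.
#'
#' @param X feature matrix
#' @param y binary labels
#' @param algorithm,params,threshold,maxit as in [submodel_spec()] /
#'   `fit_submodel`
#' @param cv_folds number of folds
#' @param seed integer seed
#' @return list with `Q` (pooled accuracy), `fold_accuracy`, `oof_scores`,
#'   `oof_decisions`, `fold`
#' @export
cross_validate <- function(X, y, algorithm, params, cv_folds = 5L, seed = 1L,
                           threshold = 0.5, maxit = 200L) {
  fold <- make_cv_folds(y, cv_folds, seed)
  oof <- numeric(length(y))
  fold_acc <- numeric(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    m <- fit_submodel(X[tr, , drop = FALSE], y[tr], algorithm, params,
                      seed = seed + f, maxit = maxit)
    oof[!tr] <- predict_scores(m, X[!tr, , drop = FALSE])
    fold_acc[f] <- mean(as.integer(oof[!tr] >= threshold) == y[!tr])
  }
  decisions <- as.integer(oof >= threshold)
  list(Q = mean(decisions == y), fold_accuracy = fold_acc,
       oof_scores = oof, oof_decisions = decisions, fold = fold)
}

#' Grid search with five-fold cross-validation
#'
#' Exhaustively scores every grid row by pooled CV accuracy Q, picks the
#' best (ties resolved by grid order), and refits that configuration on the
#' full training data. Both the CV accuracy of the winning configuration
#' and the resubstitution (training) accuracy are reported, labelled.
#'
#' @param X training feature matrix (restricted to the selected features)
#' @param y binary training labels, both classes present
#' @param spec a [submodel_spec()]
#' @return a `submodel_result`: list with `algorithm`, `best_params`,
#'   `model` (bundle), `cv_accuracy` (Q of the winner), `fold_accuracy`,
#'   `grid_Q` (Q per grid row), `train_scores`, `train_decisions`,
#'   `train_accuracy` (resubstitution), `threshold`
#' @export
grid_search_fit <- function(X, y, spec) {
  stopifnot(inherits(spec, "submodel_spec"))
  if (length(unique(y)) < 2) {
    stop_mutafuse("labels are single-class; cannot fit",
                  "mutafuse_degenerate_label_error")
  }
  grid_Q <- numeric(nrow(spec$grid))
  cvs <- vector("list", nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    cvs[[i]] <- cross_validate(X, y, spec$algorithm,
                               as.list(spec$grid[i, , drop = FALSE]),
                               spec$cv_folds, spec$seed, spec$threshold,
                               spec$maxit)
    grid_Q[i] <- cvs[[i]]$Q
  }
  best <- which.max(grid_Q)  # first max wins: deterministic tie-break
  model <- fit_submodel(X, y, spec$algorithm,
                        as.list(spec$grid[best, , drop = FALSE]),
                        seed = spec$seed, maxit = spec$maxit)
  train_scores <- predict_scores(model, X)
  train_decisions <- as.integer(train_scores >= spec$threshold)
  res <- list(algorithm = spec$algorithm,
              best_params = as.list(spec$grid[best, , drop = FALSE]),
              model = model,
              cv_accuracy = grid_Q[best],
              fold_accuracy = cvs[[best]]$fold_accuracy,
              grid_Q = grid_Q,
              train_scores = train_scores,
              train_decisions = train_decisions,
              train_accuracy = mean(train_decisions == y),
              threshold = spec$threshold)
  class(res) <- "submodel_result"
  res
}

#' Write long-format sub-model predictions
#'
#' One row per compound x endpoint: score, decision and split, for one
#' algorithm family's three sub-models.
#'
#' @param sub_results output of [train_endpoint_models()]
#' @param path CSV output path
#' @return invisibly, `path`
#' @export
write_submodel_predictions <- function(sub_results, path) {
  rows <- lapply(c("Y1", "Y2", "Y3"), function(ep) {
    sm <- sub_results[[ep]]
    data.frame(
      compound_id = c(sm$train_ids, sm$test_ids),
      endpoint = ep,
      algorithm = sm$algorithm,
      score = c(sm$train_scores, sm$test_scores),
      decision = c(sm$train_decisions, sm$test_decisions),
      split = c(rep("train", length(sm$train_ids)),
                rep("test", length(sm$test_ids))),
      stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Train the three per-endpoint sub-models for one algorithm family
#'
#' @param ds split `modeling_dataset`
#' @param features integer indices of the selected features
#' @param spec a [submodel_spec()]
#' @return named list (Y1, Y2, Y3) of `submodel_result`s, each augmented
#'   with test-split scores/decisions, test metrics and test AUC
#' @export
train_endpoint_models <- function(ds, features, spec) {
  stopifnot(inherits(ds, "modeling_dataset"))
  out <- list()
  for (ep in c("Y1", "Y2", "Y3")) {
    tr <- dataset_xy(ds, ep, split = "train", features = features)
    te <- dataset_xy(ds, ep, split = "test", features = features)
    sm <- grid_search_fit(tr$X, tr$y, spec)
    sm$endpoint <- ep
    sm$train_ids <- tr$ids
    sm$test_ids <- te$ids
    sm$test_scores <- predict_scores(sm$model, te$X)
    sm$test_decisions <- as.integer(sm$test_scores >= spec$threshold)
    sm$test_metrics <- per_class_metrics(te$y, sm$test_decisions)
    sm$test_auc <- if (length(unique(te$y)) == 2) {
      roc_auc(te$y, sm$test_scores)$auc
    } else NA_real_
    out[[ep]] <- sm
  }
  out
}
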