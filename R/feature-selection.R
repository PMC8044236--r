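#' Specification of the SHAP backing classifier
#'
#' The per-endpoint global importances are mean absolute SHAP attributions
#' of a tree-ensemble classifier fitted to the training split. The default
#' backing model is a random forest (bagged trees, per-node feature
#' subsampling at the classification default sqrt(p)/p), fitted through
#' xgboost in its parallel-tree mode so attributions come from exact
#' tree-path SHAP; a boosted-trees backing is available as an alternative.
#'
#' @param model `"random_forest"` (default) or `"boosted_trees"`
#' @param num_trees ensemble size (default 300)
#' @param max_depth per-tree depth cap (default 8)
#' @param subsample row subsampling per tree (default 0.632, the bootstrap
#'   expectation)
#' @param nrounds boosting rounds, boosted mode only (default 50)
#' @return a `shap_backing_spec` list
#' @export
shap_backing_spec <- function(model = c("random_forest", "boosted_trees"),
                              num_trees = 300L, max_depth = 8L,
                              subsample = 0.632, nrounds = 50L) {
  spec <- list(model = match.arg(model), num_trees = as.integer(num_trees),
               max_depth = as.integer(max_depth), subsample = subsample,
               nrounds = as.integer(nrounds))
  class(spec) <- "shap_backing_spec"
  spec
}

#' Per-endpoint SHAP importance ranking of fingerprint bits
#'
#' Fits the backing classifier on the supplied training data only, computes
#' per-compound per-feature SHAP attributions, aggregates to the mean
#' absolute value per feature (the standard global importance; signed means
#' are stored alongside for inspection), and ranks features by descending
#' importance with ties broken by ascending feature index.
#'
#' A constant feature can never be split on, so its attribution — and hence
#' its importance — is exactly zero.
#'
#' @param X_train binary feature matrix (training split)
#' @param y_endpoint binary endpoint labels, both classes present
#' @param spec backing model, see [shap_backing_spec()]
#' @param seed integer seed; the ranking is deterministic given the seed
#' @return a `feature_ranking`: list with `importance` (named, length p),
#'   `signed_mean`, and `order` (a permutation of 1..p, most important
#'   first)
#' @export
shap_importance <- function(X_train, y_endpoint, spec = shap_backing_spec(),
                            seed = 1L) {
  if (length(unique(y_endpoint)) < 2) {
    stop_mutafuse("endpoint labels are single-class; cannot rank features",
                  "mutafuse_degenerate_label_error")
  }
  if (nrow(X_train) != length(y_endpoint)) {
    stop_mutafuse("X_train rows and labels differ in length",
                  "mutafuse_alignment_error")
  }
  p <- ncol(X_train)
  # canonical row order so the ranking is invariant to input row order
  ord <- order(rownames(X_train) %||% seq_len(nrow(X_train)))
  X <- X_train[ord, , drop = FALSE]
  y <- y_endpoint[ord]
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- if (spec$model == "random_forest") {
    list(objective = "binary:logistic", eta = 1, max_depth = spec$max_depth,
         subsample = spec$subsample, colsample_bynode = sqrt(p) / p,
         num_parallel_tree = spec$num_trees, nthread = 1,
         seed = as.integer(seed))
  } else {
    list(objective = "binary:logistic", eta = 0.1, max_depth = spec$max_depth,
         subsample = spec$subsample, nthread = 1, seed = as.integer(seed))
  }
  nrounds <- if (spec$model == "random_forest") 1L else spec$nrounds
  fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                            verbose = 0)
  contrib <- predict(fit, dtrain, predcontrib = TRUE)
  contrib <- contrib[, seq_len(p), drop = FALSE]  # drop the BIAS column
  importance <- colMeans(abs(contrib))
  signed <- colMeans(contrib)
  names(importance) <- names(signed) <- colnames(X_train)
  ranking <- list(
    importance = importance,
    signed_mean = signed,
    order = order(-importance, seq_len(p))
  )
  class(ranking) <- "feature_ranking"
  ranking
}

#' First fraction of a feature ranking
#'
#' @param ranking a [shap_importance()] result
#' @param fraction fraction in (0, 1]; the first quintile of 881 bits is
#'   `floor(881 * 0.2) = 176` features
#' @return integer vector of feature indices (most important first)
#' @export
top_fraction <- function(ranking, fraction = 0.2) {
  if (!(fraction > 0 && fraction <= 1)) {
    stop_mutafuse("fraction must be in (0, 1]", "mutafuse_spec_error")
  }
  k <- floor(length(ranking$order) * fraction)
  ranking$order[seq_len(k)]
}

#' Intersect the three per-endpoint top sets
#'
#' The selected descriptor set is the intersection of the three top sets,
#' ordered by descending mean importance across the three rankings (ties by
#' ascending feature index). An empty intersection yields a warning and an
#' empty selection; the caller decides how to proceed.
#'
#' @param top_sets list of three integer index sets (Y1, Y2, Y3)
#' @param rankings list of the three corresponding [shap_importance()]
#'   rankings
#' @return list with `selected` (ordered indices), `mean_importance` over
#'   the selected features, `top_sets` and `rankings`
#' @export
intersect_rankings <- function(top_sets, rankings) {
  stopifnot(length(top_sets) == 3, length(rankings) == 3)
  sel <- Reduce(intersect, top_sets)
  if (length(sel) == 0) {
    warning("empty intersection of the three top feature sets")
    return(list(selected = integer(0), mean_importance = numeric(0),
                top_sets = top_sets, rankings = rankings))
  }
  imp <- rowMeans(vapply(rankings, function(r) r$importance[sel],
                         numeric(length(sel))))
  o <- order(-imp, sel)
  list(selected = sel[o], mean_importance = imp[o],
       top_sets = top_sets, rankings = rankings)
}

#' Cross-endpoint SHAP-quintile feature selection
#'
#' Runs [shap_importance()] for each endpoint on the training split,
#' takes each ranking's first `fraction` (default the first quintile), and
#' intersects the three top sets. Selection never sees the test split.
#'
#' @param ds a split `modeling_dataset`
#' @param fraction top fraction per endpoint (default 0.2)
#' @param spec backing model, see [shap_backing_spec()]
#' @param seed integer seed
#' @return a `feature_selection_result`: list with `rankings` (per
#'   endpoint), `top_sets`, `selected` (indices), `selected_names`,
#'   `fraction`, `seed`
#' @export
select_features <- function(ds, fraction = 0.2, spec = shap_backing_spec(),
                            seed = 1L) {
  stopifnot(inherits(ds, "modeling_dataset"))
  if (is.null(ds$split)) {
    stop_mutafuse("dataset has no split assigned", "mutafuse_spec_error")
  }
  endpoints <- c("Y1", "Y2", "Y3")
  rankings <- lapply(endpoints, function(ep) {
    xy <- dataset_xy(ds, ep, split = "train")
    shap_importance(xy$X, xy$y, spec, seed)
  })
  names(rankings) <- endpoints
  top_sets <- lapply(rankings, top_fraction, fraction = fraction)
  inter <- intersect_rankings(top_sets, rankings)
  res <- list(rankings = rankings, top_sets = top_sets,
              selected = inter$selected,
              selected_names = colnames(ds$fingerprints)[inter$selected],
              mean_importance = inter$mean_importance,
              fraction = fraction, seed = as.integer(seed))
  class(res) <- "feature_selection_result"
  res
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf(
    "<feature_selection_result> %d features selected (top %.0f%% of %d per endpoint)\n",
    length(x$selected), 100 * x$fraction, length(x$rankings$Y1$importance)))
  if (length(x$selected) > 0) {
    cat("  leading bits:", paste(head(x$selected_names, 8), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write per-endpoint rankings and the selected-feature list
#'
#' Rankings go to one CSV per endpoint (feature, importance, rank); the
#' selected features to a plain-text file, one fingerprint name per line in
#' descending mean-importance order.
#'
#' @param fs a [select_features()] result
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_feature_selection <- function(fs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ep in names(fs$rankings)) {
    r <- fs$rankings[[ep]]
    df <- data.frame(feature = names(r$importance)[r$order],
                     importance = unname(r$importance[r$order]),
                     rank = seq_along(r$order))
    p <- file.path(dir, sprintf("ranking_%s.csv", ep))
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  sel_path <- file.path(dir, "selected_features.txt")
  writeLines(fs$selected_names, sel_path)
  invisible(c(paths, sel_path))
}

#' Bar plot of the top-ranked fingerprint bits for one endpoint
#'
#' @param fs a [select_features()] result
#' @param endpoint `"Y1"`, `"Y2"` or `"Y3"`
#' @param n_top number of bits to show (default 20)
#' @return a ggplot object
#' @export
plot_top_importance <- function(fs, endpoint = "Y1", n_top = 20) {
  r <- fs$rankings[[endpoint]]
  idx <- r$order[seq_len(n_top)]
  df <- data.frame(feature = factor(names(r$importance)[idx],
                                    levels = rev(names(r$importance)[idx])),
                   importance = unname(r$importance[idx]))
  ggplot2::ggplot(df, ggplot2::aes(x = importance, y = feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL,
                  title = sprintf("Top %d fingerprint bits (%s)", n_top,
                                  endpoint)) +
    ggplot2::theme_minimal()
}
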