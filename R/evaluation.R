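#' Confusion counts for binary predictions
#'
#' Positive class is 1. `TP + TN + FP + FN` equals the number of evaluated
#' compounds.
#'
#' @param y_true,y_pred equal-length 0/1 vectors
#' @return list of class `confusion_counts` with TP, TN, FP, FN
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_mutafuse("y_true and y_pred must have equal length",
                  "mutafuse_alignment_error")
  }
  if (!is_binary(y_true) || !is_binary(y_pred)) {
    stop_mutafuse("labels and predictions must be 0/1",
                  "mutafuse_parse_error")
  }
  out <- list(TP = sum(y_true == 1 & y_pred == 1),
              TN = sum(y_true == 0 & y_pred == 0),
              FP = sum(y_true == 0 & y_pred == 1),
              FN = sum(y_true == 1 & y_pred == 0))
  class(out) <- "confusion_counts"
  out
}

#' Accuracy Q = (TP + TN) / (TP + FP + FN + TN)
#' @param counts a [confusion()] result
#' @return accuracy in [0, 1]; `NA` when no compounds were evaluated
#' @export
metric_accuracy <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) return(NA_real_)
  (counts$TP + counts$TN) / n
}

#' Precision = TP / (TP + FP)
#' @param counts a [confusion()] result
#' @return precision in [0, 1]; `NA` (undefined) when nothing was predicted
#'   positive
#' @export
metric_precision <- function(counts) {
  d <- counts$TP + counts$FP
  if (d == 0) return(NA_real_)
  counts$TP / d
}

#' Recall = TP / (TP + FN)
#' @param counts a [confusion()] result
#' @return recall in [0, 1]; `NA` (undefined) when there are no positives
#' @export
metric_recall <- function(counts) {
  d <- counts$TP + counts$FN
  if (d == 0) return(NA_real_)
  counts$TP / d
}

#' F1 = 2 * precision * recall / (precision + recall)
#'
#' The harmonic mean of precision and recall. Undefined (NA) when either
#' input is undefined or both are zero; never reported as 0 or 1 in that
#' case.
#'
#' @param precision,recall rates in [0, 1]
#' @return F1 in [0, 1] or `NA`
#' @export
metric_f1 <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Per-class precision, recall and F1 plus shared accuracy
#'
#' The negative-class block is computed by treating 0 as the class of
#' interest (relabeling both vectors), matching report tables whose +/-
#' columns give each indicator for positive and non-positive outcomes.
#'
#' @param y_true,y_pred equal-length 0/1 vectors
#' @return list with `accuracy`, `counts`, and `positive` / `negative`
#'   blocks each holding precision, recall, f1
#' @export
per_class_metrics <- function(y_true, y_pred) {
  cts <- confusion(y_true, y_pred)
  neg <- confusion(1 - y_true, 1 - y_pred)
  block <- function(cc) {
    p <- metric_precision(cc); r <- metric_recall(cc)
    list(precision = p, recall = r, f1 = metric_f1(p, r))
  }
  list(accuracy = metric_accuracy(cts),
       counts = cts,
       positive = block(cts),
       negative = block(neg))
}

#' ROC curve and AUC by the midrank (Mann-Whitney) method
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with ties counted half — the Wilcoxon/Mann-Whitney statistic,
#' identical to the trapezoidal area under the empirical ROC curve. Curve
#' points are produced at every distinct score threshold.
#'
#' @param y_true 0/1 labels
#' @param scores numeric scores in [0, 1] (higher = more positive)
#' @return list with `auc` and `roc` (data.frame threshold, fpr, tpr);
#'   `auc` is `NA` with a warning when only one class is present
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop_mutafuse("labels and scores must have equal length",
                  "mutafuse_alignment_error")
  }
  if (!is_binary(y_true)) {
    stop_mutafuse("labels must be 0/1", "mutafuse_parse_error")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop_mutafuse("scores must lie in [0, 1]", "mutafuse_parse_error")
  }
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) if (n0 == 0) NA_real_ else
      sum(scores[y_true == 0] >= t) / n0, numeric(1)),
    tpr = vapply(thr, function(t) if (n1 == 0) NA_real_ else
      sum(scores[y_true == 1] >= t) / n1, numeric(1))
  )
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(list(auc = NA_real_, roc = roc))
  }
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, roc = roc)
}

# One flat report row; used by render_reports.
metrics_row <- function(algorithm, model, split, m, auc = NA_real_) {
  data.frame(algorithm = algorithm, model = model, split = split,
             recall_pos = m$positive$recall, recall_neg = m$negative$recall,
             precision_pos = m$positive$precision,
             precision_neg = m$negative$precision,
             f1_pos = m$positive$f1, f1_neg = m$negative$f1,
             accuracy = m$accuracy, auc = auc,
             stringsAsFactors = FALSE)
}

#' Assemble the report tables from a pipeline result
#'
#' Produces the accuracy comparison table (per algorithm: Y1/Y2/Y3
#' sub-models and the fusion model, training CV and test accuracy) and the
#' full indicator table (per-class recall/precision/F1, accuracy and AUC on
#' the test set), both as deterministic data.frames, printed to 3 decimals
#' (half-up) when serialized.
#'
#' @param result a [run_pipeline()] result
#' @return list with `accuracy_table` and `indicator_table`
#' @export
render_reports <- function(result) {
  acc <- list(); ind <- list()
  for (alg in names(result$models)) {
    for (ep in c("Y1", "Y2", "Y3")) {
      sm <- result$models[[alg]][[ep]]
      acc[[length(acc) + 1]] <- data.frame(
        algorithm = alg, model = ep,
        train_cv_accuracy = sm$cv_accuracy,
        train_accuracy = sm$train_accuracy,
        test_accuracy = sm$test_metrics$accuracy,
        stringsAsFactors = FALSE)
      ind[[length(ind) + 1]] <- metrics_row(alg, ep, "test", sm$test_metrics,
                                            sm$test_auc)
    }
    fu <- result$fusion[[alg]]
    acc[[length(acc) + 1]] <- data.frame(
      algorithm = alg, model = "fusion",
      train_cv_accuracy = fu$train_metrics$accuracy,
      train_accuracy = fu$train_metrics$accuracy,
      test_accuracy = fu$test_metrics$accuracy,
      stringsAsFactors = FALSE)
    ind[[length(ind) + 1]] <- metrics_row(alg, "fusion", "test",
                                          fu$test_metrics, fu$test_auc)
  }
  list(accuracy_table = do.call(rbind, acc),
       indicator_table = do.call(rbind, ind))
}

#' Write report tables to CSV/JSON
#'
#' @param reports output of [render_reports()]
#' @param dir output directory
#' @param digits printed precision (tables round half-up to 3 decimals)
#' @return invisibly, the written paths
#' @export
write_reports <- function(reports, dir, digits = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round_half_up, digits = digits)
    df
  }
  p1 <- file.path(dir, "accuracy_table.csv")
  p2 <- file.path(dir, "indicator_table.csv")
  p3 <- file.path(dir, "reports.json")
  write.csv(fmt(reports$accuracy_table), p1, row.names = FALSE, quote = FALSE)
  write.csv(fmt(reports$indicator_table), p2, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(reports, fmt), p3, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Plot ROC curves
#'
#' @param roc_list named list of `roc` data.frames from [roc_auc()]
#' @param title plot title
#' @return a ggplot object
#' @export
plot_roc <- function(roc_list, title = "ROC") {
  df <- do.call(rbind, lapply(names(roc_list), function(nm) {
    cbind(model = nm, roc_list[[nm]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, colour = model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = title) +
    ggplot2::theme_minimal()
}
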