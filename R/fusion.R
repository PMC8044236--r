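#' Weight-of-evidence fusion of the three endpoint decisions
#'
#' All-negative is judged negative, otherwise positive: the logical OR of
#' the three sub-model decisions. One positive result leads to a final
#' positive result; only when all results are non-positive is the final
#' judgement non-positive.
#'
#' @param d1,d2,d3 0/1 decision vectors of equal length
#' @return 0/1 fused decision vector
#' @examples
#' fuse_decisions(0, 0, 0)  # 0
#' fuse_decisions(1, 0, 0)  # 1
#' @export
fuse_decisions <- function(d1, d2, d3) {
  if (!is_binary(d1) || !is_binary(d2) || !is_binary(d3)) {
    stop_mutafuse("decisions must be 0/1", "mutafuse_parse_error")
  }
  as.integer(d1 | d2 | d3)
}

#' Noisy-OR fusion of the three sub-model scores
#'
#' `1 - (1 - s1)(1 - s2)(1 - s3)`: the probability that at least one
#' endpoint fires if the three scores were independent positive
#' probabilities. Used to draw the fusion ROC; thresholding the fused score
#' at `1 - (1 - t)^3` is equivalent to OR-ing the sub-scores thresholded
#' at `t`.
#'
#' @param s1,s2,s3 score vectors in [0, 1]
#' @return fused scores in [0, 1]; always >= max(s1, s2, s3)
#' @export
fuse_scores <- function(s1, s2, s3) {
  s <- cbind(s1, s2, s3)
  if (anyNA(s) || any(s < 0 | s > 1)) {
    stop_mutafuse("scores must lie in [0, 1]", "mutafuse_parse_error")
  }
  1 - (1 - s1) * (1 - s2) * (1 - s3)
}

#' Overall mutagenicity reference label from the observed endpoints
#'
#' The weight-of-evidence ground truth the fusion rule targets: a compound
#' is mutagenic overall if any observed endpoint group is positive.
#'
#' @param y1,y2,y3 observed 0/1 endpoint labels
#' @return 0/1 reference labels
#' @export
derive_reference_label <- function(y1, y2, y3) {
  fuse_decisions(y1, y2, y3)
}

#' Fuse the three endpoint sub-models of one algorithm and evaluate
#'
#' Aligns the three sub-model results on their shared compound set, applies
#' the OR rule to decisions and the noisy-OR to scores (or, in the optional
#' `"meta"` mode, a logistic meta-classifier fitted on the training-split
#' sub-scores), and evaluates against the OR of the observed endpoint
#' labels.
#'
#' @param sub_results named list (Y1, Y2, Y3) from [train_endpoint_models()]
#' @param ds the split `modeling_dataset` the sub-models were trained on
#' @param mode `"rule"` (default: deterministic OR fusion) or `"meta"`
#'   (logistic regression over the three sub-scores)
#' @return a `fusion_result`: list with `predictions` (per-compound
#'   data.frame: compound_id, split, d1..d3, s1..s3, fused_decision,
#'   fused_score, reference_label), `train_metrics`, `test_metrics`,
#'   `test_auc`, `test_roc`, `mode`
#' @export
evaluate_fusion <- function(sub_results, ds, mode = c("rule", "meta")) {
  mode <- match.arg(mode)
  eps <- c("Y1", "Y2", "Y3")
  stopifnot(all(eps %in% names(sub_results)))
  for (ep in eps[-1]) {
    if (!identical(sub_results[[ep]]$train_ids, sub_results$Y1$train_ids) ||
        !identical(sub_results[[ep]]$test_ids, sub_results$Y1$test_ids)) {
      stop_mutafuse("sub-models do not share a compound set",
                    "mutafuse_alignment_error")
    }
  }
  assemble <- function(which_split) {
    ids <- sub_results$Y1[[paste0(which_split, "_ids")]]
    sc <- vapply(eps, function(ep)
      sub_results[[ep]][[paste0(which_split, "_scores")]],
      numeric(length(ids)))
    dc <- vapply(eps, function(ep)
      sub_results[[ep]][[paste0(which_split, "_decisions")]],
      integer(length(ids)))
    lab <- ds$labels[match(ids, ds$labels$compound_id), ]
    data.frame(compound_id = ids, split = which_split,
               d1 = dc[, 1], d2 = dc[, 2], d3 = dc[, 3],
               s1 = sc[, 1], s2 = sc[, 2], s3 = sc[, 3],
               reference_label = derive_reference_label(lab$Y1, lab$Y2, lab$Y3),
               stringsAsFactors = FALSE)
  }
  preds <- rbind(assemble("train"), assemble("test"))
  if (mode == "rule") {
    preds$fused_decision <- fuse_decisions(preds$d1, preds$d2, preds$d3)
    preds$fused_score <- fuse_scores(preds$s1, preds$s2, preds$s3)
  } else {
    tr <- preds$split == "train"
    meta <- stats::glm(reference_label ~ s1 + s2 + s3,
                       data = preds[tr, ], family = stats::binomial())
    preds$fused_score <- as.numeric(predict(meta, preds, type = "response"))
    preds$fused_decision <- as.integer(preds$fused_score >= 0.5)
  }
  tr <- preds$split == "train"
  te <- !tr
  res <- list(
    predictions = preds,
    mode = mode,
    train_metrics = per_class_metrics(preds$reference_label[tr],
                                      preds$fused_decision[tr]),
    test_metrics = per_class_metrics(preds$reference_label[te],
                                     preds$fused_decision[te])
  )
  if (length(unique(preds$reference_label[te])) == 2) {
    ra <- roc_auc(preds$reference_label[te], preds$fused_score[te])
    res$test_auc <- ra$auc
    res$test_roc <- ra$roc
  } else {
    res$test_auc <- NA_real_
    res$test_roc <- NULL
  }
  class(res) <- "fusion_result"
  res
}

#' Write per-compound fusion predictions
#'
#' @param fusion a [evaluate_fusion()] result
#' @param path CSV output path
#' @return invisibly, `path`
#' @export
write_fusion_predictions <- function(fusion, path) {
  write.csv(fusion$predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
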