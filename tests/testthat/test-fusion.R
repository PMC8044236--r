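test_that("the fused decision is the OR truth table, exhaustively", {
  triples <- expand.grid(d1 = 0:1, d2 = 0:1, d3 = 0:1)
  fused <- fuse_decisions(triples$d1, triples$d2, triples$d3)
  expect_identical(fused,
                   as.integer(triples$d1 | triples$d2 | triples$d3))
  expect_identical(fuse_decisions(0, 0, 0), 0L)
  expect_identical(fuse_decisions(1, 0, 0), 1L)
  expect_identical(sum(fused == 0), 1L)  # only all-negative is negative
  expect_error(fuse_decisions(2, 0, 0), class = "mutafuse_parse_error")
})

test_that("noisy-OR scores are absorbing, bounded and dominate each input", {
  expect_equal(fuse_scores(0, 0, 0), 0)
  expect_equal(fuse_scores(0.5, 0.5, 0.5), 0.875)  # 1 - 0.5^3
  set.seed(23)
  s <- matrix(runif(300), ncol = 3)
  expect_true(all(fuse_scores(1, s[, 1], s[, 2]) == 1))
  f <- fuse_scores(s[, 1], s[, 2], s[, 3])
  expect_true(all(f >= pmax(s[, 1], s[, 2], s[, 3])))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("a fused score above 1-(1-t)^3 implies some sub-score above t", {
  # the noisy-OR score exceeds 1-(1-t)^3 only if at least one sub-score
  # exceeds t (the converse does not hold: fuse_scores(0.9, 0, 0) = 0.9
  # stays below 1-(1-0.7)^3 = 0.973 although the OR of decisions at 0.7
  # fires), so the score-level threshold is conservative
  set.seed(24)
  s <- matrix(runif(600), ncol = 3)
  for (t in c(0.3, 0.5, 0.7)) {
    lhs <- as.integer(fuse_scores(s[, 1], s[, 2], s[, 3]) > 1 - (1 - t)^3)
    rhs <- fuse_decisions(as.integer(s[, 1] > t), as.integer(s[, 2] > t),
                          as.integer(s[, 3] > t))
    expect_true(all(lhs <= rhs))
  }
  # with equal sub-scores the two thresholdings coincide (grid chosen off
  # the thresholds: at v == t the two sides differ only by rounding)
  v <- seq(0.025, 0.975, by = 0.05)
  for (t in c(0.3, 0.5, 0.7)) {
    expect_identical(as.integer(fuse_scores(v, v, v) > 1 - (1 - t)^3),
                     fuse_decisions(as.integer(v > t), as.integer(v > t),
                                    as.integer(v > t)))
  }
})

test_that("the reference label is the OR of the observed endpoints", {
  expect_identical(derive_reference_label(0, 0, 0), 0L)
  expect_identical(derive_reference_label(0, 1, 0), 1L)
  set.seed(25)
  y <- matrix(rbinom(300, 1, 0.5), ncol = 3)
  expect_identical(derive_reference_label(y[, 1], y[, 2], y[, 3]),
                   as.integer(rowSums(y) > 0))
})

test_that("fusion is monotone: flipping any sub-decision 0->1 never unflips the verdict", {
  set.seed(26)
  for (i in 1:100) {
    d <- rbinom(3, 1, 0.5)
    base <- fuse_decisions(d[1], d[2], d[3])
    for (j in which(d == 0)) {
      d2 <- d; d2[j] <- 1L
      expect_gte(fuse_decisions(d2[1], d2[2], d2[3]), base)
    }
  }
})

test_that("fusion dominates sub-model recall and is dominated in specificity on random panels", {
  set.seed(27)
  for (i in 1:100) {
    n <- 60
    y <- matrix(rbinom(3 * n, 1, 0.5), ncol = 3)     # observed endpoints
    d <- matrix(rbinom(3 * n, 1, 0.5), ncol = 3)     # sub-decisions
    ref <- derive_reference_label(y[, 1], y[, 2], y[, 3])
    if (length(unique(ref)) < 2) next
    fused <- fuse_decisions(d[, 1], d[, 2], d[, 3])
    rec <- function(pred) {
      cc <- confusion(ref, pred); metric_recall(cc)
    }
    spec <- function(pred) {
      cc <- confusion(ref, pred)
      if (cc$TN + cc$FP == 0) NA_real_ else cc$TN / (cc$TN + cc$FP)
    }
    subs_rec <- vapply(1:3, function(k) rec(d[, k]), numeric(1))
    subs_spec <- vapply(1:3, function(k) spec(d[, k]), numeric(1))
    expect_gte(rec(fused), max(subs_rec, na.rm = TRUE))
    if (!all(is.na(subs_spec))) {
      expect_lte(spec(fused), min(subs_spec, na.rm = TRUE))
    }
    # the fusion true-positive set contains each sub-model's
    for (k in 1:3) {
      expect_true(all(which(ref == 1 & d[, k] == 1) %in%
                        which(ref == 1 & fused == 1)))
    }
  }
})

test_that("with independent per-sample errors the fused recall follows 1 - prod(1 - r)", {
  r <- c(0.75, 0.6, 0.5)
  n <- 1e5
  withr::with_seed(28, {
    d <- vapply(r, function(ri) rbinom(n, 1, ri), integer(n))
  })
  fused <- fuse_decisions(d[, 1], d[, 2], d[, 3])
  ref <- rep(1L, n)
  cc <- confusion(ref, fused)
  expect_lt(abs(metric_recall(cc) - (1 - prod(1 - r))), 0.01)
})

test_that("fusing perfect sub-models reproduces the reference exactly", {
  panel <- small_panel(seed = 29, n = 120, p = 60)
  lt <- build_label_table(panel$assays)
  y <- lt$labels
  ref <- derive_reference_label(y$Y1, y$Y2, y$Y3)
  fused <- fuse_decisions(y$Y1, y$Y2, y$Y3)  # sub-models = the labels
  expect_equal(metric_accuracy(confusion(ref, fused)), 1.0)
})

test_that("evaluate_fusion aligns sub-models and fills the prediction schema", {
  panel <- small_panel(seed = 30, n = 180, p = 80)
  res <- run_pipeline(panel$assays, panel$fingerprints, algorithms = "rf",
                      grids = tiny_grids, seed = 6,
                      shap_spec = shap_backing_spec(num_trees = 50))
  fu <- res$fusion$rf
  preds <- fu$predictions
  expect_true(all(c("compound_id", "split", "d1", "d2", "d3", "s1", "s2",
                    "s3", "fused_decision", "fused_score",
                    "reference_label") %in% names(preds)))
  expect_identical(preds$fused_decision,
                   fuse_decisions(preds$d1, preds$d2, preds$d3))
  expect_equal(preds$fused_score,
               fuse_scores(preds$s1, preds$s2, preds$s3))
  expect_true(all(preds$fused_score >=
                    pmax(preds$s1, preds$s2, preds$s3) - 1e-12))
  # mismatched compound sets are rejected
  broken <- res$models$rf
  broken$Y2$test_ids <- rev(broken$Y2$test_ids)
  expect_error(evaluate_fusion(broken, res$dataset),
               class = "mutafuse_alignment_error")
  # optional meta mode returns the same schema
  meta <- evaluate_fusion(res$models$rf, res$dataset, mode = "meta")
  expect_identical(meta$mode, "meta")
  expect_true(all(meta$predictions$fused_score >= 0 &
                    meta$predictions$fused_score <= 1))
})

test_that("fusion accuracy beats each sub-model against the OR reference on the default panel", {
  panel <- small_panel(seed = 31, n = 250, p = 80)
  res <- run_pipeline(panel$assays, panel$fingerprints, algorithms = "rf",
                      grids = list(rf = data.frame(num_trees = 300L,
                                                   max_depth = 0L)),
                      seed = 7, shap_spec = shap_backing_spec(num_trees = 100))
  fu <- res$fusion$rf
  preds <- fu$predictions
  te <- preds$split == "test"
  ref <- preds$reference_label[te]
  acc_fused <- metric_accuracy(confusion(ref, preds$fused_decision[te]))
  for (k in 1:3) {
    acc_sub <- metric_accuracy(confusion(ref, preds[[paste0("d", k)]][te]))
    expect_gte(acc_fused, acc_sub)
  }
})
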