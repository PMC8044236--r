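# Independent oracles, kept deliberately naive.

# majority vote with exact ties positive, by direct counting
oracle_vote <- function(v) {
  as.integer(sum(v == 1) >= sum(v == 0))
}

# all 0/1 vectors of a given length
all_binary_vectors <- function(len) {
  if (len == 0) return(list())
  grid <- expand.grid(rep(list(c(0L, 1L)), len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# AUC by explicit concordant / tied pair counting
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# confusion counts by an explicit loop
oracle_confusion <- function(y, d) {
  out <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(y)) {
    key <- if (y[i] == 1 && d[i] == 1) "TP"
    else if (y[i] == 0 && d[i] == 0) "TN"
    else if (y[i] == 0 && d[i] == 1) "FP"
    else "FN"
    out[key] <- out[key] + 1
  }
  out
}

# a small quick synthetic panel for unit tests
small_panel <- function(seed = 3, n = 200, p = 100) {
  generate_panel(synthetic_config(
    n_compounds = n, n_features = p, core_size = 8, private_size = 4,
    seed = seed))
}

dataset_xy_for_tests <- function(ds, endpoint, split) {
  mutafuse:::dataset_xy(ds, endpoint, split = split)
}

# one-point grids keep model tests fast
tiny_grids <- list(
  rf = data.frame(num_trees = 100L, max_depth = 0L),
  svm = data.frame(cost = 1, gamma = "0.1", stringsAsFactors = FALSE),
  bp = data.frame(size = 8L, decay = 1e-3)
)
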