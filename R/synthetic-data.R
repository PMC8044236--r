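#' Configuration for the synthetic compound-panel generator
#'
#' The generator emulates the statistical structure of an integrated
#' genotoxicity panel: independent Bernoulli fingerprint bits of varying
#' prevalence, three correlated binary endpoint labels driven by planted
#' informative bits (a shared core informative for all three endpoints plus
#' endpoint-private sets), redundant assay records per endpoint with flip
#' noise (so that singleton, majority and tie voting paths all occur), and
#' controllable group-level missingness.
#'
#' Endpoint label k follows a logistic model,
#' `logit P(y_k = 1) = a_k + beta * sum(x_j, j in S_k)`, where `S_k` is the
#' union of the shared core and endpoint k's private set; the intercept
#' `a_k` is calibrated by root-finding on the empirical linear predictor so
#' that the post-flip-noise positive rate hits `target_rates[k]`.
#'
#' @param n_compounds panel size (default 665, a typical complete-case
#'   integrated panel)
#' @param n_features number of fingerprint bits (881)
#' @param prevalence_range per-bit Bernoulli prevalence drawn uniformly from
#'   this range (default 0.05-0.5)
#' @param core_size size of the shared informative core (default 20)
#' @param private_size informative bits private to each endpoint (default 15)
#' @param beta per-informative-bit effect on the log-odds scale (default 2)
#' @param target_rates endpoint positive rates to calibrate intercepts to
#'   (defaults 0.4323 / 0.5564 / 0.5301, the training-set rates of a
#'   representative curated panel)
#' @param label_flip label flip-noise rate (default 0.05)
#' @param assays_per_endpoint set the per-compound record count per endpoint
#'   is drawn uniformly from (default 1:3)
#' @param assay_flip per-record flip noise relative to the noisy label
#'   (default 0.1)
#' @param inconclusive_rate per-record probability of being recorded as
#'   inconclusive (default 0.02)
#' @param missing_group_rate fraction of compounds losing all records of one
#'   randomly chosen endpoint group (default 0.05)
#' @param seed integer seed; the panel is reproducible exactly from
#'   config + seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_compounds = 665L,
                             n_features = 881L,
                             prevalence_range = c(0.05, 0.5),
                             core_size = 20L,
                             private_size = 15L,
                             beta = 2,
                             target_rates = c(Y1 = 0.4323, Y2 = 0.5564,
                                              Y3 = 0.5301),
                             label_flip = 0.05,
                             assays_per_endpoint = 1:3,
                             assay_flip = 0.1,
                             inconclusive_rate = 0.02,
                             missing_group_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_features = as.integer(n_features),
              prevalence_range = prevalence_range,
              core_size = as.integer(core_size),
              private_size = as.integer(private_size),
              beta = beta,
              target_rates = setNames(as.numeric(target_rates),
                                      c("Y1", "Y2", "Y3")),
              label_flip = label_flip,
              assays_per_endpoint = as.integer(assays_per_endpoint),
              assay_flip = assay_flip,
              inconclusive_rate = inconclusive_rate,
              missing_group_rate = missing_group_rate,
              seed = as.integer(seed))
  probs <- c(cfg$prevalence_range, cfg$target_rates, cfg$label_flip,
             cfg$assay_flip, cfg$inconclusive_rate, cfg$missing_group_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_mutafuse("all probabilities must lie in [0, 1]", "mutafuse_config_error")
  }
  if (cfg$core_size + 3L * cfg$private_size > cfg$n_features) {
    stop_mutafuse("informative sets exceed the number of features",
                  "mutafuse_config_error")
  }
  if (cfg$label_flip < 0.5 &&
      any(cfg$target_rates <= cfg$label_flip |
          cfg$target_rates >= 1 - cfg$label_flip)) {
    stop_mutafuse("target rates unreachable under the label flip noise",
                  "mutafuse_config_error")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# intercept a s.t. mean(plogis(a + s)) == target, on the realized signal s
calibrate_intercept <- function(signal, target) {
  f <- function(a) mean(plogis(a + signal)) - target
  r <- tryCatch(uniroot(f, c(-80, 80), tol = 1e-10),
                error = function(e) NULL)
  if (is.null(r)) {
    stop_mutafuse(sprintf("infeasible target positive rate %.4f", target),
                  "mutafuse_config_error")
  }
  r$root
}

#' Generate a synthetic compound panel with ground truth
#'
#' @param config a [synthetic_config()]
#' @return list with `fingerprints` (binary matrix), `assays` (long-format
#'   record data.frame), and `truth` (informative sets per endpoint,
#'   pre-noise and post-noise labels, intercepts, missing-group assignment,
#'   and the generating config)
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_compounds
    p <- config$n_features
    ids <- sprintf("CPD%05d", seq_len(n))

    prevalence <- runif(p, config$prevalence_range[1], config$prevalence_range[2])
    X <- matrix(rbinom(n * p, 1L, rep(prevalence, each = n)), n, p)
    fp <- fingerprint_matrix(X, ids, p)

    planted <- sample.int(p, config$core_size + 3L * config$private_size)
    core <- planted[seq_len(config$core_size)]
    private <- split(planted[-seq_len(config$core_size)],
                     rep(c("Y1", "Y2", "Y3"), each = config$private_size))
    informative <- lapply(private, function(pr) sort(c(core, pr)))

    eps <- config$label_flip
    labels_true <- labels_noisy <- matrix(0L, n, 3,
                                          dimnames = list(ids, c("Y1", "Y2", "Y3")))
    intercepts <- numeric(3)
    for (k in 1:3) {
      ep <- c("Y1", "Y2", "Y3")[k]
      signal <- config$beta * rowSums(fp[, informative[[ep]], drop = FALSE])
      # calibrate the pre-noise rate so the flipped labels hit the target
      pre_target <- (config$target_rates[[ep]] - eps) / (1 - 2 * eps)
      if (pre_target <= 0 || pre_target >= 1) {
        stop_mutafuse(sprintf("infeasible target positive rate %.4f",
                              config$target_rates[[ep]]),
                      "mutafuse_config_error")
      }
      intercepts[k] <- calibrate_intercept(signal, pre_target)
      y <- rbinom(n, 1L, plogis(intercepts[k] + signal))
      flip <- rbinom(n, 1L, eps)
      labels_true[, k] <- y
      labels_noisy[, k] <- ifelse(flip == 1L, 1L - y, y)
    }

    # group-level missingness: some compounds lose one whole endpoint group
    missing_group <- rep(NA_character_, n)
    lose <- which(rbinom(n, 1L, config$missing_group_rate) == 1L)
    missing_group[lose] <- sample(c("Y1", "Y2", "Y3"), length(lose),
                                  replace = TRUE)

    group_codes <- list(Y1 = "AMES", Y2 = c("MN_VIVO", "BM_CA"),
                        Y3 = c("VITRO_CA", "TK", "SPERM_CA", "DOM_LETHAL",
                               "HGPRT", "UDS", "SLRL"))
    rows <- vector("list", n * 3L)
    r <- 0L
    for (i in seq_len(n)) {
      for (k in 1:3) {
        ep <- c("Y1", "Y2", "Y3")[k]
        if (identical(missing_group[i], ep)) next
        m <- sample(config$assays_per_endpoint, 1L)
        bit <- labels_noisy[i, k]
        rec <- rbinom(m, 1L, 1 - config$assay_flip)
        outcome <- ifelse(rec == 1L, bit, 1L - bit)
        state <- ifelse(outcome == 1L, "positive", "negative")
        inc <- rbinom(m, 1L, config$inconclusive_rate) == 1L
        state[inc] <- "inconclusive"
        r <- r + 1L
        rows[[r]] <- data.frame(
          compound_id = ids[i],
          assay_code = sample(group_codes[[ep]], m, replace = TRUE),
          outcome = state, stringsAsFactors = FALSE)
      }
    }
    assays <- do.call(rbind, rows[seq_len(r)])
    rownames(assays) <- NULL

    truth <- list(
      informative_sets = informative,
      core = sort(core),
      private = lapply(private, sort),
      labels_true = labels_true,
      labels_noisy = labels_noisy,
      intercepts = setNames(intercepts, c("Y1", "Y2", "Y3")),
      prevalence = prevalence,
      missing_group = setNames(missing_group, ids),
      config = config
    )
    list(fingerprints = fp, assays = assays, truth = truth)
  })
}

#' Write a synthetic panel to the pipeline's input file formats
#'
#' Emits the PaDEL-dialect fingerprint CSV, the long-format assay CSV, and
#' a ground-truth JSON; reading the files back yields the in-memory panel.
#'
#' @param panel output of [generate_panel()]
#' @param dir output directory (created if absent)
#' @return named character vector of paths (fingerprints, assays, truth)
#' @export
panel_to_files <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp_path <- file.path(dir, "fingerprints.csv")
  assay_path <- file.path(dir, "assays.csv")
  truth_path <- file.path(dir, "truth.json")
  write_fingerprint_table(panel$fingerprints, fp_path)
  write.csv(panel$assays, assay_path, row.names = FALSE, quote = FALSE)
  tr <- panel$truth
  jsonlite::write_json(list(
    core = tr$core,
    private = tr$private,
    informative_sets = tr$informative_sets,
    intercepts = as.list(tr$intercepts),
    missing_group = as.list(tr$missing_group[!is.na(tr$missing_group)]),
    config = unclass(tr$config)
  ), truth_path, auto_unbox = TRUE, digits = NA)
  c(fingerprints = fp_path, assays = assay_path, truth = truth_path)
}
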