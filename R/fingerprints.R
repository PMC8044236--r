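#' Canonical PubChem fingerprint feature names
#'
#' @param n_features number of bits (881 for the PubChem substructure keys)
#' @return character vector `PubchemFP0` ... `PubchemFP<n-1>`
#' @export
fingerprint_feature_names <- function(n_features = 881L) {
  paste0("PubchemFP", seq_len(n_features) - 1L)
}

# Validate an n x 881 binary matrix with unique compound-id rownames.
validate_fingerprint_matrix <- function(values, n_features = 881L) {
  if (!is.matrix(values) || ncol(values) != n_features) {
    stop_mutafuse(
      sprintf("fingerprint matrix must have exactly %d feature columns, got %d",
              n_features, NCOL(values)),
      "mutafuse_format_error")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_mutafuse("compound ids (rownames) must be present and unique",
                  "mutafuse_format_error")
  }
  bad <- which(!(values %in% c(0, 1)) | is.na(values))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop_mutafuse(
      sprintf("non-binary fingerprint value at row %d (%s), column %s",
              i, rownames(values)[i], colnames(values)[j]),
      "mutafuse_format_error")
  }
  if (!identical(colnames(values), fingerprint_feature_names(n_features))) {
    stop_mutafuse("fingerprint columns must be named PubchemFP0...PubchemFP880",
                  "mutafuse_format_error")
  }
  invisible(values)
}

#' Construct a fingerprint matrix
#'
#' @param values n x 881 matrix with entries in \{0, 1\}
#' @param compound_ids character vector of unique compound identifiers
#' @param n_features expected number of bits
#' @return the validated matrix with compound ids as rownames and
#'   `PubchemFP*` colnames
#' @export
fingerprint_matrix <- function(values, compound_ids,
                               n_features = 881L) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  rownames(values) <- as.character(compound_ids)
  colnames(values) <- fingerprint_feature_names(n_features)
  validate_fingerprint_matrix(values, n_features)
  values
}

#' Read a fingerprint table in the PaDEL-Descriptor CSV dialect
#'
#' PaDEL writes one header row (`Name,PubchemFP0,...,PubchemFP880`) and one
#' row per compound. Column count and binariness are validated; the error
#' for a non-binary cell names its row and column.
#'
#' @param path CSV file
#' @param n_features expected number of fingerprint bits (881 for the
#'   PubChem keys); `NULL` accepts any contiguous `PubchemFP0...` block,
#'   which reduced synthetic panels use
#' @return binary matrix with compound ids as rownames
#' @export
read_fingerprint_table <- function(path, n_features = 881L) {
  if (!file.exists(path)) {
    stop_mutafuse(sprintf("file not found: %s", path), "mutafuse_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  n_features <- as.integer(n_features %||% (ncol(df) - 1L))
  expected <- fingerprint_feature_names(n_features)
  if (ncol(df) != n_features + 1L || !identical(names(df)[-1], expected)) {
    stop_mutafuse(
      sprintf(paste0("expected PaDEL layout: a name column followed by %d ",
                     "columns PubchemFP0...PubchemFP%d"),
              n_features, n_features - 1L),
      "mutafuse_format_error")
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(values) <- "integer")
  fingerprint_matrix(values, df[[1]], n_features)
}

#' Write a fingerprint matrix in the PaDEL-Descriptor CSV dialect
#'
#' @param fp fingerprint matrix (see [fingerprint_matrix()])
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_fingerprint_table <- function(fp, path) {
  df <- data.frame(Name = rownames(fp), fp, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Join fingerprints with endpoint labels into a modeling dataset
#'
#' Inner join on compound_id; rows are canonically sorted by compound_id so
#' downstream seeding is row-order invariant.
#'
#' @param fp fingerprint matrix
#' @param labels label table (compound_id, Y1, Y2, Y3)
#' @return a `modeling_dataset`: list with `fingerprints`, `labels`,
#'   `dropped` (counts dropped from each side), and (after
#'   [split_train_test()]) `split`, `split_ratio`, `split_seed`
#' @export
join_features_labels <- function(fp, labels) {
  shared <- intersect(rownames(fp), labels$compound_id)
  if (length(shared) == 0) {
    stop_mutafuse("no compounds shared between fingerprints and labels",
                  "mutafuse_join_error")
  }
  shared <- sort(shared)
  n_label_dropped <- sum(!labels$compound_id %in% shared)
  labels <- labels[match(shared, labels$compound_id), , drop = FALSE]
  rownames(labels) <- NULL
  ds <- list(
    fingerprints = fp[shared, , drop = FALSE],
    labels = labels,
    dropped = c(fingerprints = nrow(fp) - length(shared),
                labels = n_label_dropped),
    split = NULL, split_ratio = NULL, split_seed = NULL
  )
  class(ds) <- "modeling_dataset"
  ds
}

#' @export
print.modeling_dataset <- function(x, ...) {
  cat(sprintf("<modeling_dataset> %d compounds x %d fingerprint bits\n",
              nrow(x$fingerprints), ncol(x$fingerprints)))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d train / %d test (ratio %.2f, seed %d)\n",
                sum(x$split == "train"), sum(x$split == "test"),
                x$split_ratio, x$split_seed))
  }
  invisible(x)
}

#' Split a modeling dataset into training and test sets
#'
#' Uniform random assignment without replacement; the training set size is
#' `round(n * ratio)` (half away from zero), so 665 compounds at the default
#' 4:1 ratio give 532 training and 133 test compounds. With
#' `stratify = TRUE` the split is drawn within each (Y1, Y2, Y3) label
#' triple, preserving the joint label distribution.
#'
#' @param ds modeling dataset from [join_features_labels()]
#' @param ratio training fraction in (0, 1); default 0.8
#' @param seed integer seed; the assignment is deterministic given the seed
#' @param stratify stratify on the label triple (off by default)
#' @return the dataset with `split` assigned (named character vector with
#'   values "train"/"test")
#' @export
split_train_test <- function(ds, ratio = 0.8, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(ds, "modeling_dataset"))
  if (!(ratio > 0 && ratio < 1)) {
    stop_mutafuse("ratio must be in (0, 1)", "mutafuse_spec_error")
  }
  ids <- sort(rownames(ds$fingerprints))
  n <- length(ids)
  if (n < 2) {
    stop_mutafuse("need at least 2 compounds to split", "mutafuse_size_error")
  }
  n_train <- as.integer(round_half_up(n * ratio))
  train_ids <- withr::with_seed(seed, {
    if (!stratify) {
      sample(ids, n_train)
    } else {
      triple <- interaction(ds$labels$Y1, ds$labels$Y2, ds$labels$Y3,
                            drop = TRUE)
      names(triple) <- ds$labels$compound_id
      picked <- unlist(lapply(split(ids, triple[ids]), function(g) {
        sample(g, as.integer(round_half_up(length(g) * ratio)))
      }), use.names = FALSE)
      # per-stratum rounding can drift from the global target; trim/top up
      pool <- setdiff(ids, picked)
      if (length(picked) > n_train) {
        picked <- sample(picked, n_train)
      } else if (length(picked) < n_train) {
        picked <- c(picked, sample(pool, n_train - length(picked)))
      }
      picked
    }
  })
  split <- setNames(ifelse(ids %in% train_ids, "train", "test"), ids)
  ds$split <- split
  ds$split_ratio <- ratio
  ds$split_seed <- as.integer(seed)
  ds
}

# Feature matrix and label vector for one split/endpoint.
dataset_xy <- function(ds, endpoint, split = NULL, features = NULL) {
  stopifnot(endpoint %in% c("Y1", "Y2", "Y3"))
  ids <- rownames(ds$fingerprints)
  if (!is.null(split)) {
    if (is.null(ds$split)) stop_mutafuse("dataset has no split assigned",
                                         "mutafuse_spec_error")
    ids <- ids[ds$split[ids] == split]
  }
  X <- ds$fingerprints[ids, , drop = FALSE]
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- ds$labels[[endpoint]][match(ids, ds$labels$compound_id)]
  list(X = X, y = y, ids = ids)
}

#' Write the split assignment
#'
#' @param ds split modeling dataset
#' @param path CSV output path (compound_id, split)
#' @return invisibly, `path`
#' @export
write_split_assignment <- function(ds, path) {
  stopifnot(inherits(ds, "modeling_dataset"))
  if (is.null(ds$split)) {
    stop_mutafuse("dataset has no split assigned", "mutafuse_spec_error")
  }
  write.csv(data.frame(compound_id = names(ds$split),
                       split = unname(ds$split)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the run manifest for a split dataset
#'
#' @param ds split modeling dataset
#' @param path JSON output path
#' @return invisibly, `path`
#' @export
write_run_manifest <- function(ds, path) {
  stopifnot(inherits(ds, "modeling_dataset"))
  jsonlite::write_json(list(
    n_compounds = nrow(ds$fingerprints),
    n_features = ncol(ds$fingerprints),
    split_ratio = ds$split_ratio,
    split_seed = ds$split_seed,
    n_train = if (is.null(ds$split)) NULL else sum(ds$split == "train"),
    n_test = if (is.null(ds$split)) NULL else sum(ds$split == "test")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
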