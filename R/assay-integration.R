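#' Normalize assay outcome spellings
#'
#' Maps the spellings found in curated genotoxicity tables onto the three
#' canonical states. Recognized (case-insensitively, after trimming):
#' positive = `positive`, `pos`, `1`, `+`; negative = `negative`, `neg`,
#' `0`, `-`; inconclusive = `inconclusive`, `equivocal`, `NA` (literal or
#' missing).
#'
#' @param x character vector of raw outcome strings
#' @return character vector with values in
#'   `c("positive", "negative", "inconclusive")`
#' @export
normalize_outcome <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  raw[is.na(raw)] <- "na"
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("positive", "pos", "1", "+")] <- "positive"
  out[raw %in% c("negative", "neg", "0", "-")] <- "negative"
  out[raw %in% c("inconclusive", "equivocal", "na")] <- "inconclusive"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_mutafuse(
      sprintf("unrecognized outcome value(s): %s", paste(bad, collapse = ", ")),
      "mutafuse_parse_error")
  }
  out
}

#' Read a long-format assay-result table
#'
#' One row per compound x assay observation. Requires columns
#' `compound_id`, `assay_code`, `outcome`; outcome spellings are normalized
#' via [normalize_outcome()] and assay codes validated against the
#' taxonomy at parse time.
#'
#' @param path CSV or TSV file (delimiter chosen by extension; `.tsv`/`.txt`
#'   are read tab-separated)
#' @param taxonomy see [assay_taxonomy()]
#' @return data.frame with columns compound_id, assay_code, outcome
#' @export
read_assay_table <- function(path, taxonomy = assay_taxonomy()) {
  if (!file.exists(path)) {
    stop_mutafuse(sprintf("file not found: %s", path), "mutafuse_io_error")
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("compound_id", "assay_code", "outcome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_mutafuse(
      sprintf("assay table lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "mutafuse_parse_error")
  }
  df <- df[need]
  df$outcome <- normalize_outcome(df$outcome)
  classify_assay(df$assay_code, taxonomy)  # reject unknown codes at parse time
  df
}

#' Vote within an endpoint group, ties resolved positive
#'
#' Majority vote over dichotomous outcomes; an exact tie is judged positive,
#' which favours sensitivity of the downstream model. Inconclusive records
#' must already have been removed.
#'
#' @param outcomes non-empty vector of 0/1 outcomes
#' @return 0 or 1
#' @examples
#' vote_outcomes(c(1, 0))    # tie -> positive
#' vote_outcomes(c(0, 0, 1)) # strict majority -> negative
#' @export
vote_outcomes <- function(outcomes) {
  if (length(outcomes) == 0) {
    stop_mutafuse("no usable outcomes to vote on", "mutafuse_missing_data_error")
  }
  if (!is_binary(outcomes)) {
    stop_mutafuse("outcomes must be 0/1", "mutafuse_parse_error")
  }
  as.integer(2 * sum(outcomes) >= length(outcomes))
}

#' Integrate all assay records of one compound into endpoint labels
#'
#' Drops inconclusive records, groups the remainder by endpoint via
#' [classify_assay()], and votes within each group. A compound is labelled
#' only if all three groups retain at least one usable record; otherwise it
#' is excluded, tagged with whether a group had no records at all
#' (`missing_group`) or only inconclusive ones (`all_inconclusive`).
#'
#' @param records data.frame with columns compound_id, assay_code, outcome
#'   (normalized), all rows sharing one compound_id
#' @param taxonomy see [assay_taxonomy()]
#' @return list with either `labels = c(y1, y2, y3)` or
#'   `exclusion = list(reason, groups)`
#' @export
integrate_compound <- function(records, taxonomy = assay_taxonomy()) {
  stopifnot(nrow(records) > 0)
  if (length(unique(records$compound_id)) != 1) {
    stop_mutafuse("records must belong to a single compound", "mutafuse_parse_error")
  }
  grp_all <- classify_assay(records$assay_code, taxonomy)
  usable <- records$outcome != "inconclusive"
  grp_use <- grp_all[usable]
  val_use <- as.integer(records$outcome[usable] == "positive")

  groups <- c("Y1", "Y2", "Y3")
  missing <- setdiff(groups, grp_use)
  if (length(missing) > 0) {
    had_records <- missing %in% grp_all
    reason <- if (any(had_records)) "all_inconclusive" else "missing_group"
    return(list(labels = NULL,
                exclusion = list(reason = reason, groups = missing)))
  }
  labels <- vapply(groups, function(g) vote_outcomes(val_use[grp_use == g]),
                   integer(1))
  list(labels = labels, exclusion = NULL)
}

#' Build the complete-case endpoint label table
#'
#' Applies [integrate_compound()] per compound and keeps only compounds with
#' all three endpoint labels. If an identity table is supplied, exact
#' duplicates are collapsed and conflicting rows for the same compound_id
#' raise a deduplication error listing the offending IDs.
#'
#' @param records assay records data.frame (see [read_assay_table()])
#' @param taxonomy see [assay_taxonomy()]
#' @param identity optional data.frame with a `compound_id` column and
#'   identity fields (name, CAS, SMILES, InChI)
#' @return list with `labels` (data.frame compound_id, Y1, Y2, Y3, sorted by
#'   compound_id), `exclusions` (data.frame compound_id, reason) and
#'   `report` (an integration report, see Details)
#'
#' @details The report carries `n_input_compounds`,
#'   `n_excluded_inconclusive` (a group present but entirely inconclusive),
#'   `n_excluded_missing_group`, `n_complete`, and per-group usable record
#'   counts; `n_complete` plus the exclusions always reconciles with the
#'   input compound count.
#' @export
build_label_table <- function(records, taxonomy = assay_taxonomy(),
                              identity = NULL) {
  if (!is.null(identity)) {
    identity <- unique(identity)
    dup <- identity$compound_id[duplicated(identity$compound_id)]
    if (length(dup) > 0) {
      stop_mutafuse(
        sprintf("conflicting identity rows for compound(s): %s",
                paste(sort(unique(dup)), collapse = ", ")),
        "mutafuse_dedup_error")
    }
  }
  empty_labels <- data.frame(compound_id = character(0), Y1 = integer(0),
                             Y2 = integer(0), Y3 = integer(0),
                             stringsAsFactors = FALSE)
  empty_excl <- data.frame(compound_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    report <- list(n_input_compounds = 0L, n_excluded_inconclusive = 0L,
                   n_excluded_missing_group = 0L, n_complete = 0L,
                   n_records_per_group = c(Y1 = 0L, Y2 = 0L, Y3 = 0L))
    return(list(labels = empty_labels, exclusions = empty_excl, report = report))
  }
  ids <- sort(unique(records$compound_id))
  res <- lapply(ids, function(id) {
    integrate_compound(records[records$compound_id == id, , drop = FALSE],
                       taxonomy)
  })
  keep <- vapply(res, function(r) is.null(r$exclusion), logical(1))
  labels <- if (any(keep)) {
    lab <- do.call(rbind, lapply(res[keep], function(r) r$labels))
    data.frame(compound_id = ids[keep], Y1 = lab[, "Y1"], Y2 = lab[, "Y2"],
               Y3 = lab[, "Y3"], row.names = NULL, stringsAsFactors = FALSE)
  } else empty_labels
  exclusions <- if (any(!keep)) {
    data.frame(
      compound_id = ids[!keep],
      reason = vapply(res[!keep], function(r) r$exclusion$reason, character(1)),
      stringsAsFactors = FALSE)
  } else empty_excl

  usable <- records[records$outcome != "inconclusive", , drop = FALSE]
  grp <- classify_assay(usable$assay_code, taxonomy)
  report <- list(
    n_input_compounds = length(ids),
    n_excluded_inconclusive = sum(exclusions$reason == "all_inconclusive"),
    n_excluded_missing_group = sum(exclusions$reason == "missing_group"),
    n_complete = sum(keep),
    n_records_per_group = c(Y1 = sum(grp == "Y1"), Y2 = sum(grp == "Y2"),
                            Y3 = sum(grp == "Y3"))
  )
  list(labels = labels, exclusions = exclusions, report = report)
}

#' Summarize endpoint labels per split
#'
#' Produces the data-distribution table: per split and endpoint, the counts
#' of positives and negatives and the positive rate
#' `100 * positives / (positives + negatives)`, half-up rounded to two
#' decimals.
#'
#' @param labels label table (compound_id, Y1, Y2, Y3)
#' @param split_assignment named character vector (names = compound_id,
#'   values = split label such as "train"/"test"), or `NULL` to summarize
#'   all compounds as one split `"all"`
#' @return data.frame with columns split, endpoint, n_positive, n_negative,
#'   positive_rate
#' @export
summarize_labels <- function(labels, split_assignment = NULL) {
  if (is.null(split_assignment)) {
    split_assignment <- setNames(rep("all", nrow(labels)), labels$compound_id)
  }
  if (!all(labels$compound_id %in% names(split_assignment))) {
    stop_mutafuse("every compound must be assigned to exactly one split",
                  "mutafuse_parse_error")
  }
  spl <- split_assignment[labels$compound_id]
  out <- do.call(rbind, lapply(sort(unique(spl)), function(s) {
    sub <- labels[spl == s, , drop = FALSE]
    do.call(rbind, lapply(c("Y1", "Y2", "Y3"), function(ep) {
      pos <- sum(sub[[ep]] == 1)
      neg <- sum(sub[[ep]] == 0)
      data.frame(split = s, endpoint = ep, n_positive = pos, n_negative = neg,
                 positive_rate = positive_rate(pos, neg),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Positive rate in percent
#'
#' @param n_positive,n_negative class counts
#' @return `100 * n_positive / (n_positive + n_negative)`, half-up rounded to
#'   2 decimals; 0 total gives `NA`
#' @export
positive_rate <- function(n_positive, n_negative) {
  total <- n_positive + n_negative
  ifelse(total == 0, NA_real_,
         round_half_up(100 * n_positive / total, 2))
}

#' Write the label table and integration report
#'
#' @param result output of [build_label_table()]
#' @param labels_path CSV path for the label table
#' @param report_path optional JSON path for the integration report
#' @return invisibly, the paths written
#' @export
write_label_table <- function(result, labels_path, report_path = NULL) {
  labs <- result$labels[order(result$labels$compound_id), , drop = FALSE]
  write.csv(labs, labels_path, row.names = FALSE, quote = FALSE)
  paths <- labels_path
  if (!is.null(report_path)) {
    jsonlite::write_json(result$report, report_path, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, report_path)
  }
  invisible(paths)
}
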