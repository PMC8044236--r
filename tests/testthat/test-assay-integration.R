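test_that("taxonomy maps every assay code to its endpoint group", {
  expect_identical(classify_assay("AMES"), "Y1")
  expect_identical(classify_assay(c("MN_VIVO", "BM_CA")), c("Y2", "Y2"))
  expect_identical(
    classify_assay(c("VITRO_CA", "TK", "SPERM_CA", "DOM_LETHAL",
                     "HGPRT", "UDS", "SLRL")),
    rep("Y3", 7))
  expect_error(classify_assay("COMET"), "COMET",
               class = "mutafuse_taxonomy_error")
  # extension hook adds codes but cannot remap built-ins
  tax <- assay_taxonomy(extra = c(COMET = "Y3"))
  expect_identical(classify_assay("COMET", tax), "Y3")
  expect_error(assay_taxonomy(extra = c(AMES = "Y2")),
               class = "mutafuse_taxonomy_error")
  expect_error(assay_taxonomy(extra = c(FOO = "Y9")),
               class = "mutafuse_taxonomy_error")
})

test_that("outcome spellings normalize case-insensitively", {
  expect_identical(
    normalize_outcome(c("Positive", "pos", "1", "+",
                        "NEGATIVE", "neg", "0", "-",
                        "Inconclusive", "equivocal", "NA", NA)),
    c(rep("positive", 4), rep("negative", 4), rep("inconclusive", 4)))
  expect_error(normalize_outcome("maybe"), "maybe",
               class = "mutafuse_parse_error")
})

test_that("voting matches the brute-force majority-tie-positive oracle on all vectors up to length 6", {
  for (len in 1:6) {
    for (v in all_binary_vectors(len)) {
      expect_identical(vote_outcomes(v), oracle_vote(v))
    }
  }
  # spot checks: tie positive, strict majority, singleton
  expect_identical(vote_outcomes(c(1, 0)), 1L)
  expect_identical(vote_outcomes(c(0, 0, 1)), 0L)
  expect_identical(vote_outcomes(1), 1L)
  expect_error(vote_outcomes(integer(0)),
               class = "mutafuse_missing_data_error")
})

test_that("voting is permutation-invariant and monotone in 0->1 flips", {
  set.seed(42)
  for (i in 1:50) {
    v <- sample(c(0L, 1L), sample(1:6, 1), replace = TRUE)
    expect_identical(vote_outcomes(v), vote_outcomes(sample(v)))
    zeros <- which(v == 0)
    if (length(zeros) > 0) {
      w <- v
      w[sample(zeros, 1)] <- 1L
      expect_gte(vote_outcomes(w), vote_outcomes(v))
    }
  }
})

test_that("integrate_compound labels complete compounds and tags exclusions", {
  rec <- function(id, code, out) data.frame(compound_id = id,
                                            assay_code = code, outcome = out,
                                            stringsAsFactors = FALSE)
  full <- rbind(rec("a", "AMES", "positive"),
                rec("a", "MN_VIVO", "negative"),
                rec("a", "VITRO_CA", "negative"))
  r <- integrate_compound(full)
  expect_identical(r$labels, c(Y1 = 1L, Y2 = 0L, Y3 = 0L))

  partial <- rbind(rec("b", "AMES", "positive"),
                   rec("b", "MN_VIVO", "negative"))
  r <- integrate_compound(partial)
  expect_null(r$labels)
  expect_identical(r$exclusion$reason, "missing_group")
  expect_identical(r$exclusion$groups, "Y3")

  # a group whose only record is inconclusive counts as all-inconclusive
  inc <- rbind(rec("c", "AMES", "inconclusive"),
               rec("c", "MN_VIVO", "negative"),
               rec("c", "TK", "positive"))
  r <- integrate_compound(inc)
  expect_null(r$labels)
  expect_identical(r$exclusion$reason, "all_inconclusive")
  expect_identical(r$exclusion$groups, "Y1")
})

test_that("build_label_table reconciles exclusion counts with input size", {
  rec <- function(id, code, out) data.frame(compound_id = id,
                                            assay_code = code, outcome = out,
                                            stringsAsFactors = FALSE)
  records <- rbind(
    rec("c1", "AMES", "positive"), rec("c1", "MN_VIVO", "negative"),
    rec("c1", "TK", "positive"),
    rec("c2", "AMES", "negative"), rec("c2", "BM_CA", "positive"),
    rec("c2", "UDS", "negative"),
    rec("c3", "AMES", "positive"), rec("c3", "VITRO_CA", "negative"))
  out <- build_label_table(records)
  expect_identical(out$labels$compound_id, c("c1", "c2"))
  expect_identical(out$report$n_excluded_missing_group, 1L)
  expect_identical(out$report$n_complete + out$report$n_excluded_inconclusive +
                     out$report$n_excluded_missing_group,
                   out$report$n_input_compounds)
  # labels are complete cases
  expect_false(anyNA(out$labels[c("Y1", "Y2", "Y3")]))

  empty <- build_label_table(records[0, ])
  expect_identical(nrow(empty$labels), 0L)
  expect_identical(empty$report$n_input_compounds, 0L)
})

test_that("build_label_table rejects conflicting identity rows and accepts exact duplicates", {
  rec <- data.frame(compound_id = "c1", assay_code = "AMES",
                    outcome = "positive", stringsAsFactors = FALSE)
  id_ok <- data.frame(compound_id = c("c1", "c1"), cas = c("50-00-0", "50-00-0"),
                      stringsAsFactors = FALSE)
  expect_silent(build_label_table(rec, identity = id_ok))
  id_bad <- data.frame(compound_id = c("c1", "c1"), cas = c("50-00-0", "64-17-5"),
                       stringsAsFactors = FALSE)
  expect_error(build_label_table(rec, identity = id_bad), "c1",
               class = "mutafuse_dedup_error")
})

test_that("exclusions on a synthetic panel match the generator's bookkeeping", {
  panel <- generate_panel(synthetic_config(
    n_compounds = 400, n_features = 50, core_size = 4, private_size = 2,
    missing_group_rate = 0.2, seed = 11))
  out <- build_label_table(panel$assays)
  planted_missing <- names(panel$truth$missing_group)[
    !is.na(panel$truth$missing_group)]
  # every compound the generator deprived of a group is excluded; the
  # generator is the only source of absent groups, so every missing_group
  # exclusion is planted (a planted compound may be tagged all_inconclusive
  # if another of its groups was recorded but entirely inconclusive)
  missing_excl <- out$exclusions$compound_id[
    out$exclusions$reason == "missing_group"]
  expect_true(all(planted_missing %in% out$exclusions$compound_id))
  expect_true(all(missing_excl %in% planted_missing))
  expect_gte(out$report$n_excluded_missing_group, floor(0.2 * 400 * 0.5))

  # with missingness off, only inconclusive-driven exclusions remain
  panel0 <- generate_panel(synthetic_config(
    n_compounds = 300, n_features = 50, core_size = 4, private_size = 2,
    missing_group_rate = 0, seed = 12))
  out0 <- build_label_table(panel0$assays)
  expect_identical(out0$report$n_excluded_missing_group, 0L)
  expect_true(all(out0$exclusions$reason == "all_inconclusive"))
})

test_that("summarize_labels reproduces the printed positive rates and its counts add up", {
  # counts of the published data-distribution table
  make_labels <- function(n, pos) {
    # first `pos[[ep]]` compounds positive for each endpoint
    data.frame(compound_id = sprintf("c%04d", seq_len(n)),
               Y1 = as.integer(seq_len(n) <= pos[1]),
               Y2 = as.integer(seq_len(n) <= pos[2]),
               Y3 = as.integer(seq_len(n) <= pos[3]),
               stringsAsFactors = FALSE)
  }
  train <- make_labels(532, c(230, 296, 282))
  test <- make_labels(133, c(53, 76, 74))
  test$compound_id <- sprintf("t%04d", seq_len(133))
  labels <- rbind(train, test)
  split <- setNames(c(rep("train", 532), rep("test", 133)),
                    labels$compound_id)
  s <- summarize_labels(labels, split)
  rate <- function(spl, ep) s$positive_rate[s$split == spl & s$endpoint == ep]
  expect_equal(rate("train", "Y1"), 43.23)
  expect_equal(rate("train", "Y2"), 55.64)
  expect_equal(rate("train", "Y3"), 53.01)
  expect_equal(rate("test", "Y1"), 39.85)
  expect_equal(rate("test", "Y2"), 57.14)
  expect_equal(rate("test", "Y3"), 55.64)
  # positives + negatives per endpoint per split equal the split size,
  # and train + test column sums give the totals
  expect_true(all(s$n_positive + s$n_negative ==
                    ifelse(s$split == "train", 532, 133)))
  tot <- tapply(s$n_positive, s$endpoint, sum)
  expect_equal(unname(tot[c("Y1", "Y2", "Y3")]), c(283, 372, 356),
               ignore_attr = TRUE)

  expect_equal(positive_rate(0, 10), 0)
  expect_true(is.na(positive_rate(0, 0)))
})

test_that("assay tables round-trip through CSV with spelling normalization", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,assay_code,outcome",
               "c1,AMES,Pos", "c1,MN_VIVO,-", "c1,TK,equivocal"), path)
  df <- read_assay_table(path)
  expect_identical(df$outcome, c("positive", "negative", "inconclusive"))
  writeLines(c("compound_id,assay_code,outcome", "c1,NOT_AN_ASSAY,1"), path)
  expect_error(read_assay_table(path), "NOT_AN_ASSAY",
               class = "mutafuse_taxonomy_error")
})
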