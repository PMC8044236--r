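---
title: "Weight-of-evidence fusion models for mutagenicity QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-of-evidence fusion models for mutagenicity QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

No single genotoxicity assay detects every mutagenic mechanism: a compound
can be Ames-negative and still damage chromosomes in vivo. Regulatory
practice therefore judges mutagenicity from a battery of assays under the
weight-of-evidence principle — a compound is called positive if any assay
group in the battery is positive, and negative only when all groups are
negative. `mutafuse` builds QSAR classifiers that mirror this logic: instead
of one model for one assay, it trains one sub-model per evidence group and
combines their verdicts with the same all-negative-is-negative rule.

The two standard ICH S2(R1) batteries share their first two slots and differ
in the third, which motivates three endpoint groups:

* **Y1** — bacterial reverse mutation (Ames); the prokaryotic endpoint.
* **Y2** — in vivo mammalian cytogenetics: erythrocyte micronucleus or bone
  marrow chromosome aberration, mutually substitutable.
* **Y3** — the pooled third slot of both batteries (in vitro chromosomal
  aberration, in vitro TK gene mutation, spermatocyte chromosome aberration,
  rodent dominant lethal) plus the supplements used when those are missing
  (HGPRT gene mutation, unscheduled DNA synthesis, Drosophila sex-linked
  recessive lethal).

The taxonomy is a closed enumeration (`assay_taxonomy()`) with an `extra`
hook for additional codes, because curated sources name assays in free text
and silent misclassification would corrupt the endpoint labels.

## Assay integration

Raw data are long-format records (compound, assay, outcome), with outcomes
dichotomized as positive / negative and an inconclusive state allowed.
Integration (`build_label_table()`) proceeds per compound:

1. inconclusive records are dropped;
2. remaining records are grouped by endpoint;
3. each group is reduced by majority vote, with an exact tie judged
   **positive** (`vote_outcomes()`) — the tie break deliberately favours
   sensitivity, since a false negative is the costlier error for an early
   warning system;
4. the compound is kept only if all three groups retain at least one usable
   record (complete cases), otherwise it is excluded and tagged with the
   reason — a group with no records at all (`missing_group`) or a group
   whose records were all inconclusive (`all_inconclusive`).

Voting applies uniformly to all three groups, including multiple Ames
records in Y1; the rule is stated in the literature for the multi-assay
groups and treating Y1 differently would be an arbitrary asymmetry.
The integration report reconciles exactly: complete cases plus exclusions
equal the input compound count, a property the tests assert on every panel.

## Features and the train/test split

Structure enters as the 881-bit PubChem substructure fingerprint in the
PaDEL-Descriptor CSV dialect (`Name,PubchemFP0,...,PubchemFP880`), validated
strictly on read: column count, naming, and binariness (errors name the
offending row and column). Computing fingerprints from structures is out of
scope; the package consumes the descriptor software's output.

The labelled panel is split uniformly at random into training and test sets,
default ratio 0.8 — the 4:1 split under which a 665-compound panel yields
exactly 532/133. (Curation reports of such panels quote both 4:1 and 7:3
splits in different places; the package defaults to the ratio that matches
the printed data distribution and leaves `ratio` configurable.) An optional
stratified mode keyed on the (Y1, Y2, Y3) triple exists but is off by
default, matching the plain "random selection" description. The split is
`round(n * ratio)` exact, seeded, and performed on compound ids in canonical
sorted order, so it is invariant to input row order.

Zero-variance fingerprint columns are *not* pruned before feature ranking:
all 881 bits are ranked, and constant columns receive exactly zero
importance naturally.

## SHAP-quintile feature selection

For each endpoint separately, a classifier is fitted on the training split
and each fingerprint bit receives a global importance: the mean absolute
SHAP attribution over training compounds (signed means are stored alongside
for direction of effect). Bits are sorted descending, ties broken by
ascending feature index so rankings are reproducible. The selected
descriptor set is the intersection of the three per-endpoint *first
quintiles* — the top `floor(881 * 0.2) = 176` bits each. Floor rather than
ceiling is an arbitrary but fixed convention; at 881 features the
alternative differs by one feature and does not change behaviour
measurably. Selection uses the training split only, so the test set never
leaks into the feature set.

The backing classifier is a random forest — bagged trees (subsample 0.632,
the bootstrap expectation), per-node feature subsampling at the
classification default `sqrt(p)/p`, 300 trees, depth cap 8 — fitted through
xgboost's parallel-tree mode, whose `predcontrib` attributions are exact
tree-path SHAP values. A boosted-trees backing is available via
`shap_backing_spec(model = "boosted_trees")`. Tree attribution was chosen
because the endpoint-wise global importance bar charts this mimics are
characteristic of tree-ensemble SHAP, and because exact attribution keeps
the ranking deterministic given the seed.

On a real 665-compound panel this procedure selects on the order of 90
bits; the number is data-dependent and the package treats it as an outcome,
not a target.

## Sub-models and grid search

Three algorithm families are supported, each trained once per endpoint on
the selected features:

* **RF** (`ranger`): probability forest; grid `trees {100, 300, 500} x
  max depth {unlimited, 10, 20}`; scores are the forest's positive-class
  vote fraction.
* **SVM** (`e1071`): RBF kernel; grid `C {0.1, 1, 10, 100} x width {scale,
  0.01, 0.1}` where `scale` resolves to `1/p`; scores are Platt-calibrated
  positive-class probabilities, so score-level fusion is meaningful.
* **BP** (`nnet`): one hidden layer, logistic output, cross-entropy loss;
  grid `hidden units {32, 64, 128} x L2 decay {1e-4, 1e-3}`. The network is
  trained to a fixed iteration cap (default 200) with the decay term as the
  regulariser; this replaces an early-stopping rule, which the quasi-Newton
  optimiser used here does not expose, and in practice the decay grid
  controls overfitting the same way.

Grid search is exhaustive, scored by pooled out-of-fold accuracy Q under
stratified five-fold cross-validation — accuracy, not AUC, is the selection
criterion, matching the robustness statistic reported for such models. Ties
prefer the earlier grid row; fold assignment is stratified, seeded, and
applied after canonical sorting, so the whole fit is a deterministic
function of (data, grid, seed). Accuracy is reported both as CV Q and as
resubstitution training accuracy, labelled separately, because the two are
often conflated in published tables. Decisions are `score >= 0.5` by
default; the threshold is part of the spec and configurable.

No class reweighting is applied: the endpoint positive rates (roughly
0.43-0.56) are mild, and unweighted training reproduces the characteristic
per-class asymmetries seen in published indicator tables.

## Fusion

For one algorithm family, the three endpoint sub-models fuse by the
weight-of-evidence rule: `fused = d1 OR d2 OR d3` (`fuse_decisions()`).
The reference label for evaluating fusion is the OR of the *observed*
endpoint labels — the ground truth the rule targets. Two consequences hold
on any panel and are asserted as properties: fusion recall on the positive
class never falls below any sub-model's, and fusion specificity never
exceeds any sub-model's.

A binary rule has no natural ROC, so for ROC/AUC the package fuses scores
by noisy-OR: `1 - (1 - s1)(1 - s2)(1 - s3)` — the probability that at least
one endpoint fires if the scores were independent probabilities. The fused
score always dominates each sub-score, and a fused score above
`1 - (1 - t)^3` implies some sub-score above `t` (the converse is false;
the score-level threshold is conservative). How a fusion AUC should be
computed is genuinely open — the rule itself is threshold-free — and
noisy-OR is this package's reading; a logistic meta-classifier over the
three scores is available as `evaluate_fusion(..., mode = "meta")` but is
not the default, because the published rule is stated deterministically.

## Evaluation

The metric suite is the standard confusion-matrix family, positive class
= 1: accuracy `Q = (TP + TN) / n`, precision `TP / (TP + FP)`, recall
`TP / (TP + FN)`, and `F1 = 2pr / (p + r)`. Negative-class ("non-positive")
blocks are computed by relabelling 0 as the class of interest. Zero
denominators yield `NA` — an explicit undefined marker, never 0 or 1 —
because an all-positive predictor genuinely has no negative-class
precision. AUC uses midranks (the Mann-Whitney statistic, equal to the
trapezoidal area under the empirical ROC), with curve points at every
distinct threshold. Report tables round half-up to 3 decimals; rates print
as percentages to 2 decimals. Every report row's F1 recomputes from that
row's own precision and recall — the package's tables are self-consistent
by construction, which published tables of this kind sometimes are not.

## The synthetic panel generator

`generate_panel()` emulates the statistical structure the pipeline assumes,
so every stage is testable without any external download:

* fingerprint bits are independent Bernoulli with per-bit prevalence drawn
  uniformly from 0.05-0.5;
* endpoint k follows `logit P(y=1) = a_k + beta * sum(x_j, j in S_k)` with
  `S_k` the union of a shared 20-bit core (informative for all three
  endpoints — the reason a cross-endpoint intersection retains signal) and
  15 endpoint-private bits, all disjoint, `beta = 2`;
* intercepts are calibrated by root-finding on the realized linear
  predictor so the post-noise positive rates hit 0.4323 / 0.5564 / 0.5301,
  the training-set rates of a representative curated panel;
* labels flip with probability 0.05; each endpoint then emits 1-3 assay
  records per compound (exercising the singleton, majority and tie voting
  paths) with per-record flip noise 0.10 and a 2% inconclusive rate;
* 5% of compounds lose all records of one endpoint group, exercising the
  complete-case filter.

The default panel size is 665 compounds, the size of the curated
complete-case panel this pipeline targets. Everything is reproducible
exactly from config + seed.

What the generator does **not** emulate: real substructure keys co-occur
(fragments nest and correlate), chemical series induce clustered rather
than independent compounds, and assay errors are not independent across
records of one compound. Passing tests on synthetic panels therefore
demonstrate that the machinery — integration, selection, fusion, metrics —
behaves correctly under a known ground truth; they do not certify predictive
performance on real chemistry.

## Numerical choices and degenerate inputs

* Rounding in printed tables is half-up (base R rounds half to even).
* Ranking and intersection tie-breaks are by ascending feature index.
* Grid-search ties take the first grid row.
* Empty top-set intersection is a warning plus empty selection (the
  pipeline then stops with an explicit error); single-class labels, empty
  outcome lists, unknown assay codes, malformed fingerprint files and
  mismatched feature schemas are all classed errors.
* A degenerate CV fold (single class after assignment) is redrawn once,
  then errors.

## Problem sizes used in the shipped checks

The test suite exercises small panels (40-400 compounds, 40-120 features)
for logic, and the documented study condition (2000 compounds, 881 bits,
20-bit core, beta 2, flip 0.05, quintile fraction 0.2, five seeds) for
feature recovery, where the quintile intersection recovers most of the
planted core while retaining under 2% of never-informative bits. The
bundled evaluation script runs the full pipeline on the default 665-compound
panel with reduced grids (RF trees {100, 300}; SVM C {1, 10} at the `scale`
width; BP 32 hidden units), which preserves the behaviour of interest at a
fraction of the full grid's cost; the full defaults remain available through
`run_pipeline(grids = NULL)`.

## Known limitations

* Fingerprint independence in the generator (above).
* The identity table supports exact-match deduplication only; resolving
  conflicting CAS/SMILES/InChI records is out of scope.
* Fusion is within one algorithm family; cross-family evidence combination
  is not implemented.
* No applicability-domain analysis: predictions for compounds far from the
  training distribution carry no warning.
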