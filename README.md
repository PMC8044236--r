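# mutafuse

Weight-of-evidence fusion models for mutagenicity QSAR.

No single genotoxicity assay detects every mutagenic mechanism, so
regulatory batteries combine a bacterial reverse mutation test with in vivo
and in vitro mammalian assays and judge a compound by weight of evidence:
positive if *any* assay group is positive, negative only when *all* are
negative. `mutafuse` builds QSAR classifiers with the same architecture.
It is aimed at computational toxicologists who have heterogeneous,
partially redundant assay records plus molecular fingerprints, and want a
battery-level mutagenicity call rather than a single-assay prediction.

## Method

1. **Integration.** Long-format assay records (compound x assay x
   positive/negative/inconclusive) are mapped onto three ICH S2(R1)
   endpoint groups — Y1 (Ames), Y2 (in vivo mammalian cytogenetics),
   Y3 (in vitro and germ-cell assays plus supplements). Within a group,
   outcomes are reduced by majority vote with exact ties judged positive;
   only compounds with usable data in all three groups are kept.
2. **Features.** Each compound carries the 881-bit PubChem substructure
   fingerprint (PaDEL-Descriptor CSV dialect). For each endpoint a random
   forest is fitted on the training split and every bit is scored by its
   mean |SHAP| attribution; the selected descriptor set is the intersection
   of the three per-endpoint first quintiles (top `floor(881 x 0.2) = 176`
   bits each).
3. **Sub-models.** Per endpoint and per algorithm family — random forest,
   RBF support-vector classifier (Platt-calibrated), and a
   single-hidden-layer backpropagation network — hyperparameters are chosen
   by exhaustive grid search under stratified five-fold cross-validation,
   scored by pooled out-of-fold accuracy Q.
4. **Fusion.** For each algorithm the three endpoint decisions d1, d2, d3
   fuse as `d1 OR d2 OR d3`, evaluated against the OR of the observed
   endpoint labels; scores fuse by noisy-OR,
   `1 - (1-s1)(1-s2)(1-s3)`, for ROC/AUC.
5. **Evaluation.** Accuracy `Q = (TP+TN)/n`, per-class precision, recall
   and `F1 = 2pr/(p+r)`, and midrank (Mann-Whitney) AUC with full ROC
   curves; zero-denominator metrics are reported as undefined (`NA`).

A synthetic panel generator (`generate_panel()`) produces compound panels
with planted informative bits — a shared core driving all three endpoints
plus endpoint-private sets — redundant noisy assay records, and
controllable missingness, with full ground truth for recovery tests.

## Worked example

```r
library(mutafuse)

## simulate an integrated genotoxicity panel (defaults: 665 compounds,
## 881 fingerprint bits, three correlated endpoints)
panel <- generate_panel(synthetic_config(seed = 42))

## integrate assay records into the three endpoint groups
integration <- build_label_table(panel$assays)
integration$report$n_complete
#> [1] 630

## full pipeline: join, 4:1 split, SHAP-quintile selection, grid search,
## weight-of-evidence fusion
res <- run_pipeline(panel$assays, panel$fingerprints,
                    algorithms = "rf",
                    grids = list(rf = data.frame(num_trees = 300L,
                                                 max_depth = 0L)),
                    seed = 42)
length(res$selection$selected)
#> [1] 25
head(res$selection$selected_names)
#> [1] "PubchemFP710" "PubchemFP1"   "PubchemFP294" "PubchemFP186"
#> [5] "PubchemFP652" "PubchemFP859"

subset(res$reports$accuracy_table, algorithm == "rf")
#>   algorithm  model train_cv_accuracy train_accuracy test_accuracy
#> 1        rf     Y1         0.6507937      0.9503968     0.5952381
#> 2        rf     Y2         0.6706349      0.9523810     0.5714286
#> 3        rf     Y3         0.5972222      0.9742063     0.6349206
#> 4        rf fusion         0.9742063      0.9742063     0.7460317

round(subset(res$reports$indicator_table, model == "fusion",
      c(recall_pos, precision_pos, f1_pos, accuracy, auc)), 3)
#>   recall_pos precision_pos f1_pos accuracy   auc
#> 4      0.857         0.841  0.849    0.746 0.678
```

Of 665 simulated compounds, 630 survive the complete-case filter (the rest
lost an endpoint group or had only inconclusive records in one). The
quintile intersection keeps 25 of 881 bits — the planted shared core plus a
few correlated private bits. The fusion row shows the characteristic
weight-of-evidence trade: its test accuracy (0.746) and positive-class
recall (0.857) exceed every sub-model's, because one positive sub-model
verdict suffices, at the cost of specificity. Sub-model training accuracies
(~0.95) sit far above their CV accuracies (~0.6-0.67) — the overfitting gap
that fusion alleviates at the battery level.

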