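#' Run the full weight-of-evidence QSAR pipeline
#'
#' End to end: integrate assay records into endpoint labels, join with the
#' fingerprint matrix, split train/test, select features by SHAP-quintile
#' intersection, grid-search the per-endpoint sub-models for each algorithm
#' family, fuse them under the all-negative-is-negative rule, and assemble
#' the report tables.
#'
#' @param assays long-format assay record data.frame (or a path readable by
#'   [read_assay_table()])
#' @param fingerprints fingerprint matrix (or a path readable by
#'   [read_fingerprint_table()])
#' @param algorithms algorithm families to train (default all three)
#' @param ratio train fraction (default 0.8, the 4:1 split)
#' @param fraction SHAP top fraction per endpoint (default 0.2, the first
#'   quintile)
#' @param seed integer master seed for split, selection and training
#' @param grids optional named list of hyperparameter grids per algorithm
#'   (defaults to [default_grid()])
#' @param cv_folds cross-validation folds (default 5)
#' @param taxonomy see [assay_taxonomy()]
#' @param shap_spec see [shap_backing_spec()]
#' @param out_dir if non-NULL, all artifacts (label table, report JSON,
#'   rankings, selected features, predictions, report tables) are written
#'   under this directory
#' @return list with `integration`, `dataset`, `selection`, `models` (per
#'   algorithm, per endpoint), `fusion` (per algorithm), `reports`
#' @export
run_pipeline <- function(assays, fingerprints,
                         algorithms = c("rf", "svm", "bp"),
                         ratio = 0.8, fraction = 0.2, seed = 1L,
                         grids = NULL, cv_folds = 5L,
                         taxonomy = assay_taxonomy(),
                         shap_spec = shap_backing_spec(),
                         out_dir = NULL) {
  if (is.character(assays)) assays <- read_assay_table(assays, taxonomy)
  if (is.character(fingerprints)) {
    fingerprints <- read_fingerprint_table(fingerprints, n_features = NULL)
  }
  integration <- build_label_table(assays, taxonomy)
  ds <- join_features_labels(fingerprints, integration$labels)
  ds <- split_train_test(ds, ratio = ratio, seed = seed)
  selection <- select_features(ds, fraction = fraction, spec = shap_spec,
                               seed = seed)
  if (length(selection$selected) == 0) {
    stop_mutafuse("feature selection returned an empty set",
                  "mutafuse_spec_error")
  }
  models <- list(); fusion <- list()
  for (alg in algorithms) {
    spec <- submodel_spec(alg, grid = grids[[alg]], cv_folds = cv_folds,
                          seed = seed)
    models[[alg]] <- train_endpoint_models(ds, selection$selected, spec)
    fusion[[alg]] <- evaluate_fusion(models[[alg]], ds)
  }
  result <- list(integration = integration, dataset = ds,
                 selection = selection, models = models, fusion = fusion)
  result$reports <- render_reports(result)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_label_table(integration, file.path(out_dir, "labels.csv"),
                      file.path(out_dir, "integration_report.json"))
    write_run_manifest(ds, file.path(out_dir, "run_manifest.json"))
    write_split_assignment(ds, file.path(out_dir, "split_assignment.csv"))
    write_feature_selection(selection, out_dir)
    for (alg in algorithms) {
      write_submodel_predictions(models[[alg]],
                                 file.path(out_dir,
                                           sprintf("predictions_%s.csv", alg)))
      write_fusion_predictions(fusion[[alg]],
                               file.path(out_dir,
                                         sprintf("fusion_%s.csv", alg)))
    }
    write_reports(result$reports, out_dir)
  }
  result
}
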