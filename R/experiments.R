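# Experiment harnesses: the position-window study (train on the first,
# centred, or last L residues) and the capsule ablation (same data and seed,
# capsule layer toggled).

evaluate_model <- function(model, test_ds) {
  pred <- predict(model, test_ds)
  metrics_report(test_ds$label, pred$p_tf)
}

#' Position-window experiment
#'
#' Trains one model per window position (upstream, centre, downstream) from
#' the same seed and configuration, evaluates each on the test split with the
#' matching windowing, and reports one metric row per position.
#'
#' @param train_ds,test_ds labeled `capstf_dataset` splits.
#' @param config a [capstf_config()]; its `window$position` is overridden.
#' @return list with `table` (3-row data.frame: Data, Sn, Sp, Acc, MCC, AUC),
#'   `metrics` (the raw per-position metric lists) and `models`.
#' @export
run_position_experiment <- function(train_ds, test_ds, config = capstf_config()) {
  positions <- c("upstream", "centre", "downstream")
  metrics <- list()
  models <- list()
  for (pos in positions) {
    cfg <- config
    cfg$window$position <- pos
    model <- train_capstf(train_ds, cfg)
    models[[pos]] <- model
    metrics[[sprintf("%s_%d", tools::toTitleCase(pos), cfg$window$length)]] <-
      evaluate_model(model, test_ds)
  }
  list(table = metrics_table(metrics, label_col = "Data"),
       metrics = metrics, models = models)
}

#' Capsule-ablation experiment
#'
#' Trains the full model and a variant with the capsule layer removed (its
#' place taken by mask-aware mean pooling over the BiLSTM outputs; the dense
#' head is unchanged) on the same data, seed and configuration, so any metric
#' difference is attributable to the capsule layer alone.
#'
#' @param train_ds,test_ds labeled `capstf_dataset` splits.
#' @param config a [capstf_config()]; its `model$use_capsule` is overridden.
#' @return list with `table` (rows With-Capsule, Non-Capsule), `metrics`,
#'   `models`, and `param_counts` (named parameter totals for both variants).
#' @export
run_ablation <- function(train_ds, test_ds, config = capstf_config()) {
  variants <- c("With-Capsule" = TRUE, "Non-Capsule" = FALSE)
  metrics <- list()
  models <- list()
  for (nm in names(variants)) {
    cfg <- config
    cfg$model$use_capsule <- variants[[nm]]
    model <- train_capstf(train_ds, cfg)
    models[[nm]] <- model
    metrics[[nm]] <- evaluate_model(model, test_ds)
  }
  list(table = metrics_table(metrics, label_col = "Method"),
       metrics = metrics, models = models,
       param_counts = vapply(models, count_params, numeric(1)))
}
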