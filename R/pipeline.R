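# End-to-end driver: one call from cohort generation to holdout
# evaluation. This is the programmatic equivalent of running the CLI
# stages simulate -> preprocess -> featurize -> train -> evaluate.

#' Default fixed random-forest configuration
#'
#' A degenerate search space (every range collapsed to a point) encoding
#' the package's reference random-forest configuration: 300 trees,
#' mtry = 30% of features, minimum node size 5. With `n_search = 1` this
#' is a direct fit.
#'
#' @return Named list usable as the `search` argument of [model_spec()].
#' @export
fixed_rf_search <- function() {
  list(num_trees = list(type = "int", lo = 300, hi = 300),
       mtry_frac = list(type = "unif", lo = 0.3, hi = 0.3),
       min_node_size = list(type = "int", lo = 5, hi = 5))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, preprocesses and featurises it, makes a
#' stratified patient-level 90/10 split, trains the requested model on
#' training samples, and fuses holdout window probabilities into
#' patient-level risks compared against the PIM3 baseline.
#'
#' @param config A [cohort_config()]; its seed drives every stage.
#' @param spec A [model_spec()]; default is the fixed reference random
#'   forest (direct fit, no search).
#' @param holdout_fraction Patient fraction held out, default 0.10.
#' @param refs Reference ranges for Z-scoring.
#' @return List: `cohort`, `samples` (with `balance_ratio` attribute),
#'   `plan`, `model`, `holdout` (data frame `patient_id, risk,
#'   n_samples, pim3_risk, died_30d`), and `auroc` (named vector
#'   `model`, `pim3` — patient-level holdout AUROC).
#' @export
run_pipeline <- function(config,
                         spec = model_spec("random_forest",
                                           search = fixed_rf_search(),
                                           n_search = 1,
                                           seed = config$seed),
                         holdout_fraction = 0.10,
                         refs = default_reference_ranges()) {
  cohort <- generate_cohort(config, refs = refs)
  z <- preprocess_cohort(cohort$vitals, cohort$ehr, refs = refs)
  samples <- featurize_cohort(z, cohort$ehr)
  plan <- split_patients(cohort$ehr, holdout_fraction = holdout_fraction,
                         seed = config$seed)
  train <- samples[samples$patient_id %in% plan$train_ids, ]
  holdout <- samples[samples$patient_id %in% plan$holdout_ids, ]
  model <- tune_and_train(train, spec)
  risk <- predict_patient_risk(model, holdout)
  i <- match(risk$patient_id, cohort$ehr$patient_id)
  risk$pim3_risk <- cohort$ehr$pim3_risk[i]
  risk$died_30d <- cohort$ehr$died_30d[i]
  auroc <- c(model = roc_auc(risk$died_30d, risk$risk),
             pim3 = roc_auc(risk$died_30d, risk$pim3_risk))
  list(cohort = cohort, samples = samples, plan = plan, model = model,
       holdout = risk, auroc = auroc)
}
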