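# Patient-level splitting, grouped-CV random-search tuning, sample-level
# training, patient-level risk fusion, and stacking. The unit of
# inference is the patient: splits and CV folds never share a patient
# between sides.

#' Stratified patient-level train/holdout split
#'
#' Splits by patient id, stratified by 30-day outcome: within each
#' outcome class, `round(n_class * holdout_fraction)` patients go to the
#' holdout. Deterministic given the seed.
#'
#' @param ehr Static table with `patient_id` and `died_30d`.
#' @param holdout_fraction Fraction of patients held out (default 0.10);
#'   must produce a non-empty holdout and leave at least one patient of
#'   each class on each side.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: list with `train_ids`,
#'   `holdout_ids`, `seed`, and `strata` (death rate per side).
#' @export
split_patients <- function(ehr, holdout_fraction = 0.10, seed = 1L) {
  stopifnot(all(c("patient_id", "died_30d") %in% names(ehr)))
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie strictly in (0, 1)")
  }
  cls <- split(ehr$patient_id, ehr$died_30d)
  if (length(cls) < 2 || any(lengths(cls) < 2)) {
    stop("need at least 2 patients per outcome class to split")
  }
  set.seed(seed)
  holdout <- unlist(lapply(cls, function(ids) {
    k <- round(length(ids) * holdout_fraction)
    if (k < 1 || k >= length(ids)) {
      stop("holdout_fraction leaves a class empty on one side")
    }
    sample(ids, k)
  }), use.names = FALSE)
  train <- setdiff(ehr$patient_id, holdout)
  rate <- function(ids) mean(ehr$died_30d[ehr$patient_id %in% ids])
  structure(list(train_ids = train, holdout_ids = holdout, seed = seed,
                 strata = c(train = rate(train), holdout = rate(holdout))),
            class = "split_plan")
}

#' Model specification for tuning
#'
#' @param backend One of `"random_forest"` (ranger),
#'   `"logistic_regression"` (penalised logistic via glmnet),
#'   `"xgboost_like"` (depth-wise gradient-boosted trees),
#'   `"lightgbm_like"` (histogram, leaf-wise / loss-guide growth —
#'   the growth strategy characteristic of LightGBM, implemented here
#'   through xgboost's loss-guide mode).
#' @param search Named list of hyperparameter ranges; each element is
#'   `list(type, lo, hi)` with type `"int"`, `"unif"` or `"logunif"`.
#'   Defaults per backend via [default_search_space()].
#' @param cv_folds Number of patient-grouped CV folds (>= 2), default 5.
#' @param n_search Number of random-search draws (>= 1).
#' @param seed Integer seed controlling draws and fold assignment.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(backend = c("random_forest", "logistic_regression",
                                   "xgboost_like", "lightgbm_like"),
                       search = NULL, cv_folds = 5, n_search = 10,
                       seed = 1L) {
  backend <- match.arg(backend)
  if (is.null(search)) search <- default_search_space(backend)
  stopifnot(length(search) > 0, cv_folds >= 2, n_search >= 1)
  structure(list(backend = backend, search = search,
                 cv_folds = as.integer(cv_folds),
                 n_search = as.integer(n_search), seed = as.integer(seed)),
            class = "model_spec")
}

#' Default random-search spaces per backend
#'
#' @param backend Backend name as in [model_spec()].
#' @return Named list of parameter ranges.
#' @export
default_search_space <- function(backend) {
  switch(backend,
    random_forest = list(
      num_trees = list(type = "int", lo = 100, hi = 400),
      mtry_frac = list(type = "unif", lo = 0.1, hi = 0.5),
      min_node_size = list(type = "int", lo = 1, hi = 10)),
    logistic_regression = list(
      alpha = list(type = "unif", lo = 0, hi = 1),
      lambda = list(type = "logunif", lo = 1e-4, hi = 1)),
    xgboost_like = list(
      nrounds = list(type = "int", lo = 50, hi = 300),
      eta = list(type = "logunif", lo = 0.01, hi = 0.3),
      max_depth = list(type = "int", lo = 2, hi = 8),
      subsample = list(type = "unif", lo = 0.6, hi = 1),
      colsample_bytree = list(type = "unif", lo = 0.5, hi = 1),
      min_child_weight = list(type = "int", lo = 1, hi = 10)),
    lightgbm_like = list(
      nrounds = list(type = "int", lo = 50, hi = 300),
      eta = list(type = "logunif", lo = 0.01, hi = 0.3),
      max_leaves = list(type = "int", lo = 8, hi = 64),
      subsample = list(type = "unif", lo = 0.6, hi = 1),
      colsample_bytree = list(type = "unif", lo = 0.5, hi = 1),
      min_child_weight = list(type = "int", lo = 1, hi = 10)),
    stop("unknown backend: ", backend))
}

.draw_config <- function(search) {
  lapply(search, function(p) {
    switch(p$type,
      # not sample(lo:hi, 1): that would sample 1:lo when lo == hi
      int = p$lo + sample.int(p$hi - p$lo + 1L, 1) - 1L,
      unif = runif(1, p$lo, p$hi),
      logunif = exp(runif(1, log(p$lo), log(p$hi))),
      stop("unknown search-space type: ", p$type))
  })
}

# patient-grouped, outcome-stratified fold assignment: returns named
# integer vector patient_id -> fold
.grouped_folds <- function(patient_ids, labels, k) {
  pat <- unique(data.frame(patient_id = patient_ids, label = labels,
                           stringsAsFactors = FALSE))
  fold <- integer(nrow(pat))
  for (lv in unique(pat$label)) {
    idx <- which(pat$label == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  setNames(fold, pat$patient_id)
}

.fit_backend <- function(backend, X, y, hp, seed) {
  set.seed(seed)
  switch(backend,
    random_forest = ranger::ranger(
      x = X, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$num_trees,
      mtry = max(1L, floor(hp$mtry_frac * ncol(X))),
      min.node.size = hp$min_node_size,
      seed = seed, num.threads = 1, verbose = FALSE),
    logistic_regression = glmnet::glmnet(
      x = X, y = y, family = "binomial",
      alpha = hp$alpha, lambda = hp$lambda,
      standardize = TRUE),
    xgboost_like = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    min_child_weight = hp$min_child_weight,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nrounds, verbose = 0),
    lightgbm_like = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    tree_method = "hist", grow_policy = "lossguide",
                    max_depth = 0, max_leaves = hp$max_leaves,
                    subsample = hp$subsample,
                    colsample_bytree = hp$colsample_bytree,
                    min_child_weight = hp$min_child_weight,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = hp$nrounds, verbose = 0),
    stop("unknown backend: ", backend))
}

.predict_backend <- function(backend, fit, X) {
  switch(backend,
    random_forest = {
      p <- predict(fit, data = X, num.threads = 1)$predictions
      unname(p[, "1"])
    },
    logistic_regression = as.numeric(predict(fit, newx = X,
                                             type = "response")[, 1]),
    xgboost_like = ,
    lightgbm_like = as.numeric(predict(fit, xgboost::xgb.DMatrix(X))),
    stop("unknown backend: ", backend))
}

#' Tune hyperparameters by grouped CV and train the final model
#'
#' Random search over the spec's space: each candidate configuration is
#' scored by mean AUROC over patient-grouped, outcome-stratified CV folds
#' (no patient's windows ever span a fold boundary); the best
#' configuration is refit on all training samples.
#'
#' @param samples Samples table from [featurize_cohort()] (must contain
#'   both labels).
#' @param spec A [model_spec()].
#' @return Object of class `vr_model`: fitted backend, chosen
#'   hyperparameters, feature-ordering contract, CV results and training
#'   metadata.
#' @export
tune_and_train <- function(samples, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- samples$label
  if (length(unique(y)) < 2) stop("training samples contain a single class")
  X <- feature_matrix(samples)
  set.seed(spec$seed)
  folds <- .grouped_folds(samples$patient_id, y, spec$cv_folds)
  fold_of <- folds[samples$patient_id]
  configs <- lapply(seq_len(spec$n_search), function(i) .draw_config(spec$search))
  if (spec$n_search == 1L) {
    # single candidate: direct fit, no CV scoring needed
    hp <- configs[[1L]]
    fit <- .fit_backend(spec$backend, X, y, hp, spec$seed)
    return(structure(list(backend = spec$backend, fit = fit, hyperparams = hp,
                          feature_names = colnames(X),
                          cv = list(auc = NA_real_, best = 1L, folds = folds),
                          meta = list(seed = spec$seed,
                                      cv_folds = spec$cv_folds,
                                      n_search = 1L, n_samples = nrow(X))),
                     class = "vr_model"))
  }
  cv_auc <- vapply(configs, function(hp) {
    aucs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold_of != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        return(NA_real_)
      }
      fit <- .fit_backend(spec$backend, X[tr, , drop = FALSE], y[tr],
                          hp, spec$seed + f)
      roc_auc(y[!tr], .predict_backend(spec$backend, fit, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_auc)
  hp <- configs[[best]]
  fit <- .fit_backend(spec$backend, X, y, hp, spec$seed)
  structure(list(backend = spec$backend, fit = fit, hyperparams = hp,
                 feature_names = colnames(X),
                 cv = list(auc = cv_auc, best = best, folds = folds),
                 meta = list(seed = spec$seed, cv_folds = spec$cv_folds,
                             n_search = spec$n_search,
                             n_samples = nrow(X))),
            class = "vr_model")
}

#' Predict window-level mortality probabilities
#'
#' @param object A `vr_model`.
#' @param newdata Samples table or numeric matrix; columns must contain
#'   the model's feature contract (order is re-established by name, and
#'   vectors violating the contract are rejected).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.vr_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else {
    as.matrix(newdata[, intersect(names(newdata), object$feature_names),
                      drop = FALSE])
  }
  if (!all(object$feature_names %in% colnames(X))) {
    stop("newdata violates the model's feature contract")
  }
  X <- X[, object$feature_names, drop = FALSE]
  if (object$backend == "stack") {
    base_p <- vapply(object$fit$base, function(b) predict(b, X),
                     numeric(nrow(X)))
    if (is.null(dim(base_p))) base_p <- matrix(base_p, nrow = 1)
    nd <- as.data.frame(base_p)
    names(nd) <- paste0("base", seq_along(object$fit$base))
    as.numeric(predict(object$fit$meta, newdata = nd, type = "response"))
  } else {
    .predict_backend(object$backend, object$fit, X)
  }
}

#' @exportS3Method base::print
print.vr_model <- function(x, ...) {
  cat("<vr_model>", x$backend, "\n")
  cat("  features:", length(x$feature_names),
      " samples:", x$meta$n_samples, "\n")
  cat("  hyperparameters:",
      paste(names(x$hyperparams),
            vapply(x$hyperparams, function(v) format(v, digits = 3),
                   character(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Fuse window probabilities into patient-level risk
#'
#' The patient's 30-day mortality risk is the arithmetic mean of the
#' predicted probabilities of all of that patient's window samples.
#'
#' @param model A `vr_model`.
#' @param samples Samples table (one or many patients); must be
#'   non-empty.
#' @return Data frame `patient_id`, `risk`, `n_samples`.
#' @export
predict_patient_risk <- function(model, samples) {
  if (nrow(samples) == 0L) stop("no usable windows")
  p <- predict(model, samples)
  agg <- aggregate(p, by = list(patient_id = samples$patient_id),
                   FUN = mean)
  cnt <- as.data.frame(table(samples$patient_id), stringsAsFactors = FALSE)
  data.frame(patient_id = agg$patient_id, risk = agg$x,
             n_samples = cnt$Freq[match(agg$patient_id, cnt$Var1)],
             stringsAsFactors = FALSE)
}

#' Stack base models with a logistic meta-learner
#'
#' Out-of-fold predictions of each base model (refit per fold with its
#' chosen hyperparameters, folds grouped by patient) feed a logistic
#' regression meta-model. The result honours the same probability and
#' feature contracts as any `vr_model`.
#'
#' @param base_models List of >= 2 trained `vr_model`s sharing one
#'   feature contract.
#' @param samples Training samples table.
#' @param seed Integer seed for fold assignment.
#' @param cv_folds Folds used to produce out-of-fold predictions.
#' @return A `vr_model` with backend `"stack"`.
#' @export
stack_models <- function(base_models, samples, seed = 1L, cv_folds = 5) {
  stopifnot(length(base_models) >= 2)
  contracts <- lapply(base_models, `[[`, "feature_names")
  if (!all(vapply(contracts, identical, logical(1), contracts[[1]]))) {
    stop("base models have mismatched feature contracts")
  }
  y <- samples$label
  X <- feature_matrix(samples)
  set.seed(seed)
  folds <- .grouped_folds(samples$patient_id, y, cv_folds)
  fold_of <- folds[samples$patient_id]
  oof <- matrix(NA_real_, nrow = nrow(X), ncol = length(base_models))
  for (f in seq_len(cv_folds)) {
    tr <- fold_of != f
    for (b in seq_along(base_models)) {
      bm <- base_models[[b]]
      fit <- .fit_backend(bm$backend, X[tr, , drop = FALSE], y[tr],
                          bm$hyperparams, seed + f)
      oof[!tr, b] <- .predict_backend(bm$backend, fit, X[!tr, , drop = FALSE])
    }
  }
  nd <- as.data.frame(oof)
  names(nd) <- paste0("base", seq_along(base_models))
  meta <- glm(y ~ ., data = cbind(y = y, nd), family = binomial())
  structure(list(backend = "stack",
                 fit = list(base = base_models, meta = meta),
                 hyperparams = list(cv_folds = cv_folds),
                 feature_names = base_models[[1]]$feature_names,
                 meta = list(seed = seed, cv_folds = cv_folds,
                             n_samples = nrow(X))),
            class = "vr_model")
}
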