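# Metric suite: rank-formula AUROC, confusion-matrix metrics, stepwise
# average precision, patient-level percentile bootstrap, and comparison
# against the PIM3-style single-time-point baseline.

#' Area under the ROC curve (rank formulation)
#'
#' Mann–Whitney form: the probability that a random positive scores
#' above a random negative, with ties counted half, computed from
#' mid-ranks.
#'
#' @param labels 0/1 (or logical) outcome vector; both classes required.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 0, 1, 0, 0), c(0.9, 0.8, 0.7, 0.3, 0.1))
roc_auc <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(y) == length(scores), !anyNA(y), !anyNA(scores))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # mid-ranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (stepwise area under the precision–recall curve)
#'
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over descending score thresholds,
#' with tied scores grouped into a single step.
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  if (sum(y) == 0L) stop("no positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y)
  k <- seq_along(y)
  # keep only the last index of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  prec <- tp[last] / k[last]
  rec <- tp[last] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Thresholded and threshold-free classification metrics
#'
#' MCC, PPV (precision), NPV, recall (sensitivity) and F1 from the
#' confusion matrix at `threshold` (score >= threshold predicts
#' positive); AUROC and AP are threshold-free. Degenerate denominators
#' yield 0 for the affected metric (flagged in the `degenerate`
#' attribute) rather than an error.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Named numeric vector `auroc, mcc, ppv, npv, recall, f1, ap`,
#'   with attribute `confusion` (tp, fp, fn, tn) and `degenerate`
#'   (character vector of zero-denominator metrics).
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  degen <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) { degen <<- c(degen, nm); 0 } else num / den
  }
  ppv <- safe(tp, tp + fp, "ppv")
  npv <- safe(tn, tn + fn, "npv")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { degen <- c(degen, "mcc"); 0 } else {
    (tp * tn - fp * fn) / mcc_den
  }
  out <- c(auroc = roc_auc(y, scores), mcc = mcc, ppv = ppv, npv = npv,
           recall = recall, f1 = f1, ap = average_precision(y, scores))
  attr(out, "confusion") <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  attr(out, "degenerate") <- degen
  out
}

#' Youden's J optimal threshold
#'
#' The score threshold maximising sensitivity + specificity − 1 over the
#' observed scores. Used as the default operating point when no
#' threshold is configured (the report always records the one used).
#'
#' @inheritParams roc_auc
#' @return A single threshold value.
#' @export
youden_threshold <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sens <- sum(scores >= t & y == 1) / sum(y == 1)
    spec <- sum(scores < t & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  thr[which.max(j)]
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples patients (rows) with replacement `n_boot` times and takes
#' the percentile 2.5/97.5 interval of the metric. Resamples containing
#' a single outcome class are redrawn (the count is recorded in the
#' `n_redrawn` attribute).
#'
#' @inheritParams roc_auc
#' @param metric Function `(labels, scores) -> number`, e.g. [roc_auc()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level, default 0.95.
#' @return Numeric `c(lo, hi)` with attribute `n_redrawn`.
#' @export
bootstrap_ci <- function(labels, scores, metric = roc_auc, n_boot = 1000,
                         seed = 1L, conf = 0.95) {
  stopifnot(n_boot >= 100)
  y <- as.integer(as.logical(labels))
  n <- length(y)
  set.seed(seed)
  vals <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) stop("metric undefined on all resamples")
    }
    vals[b] <- metric(y[idx], scores[idx])
  }
  a <- (1 - conf) / 2
  out <- unname(quantile(vals, c(a, 1 - a), type = 7))
  names(out) <- c("lo", "hi")
  attr(out, "n_redrawn") <- redrawn
  out
}

#' Full metrics report with bootstrap confidence intervals
#'
#' @inheritParams bootstrap_ci
#' @param threshold Decision threshold; `NULL` (default) selects Youden's
#'   J maximiser on the supplied data.
#' @return Object of class `vr_metrics_report`: data frame
#'   (`metric, estimate, lo, hi`) with attributes `threshold`, `n`,
#'   `n_events`.
#' @export
metrics_report <- function(labels, scores, threshold = NULL, n_boot = 1000,
                           seed = 1L) {
  y <- as.integer(as.logical(labels))
  if (is.null(threshold)) threshold <- youden_threshold(y, scores)
  pt <- classification_metrics(y, scores, threshold)
  cis <- lapply(names(pt), function(nm) {
    bootstrap_ci(y, scores,
                 metric = function(l, s) {
                   unname(classification_metrics(l, s, threshold)[nm])
                 },
                 n_boot = n_boot, seed = seed)
  })
  out <- data.frame(metric = names(pt), estimate = unname(pt),
                    lo = vapply(cis, `[[`, numeric(1), "lo"),
                    hi = vapply(cis, `[[`, numeric(1), "hi"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "n") <- length(y)
  attr(out, "n_events") <- sum(y)
  class(out) <- c("vr_metrics_report", "data.frame")
  out
}

#' Compare model risk against the PIM3-style baseline
#'
#' Computes a [metrics_report()] for the fused model risk and for the
#' single-time-point baseline risk on the same patients, plus a
#' per-patient scatter export (`patient_id, model_risk, pim3_risk,
#' outcome`).
#'
#' @param model_risks Data frame `patient_id, risk` (e.g. from
#'   [predict_patient_risk()]).
#' @param pim3_risks Data frame `patient_id, risk` of baseline risks for
#'   the same patient set.
#' @param labels Data frame `patient_id, died_30d` (or a named logical
#'   vector).
#' @param n_boot,seed Passed to [metrics_report()].
#' @return List `model` (report), `baseline` (report), `scatter`
#'   (data frame with one row per patient).
#' @export
compare_to_baseline <- function(model_risks, pim3_risks, labels,
                                n_boot = 1000, seed = 1L) {
  if (!is.data.frame(labels)) {
    labels <- data.frame(patient_id = names(labels),
                         died_30d = as.logical(labels),
                         stringsAsFactors = FALSE)
  }
  ids <- sort(model_risks$patient_id)
  if (!identical(ids, sort(pim3_risks$patient_id)) ||
      !all(ids %in% labels$patient_id)) {
    stop("patient id mismatch between model, baseline and labels")
  }
  y <- labels$died_30d[match(ids, labels$patient_id)]
  mr <- model_risks$risk[match(ids, model_risks$patient_id)]
  br <- pim3_risks$risk[match(ids, pim3_risks$patient_id)]
  list(
    model = metrics_report(y, mr, n_boot = n_boot, seed = seed),
    baseline = metrics_report(y, br, n_boot = n_boot, seed = seed),
    scatter = data.frame(patient_id = ids, model_risk = mr,
                         pim3_risk = br, outcome = y,
                         stringsAsFactors = FALSE)
  )
}
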