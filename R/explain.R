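# Model-agnostic Shapley attribution of window-level risk predictions,
# per-window risk traces over a transport episode, and detection of the
# moments at which a feature's contribution flips from favouring
# survival to favouring non-survival.

#' Shapley attributions for one feature vector
#'
#' Attributions are computed in the model's probability output space.
#' `mode = "exact"` enumerates all feature coalitions; the value of a
#' coalition S is the mean prediction over the background set with
#' features outside S replaced by the background row's values. Exact
#' mode satisfies local accuracy (`base + sum(phi) == prediction`) to
#' machine precision and the dummy axiom, but costs `2^p` coalition
#' evaluations, so it is capped at `exact_cap` features.
#' `mode = "sampled"` uses seeded permutation sampling: for each of
#' `n_perms` permutations a background row is drawn and features are
#' switched in one at a time in permutation order, assigning each its
#' marginal contribution. Because each permutation telescopes from the
#' background prediction to the instance prediction, local accuracy
#' holds exactly with the base value defined as the mean prediction over
#' the drawn background rows; per-feature Monte-Carlo standard errors
#' are reported.
#'
#' @param predict_fn Function mapping a numeric matrix (rows = feature
#'   vectors in contract order) to probabilities.
#' @param instance Named numeric feature vector.
#' @param background Matrix or data frame of background feature vectors
#'   (non-empty), same columns as `instance`.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_perms Permutations for sampled mode (>= 100).
#' @param seed Integer seed (sampled mode).
#' @param exact_cap Maximum feature count admitted in exact mode.
#' @return Object of class `vr_attribution`: list with `phi` (named
#'   contributions), `base`, `prediction`, and `se` (sampled mode only).
#' @export
shapley_attributions <- function(predict_fn, instance, background,
                                 mode = c("sampled", "exact"),
                                 n_perms = 200, seed = 1L,
                                 exact_cap = 12L) {
  mode <- match.arg(mode)
  bg <- as.matrix(background)
  if (nrow(bg) == 0L) stop("background set is empty")
  x <- as.numeric(instance)
  p <- length(x)
  stopifnot(ncol(bg) == p)
  nms <- names(instance) %||% colnames(bg) %||% paste0("f", seq_len(p))
  pred <- as.numeric(predict_fn(matrix(x, nrow = 1,
                                       dimnames = list(NULL, nms))))

  if (mode == "exact") {
    if (p > exact_cap) {
      stop("exact mode admits at most ", exact_cap,
           " features; use mode = 'sampled'")
    }
    phi <- .shapley_exact(predict_fn, x, bg, nms)
    base <- mean(as.numeric(predict_fn(`colnames<-`(bg, nms))))
    out <- list(phi = setNames(phi, nms), base = base, prediction = pred,
                se = NULL, mode = "exact")
  } else {
    if (n_perms < 100) stop("sampled mode requires n_perms >= 100")
    set.seed(seed)
    contrib <- matrix(0, nrow = n_perms, ncol = p)
    bg_pred_sum <- 0
    for (k in seq_len(n_perms)) {
      b <- bg[sample.int(nrow(bg), 1L), ]
      perm <- sample.int(p)
      # rows: background, then switch features to x in perm order
      rows <- matrix(rep(b, p + 1L), nrow = p + 1L, byrow = TRUE)
      for (j in seq_len(p)) {
        rows[(j + 1L):(p + 1L), perm[j]] <- x[perm[j]]
      }
      colnames(rows) <- nms
      f <- as.numeric(predict_fn(rows))
      contrib[k, perm] <- diff(f)
      bg_pred_sum <- bg_pred_sum + f[1L]
    }
    phi <- colMeans(contrib)
    se <- apply(contrib, 2, sd) / sqrt(n_perms)
    base <- bg_pred_sum / n_perms
    out <- list(phi = setNames(phi, nms), base = base, prediction = pred,
                se = setNames(se, nms), mode = "sampled")
  }
  class(out) <- "vr_attribution"
  out
}

# exact Shapley by coalition enumeration over bit masks
.shapley_exact <- function(predict_fn, x, bg, nms) {
  p <- length(x)
  nb <- nrow(bg)
  nS <- 2L^p
  # v[mask+1] = mean prediction with features in mask set to x
  v <- numeric(nS)
  for (mask in 0:(nS - 1L)) {
    inS <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))))
    rows <- bg
    if (any(inS)) rows[, inS] <- matrix(x[inS], nrow = nb, ncol = sum(inS),
                                        byrow = TRUE)
    colnames(rows) <- nms
    v[mask + 1L] <- mean(as.numeric(predict_fn(rows)))
  }
  sizes <- vapply(0:(nS - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0), numeric(1))
  wt <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) / factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(nS - 1L), bit) == 0L) - 1L
    sz <- sizes[without + 1L]
    phi[j] <- sum(wt[sz + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  phi
}

#' @exportS3Method base::print
print.vr_attribution <- function(x, ...) {
  cat("<vr_attribution>", x$mode, "mode\n")
  cat("  prediction:", format(x$prediction, digits = 4),
      " base:", format(x$base, digits = 4), "\n")
  top <- sort(abs(x$phi), decreasing = TRUE)
  show <- names(head(top, 5))
  cat("  top |phi|:",
      paste(show, format(x$phi[show], digits = 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-window risk trace with attributions for one patient
#'
#' Splits the patient's preprocessed Z-score stream into consecutive
#' non-overlapping intervals (default 10 min), featurises each interval,
#' predicts the window risk and attributes it with
#' [shapley_attributions()]. An episode shorter than one interval yields
#' an empty trace with a warning.
#'
#' @param model A `vr_model`.
#' @param z Z-score data frame for a single patient.
#' @param patient One-row EHR data frame for that patient.
#' @param background Background feature matrix (rows in the model's
#'   feature contract), e.g. a seeded subsample of training samples via
#'   [background_from_samples()].
#' @param interval_minutes Interval duration, default 10.
#' @param mode,n_perms,seed Passed to [shapley_attributions()]; the same
#'   seed is reused for every window (common random numbers), so
#'   window-to-window attribution changes reflect the data rather than
#'   estimator noise.
#' @return Object of class `vr_risk_trace`: list with `patient_id`,
#'   `windows` (data frame `start_s, end_s, risk`) and `attributions`
#'   (list of `vr_attribution`, one per window).
#' @export
risk_trace <- function(model, z, patient, background,
                       interval_minutes = 10, mode = "sampled",
                       n_perms = 200, seed = 1L) {
  spec <- window_spec(window_minutes = interval_minutes)
  wins <- extract_windows(z, outcome_deceased = FALSE, spec = spec)
  if (!length(wins)) {
    warning("no complete interval in the monitored episode; empty trace")
    return(structure(list(patient_id = patient$patient_id,
                          windows = data.frame(start_s = numeric(),
                                               end_s = numeric(),
                                               risk = numeric()),
                          attributions = list()),
                     class = "vr_risk_trace"))
  }
  ts <- sort(unique(z$time_s))
  dt <- if (length(ts) > 1) stats::median(diff(ts)) else 1
  predict_fn <- function(X) predict(model, X)
  records <- lapply(seq_along(wins), function(i) {
    wn <- wins[[i]]
    fv <- assemble_sample(patient, wn$zmat, dt)
    risk <- as.numeric(predict_fn(matrix(fv, nrow = 1,
                                         dimnames = list(NULL, names(fv)))))
    # common random numbers across windows: every window reuses the same
    # permutations and background draws, so window-to-window attribution
    # changes reflect the data, not Monte-Carlo resampling noise
    att <- shapley_attributions(predict_fn, fv, background, mode = mode,
                                n_perms = n_perms, seed = seed)
    list(start_s = wn$start_s, end_s = wn$end_s, risk = risk, att = att)
  })
  structure(list(
    patient_id = patient$patient_id,
    windows = data.frame(
      start_s = vapply(records, `[[`, numeric(1), "start_s"),
      end_s = vapply(records, `[[`, numeric(1), "end_s"),
      risk = vapply(records, `[[`, numeric(1), "risk")),
    attributions = lapply(records, `[[`, "att")),
    class = "vr_risk_trace")
}

#' Draw a seeded background subsample from a samples table
#'
#' @param samples Samples table ([featurize_cohort()]).
#' @param n Background size (default 100, capped at the table size).
#' @param seed Integer seed.
#' @return Numeric matrix of background feature vectors.
#' @export
background_from_samples <- function(samples, n = 100, seed = 1L) {
  set.seed(seed)
  idx <- sample.int(nrow(samples), min(n, nrow(samples)))
  feature_matrix(samples[idx, , drop = FALSE])
}

#' Detect survival-to-non-survival transition moments
#'
#' For each feature, emits an event at every window where its
#' contribution changes from `<= 0` (favouring survival) in the previous
#' window to `> 0` (favouring non-survival), optionally outside a
#' dead-zone band. Events are ordered by window time, then feature name.
#'
#' @param trace A `vr_risk_trace` with at least 2 windows.
#' @param dead_zone Half-width of a band around 0 that a flip must
#'   clear (`before <= -dead_zone`, `after > dead_zone`); default 0,
#'   the strict sign-flip reading.
#' @return Data frame `window_index, time_s, feature, before, after`
#'   (zero rows when nothing flips).
#' @export
detect_transitions <- function(trace, dead_zone = 0) {
  stopifnot(inherits(trace, "vr_risk_trace"))
  nw <- nrow(trace$windows)
  if (nw < 2) stop("trace must contain at least 2 windows")
  phis <- do.call(rbind, lapply(trace$attributions, function(a) a$phi))
  events <- list()
  for (w in 2:nw) {
    flip <- phis[w - 1, ] <= -dead_zone & phis[w, ] > dead_zone
    if (!any(flip)) next
    feats <- sort(colnames(phis)[flip])
    events[[length(events) + 1L]] <- data.frame(
      window_index = w,
      time_s = trace$windows$start_s[w],
      feature = feats,
      before = unname(phis[w - 1, feats]),
      after = unname(phis[w, feats]),
      stringsAsFactors = FALSE)
  }
  if (!length(events)) {
    return(data.frame(window_index = integer(), time_s = numeric(),
                      feature = character(), before = numeric(),
                      after = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Export a risk trace as dashboard-ready JSON and tidy CSV
#'
#' JSON carries, per window, the risk, base value and named
#' contributions; the CSV is tidy (one row per window x feature) for
#' plotting.
#'
#' @param trace A `vr_risk_trace`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param csv_path Output CSV path (`NULL` to skip).
#' @return The list that was serialised, invisibly.
#' @export
export_trace <- function(trace, json_path = NULL, csv_path = NULL) {
  payload <- list(
    patient_id = trace$patient_id,
    windows = lapply(seq_len(nrow(trace$windows)), function(i) {
      a <- trace$attributions[[i]]
      list(start_s = trace$windows$start_s[i],
           end_s = trace$windows$end_s[i],
           risk = trace$windows$risk[i],
           base = a$base,
           contributions = as.list(a$phi))
    }))
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    tidy <- do.call(rbind, lapply(seq_len(nrow(trace$windows)), function(i) {
      a <- trace$attributions[[i]]
      data.frame(patient_id = trace$patient_id,
                 window_index = i,
                 start_s = trace$windows$start_s[i],
                 risk = trace$windows$risk[i],
                 base = a$base,
                 feature = names(a$phi),
                 phi = unname(a$phi),
                 stringsAsFactors = FALSE)
    }))
    write.csv(tidy, csv_path, row.names = FALSE)
  }
  invisible(payload)
}
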