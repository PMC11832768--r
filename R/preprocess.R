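# Cleaning, imputation and age-adjusted Z-scoring of vital-sign streams.
# Fixed stage order: clean -> impute -> standardise.

#' Remove clinically implausible values
#'
#' Values outside the channel's closed plausibility interval `[lo, hi]`
#' are converted to missing (`NA`); timestamps are retained and in-range
#' values are unchanged, so cleaning is idempotent. Out-of-range values
#' are *not* clipped — clipping would fabricate physiology.
#'
#' @param vitals Long-format data frame
#'   (`patient_id, channel, time_s, value`), one or many patients.
#' @param bounds Plausibility bounds, see [default_plausibility_bounds()].
#' @return The cleaned data frame, with attribute `n_removed` giving the
#'   count of values newly marked missing.
#' @export
#' @examples
#' v <- data.frame(patient_id = "p", channel = "HR",
#'                 time_s = 0:2, value = c(120, 350, 80))
#' cleaned <- clean_series(v)
#' attr(cleaned, "n_removed")  # 1
clean_series <- function(vitals, bounds = default_plausibility_bounds()) {
  stopifnot(all(c("channel", "value") %in% names(vitals)))
  if (nrow(vitals) == 0L) {
    attr(vitals, "n_removed") <- 0L
    return(vitals)
  }
  miss <- setdiff(unique(vitals$channel), bounds$channel)
  if (length(miss)) {
    stop("channel(s) absent from bounds: ", paste(miss, collapse = ", "))
  }
  i <- match(vitals$channel, bounds$channel)
  lo <- bounds$lo[i]; hi <- bounds$hi[i]
  bad <- !is.na(vitals$value) & (vitals$value < lo | vitals$value > hi)
  vitals$value[bad] <- NA_real_
  attr(vitals, "n_removed") <- sum(bad)
  vitals
}

#' Impute missing values in vital-sign streams
#'
#' Default per-channel policy: linear interpolation in time for interior
#' gaps, nearest observed value for leading/trailing gaps. Observed
#' values are never altered. A (patient, channel) series with zero
#' observed values cannot be imputed; it is dropped and recorded in the
#' `dropped` attribute (patient, channel, reason), to be excluded
#' downstream.
#'
#' @param vitals Long-format data frame, ideally already passed through
#'   [clean_series()].
#' @param policy Named list channel -> method; methods currently
#'   supported: `"linear"` (interpolate + nearest-edge fill, the default
#'   for every channel) and `"locf"` (last observation carried forward,
#'   nearest-edge back-fill at the start).
#' @return Data frame with no missing values, with attribute `dropped`
#'   (data frame of excluded series, possibly empty).
#' @export
impute_series <- function(vitals, policy = list()) {
  stopifnot(all(c("patient_id", "channel", "time_s", "value") %in% names(vitals)))
  if (nrow(vitals) == 0L) {
    attr(vitals, "dropped") <- .empty_drop_log()
    return(vitals)
  }
  # group (patient, channel) runs without materialising sub-data-frames;
  # streams from the generator are already contiguous and time-ordered,
  # so the sort is cheap in the common case
  pid_f <- factor(vitals$patient_id)
  ch_f <- factor(vitals$channel)
  gkey <- (as.integer(pid_f) - 1L) * nlevels(ch_f) + as.integer(ch_f)
  o <- order(gkey, vitals$time_s, method = "radix")
  if (is.unsorted(o)) {
    vitals <- vitals[o, ]
    gkey <- gkey[o]
  }
  r <- rle(gkey)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  val <- vitals$value
  tim <- vitals$time_s
  chan <- as.character(vitals$channel)
  keep <- rep(TRUE, length(val))
  dropped <- list()
  for (g in seq_along(starts)) {
    i1 <- starts[g]; i2 <- ends[g]
    x <- val[i1:i2]
    obs <- !is.na(x)
    if (all(obs)) next
    if (!any(obs)) {
      keep[i1:i2] <- FALSE
      dropped[[length(dropped) + 1L]] <- data.frame(
        patient_id = vitals$patient_id[i1], channel = chan[i1],
        reason = "unimputable: no observed values", stringsAsFactors = FALSE)
      next
    }
    method <- policy[[chan[i1]]]
    if (is.null(method)) method <- "linear"
    val[i1:i2] <- switch(method,
      linear = {
        tt <- tim[i1:i2]
        if (sum(obs) == 1L) {
          v <- rep(x[obs], length(x))
          obs <- rep(TRUE, length(obs))  # fully filled
        } else {
        v <- approx(x = tt[obs], y = x[obs], xout = tt, method = "linear",
                    rule = 1)$y
        }
        # nearest-value fill at the edges
        first <- which.max(obs); last <- length(obs) + 1L - which.max(rev(obs))
        if (first > 1L) v[seq_len(first - 1L)] <- x[first]
        if (last < length(obs)) v[(last + 1L):length(obs)] <- x[last]
        v
      },
      locf = {
        v <- zoo::na.locf(x, na.rm = FALSE)
        zoo::na.locf(v, fromLast = TRUE, na.rm = FALSE)
      },
      stop("unknown imputation method: ", method)
    )
  }
  vitals$value <- val
  res <- if (all(keep)) vitals else vitals[keep, ]
  rownames(res) <- NULL
  attr(res, "dropped") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else .empty_drop_log()
  res
}

.empty_drop_log <- function() {
  data.frame(patient_id = character(), channel = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Standardise vital signs to age-adjusted Z-scores
#'
#' Applies `z = (value - ref_mean) / ref_sd` elementwise, where the
#' reference mean and SD depend on the patient's age group and the
#' channel. This removes the strong age dependence of paediatric vital
#' signs so that model features measure deviation from the age-expected
#' norm. Shape and timestamps are preserved; the transform is exactly
#' invertible (`value = z * ref_sd + ref_mean`).
#'
#' @param vitals Long-format data frame for patients present in `ehr`.
#' @param ehr Static table supplying `patient_id` and `age_group`.
#' @param refs Reference ranges ([default_reference_ranges()] or a table
#'   read via [read_reference_ranges()]).
#' @return Data frame `patient_id, channel, time_s, zvalue`.
#' @export
standardize_series <- function(vitals, ehr, refs = default_reference_ranges()) {
  stopifnot(all(c("patient_id", "channel", "time_s", "value") %in% names(vitals)),
            all(c("patient_id", "age_group") %in% names(ehr)))
  validate_reference_ranges(refs)
  ag <- ehr$age_group[match(vitals$patient_id, ehr$patient_id)]
  if (anyNA(ag)) stop("vitals contain patient_id(s) absent from ehr")
  # integer-composite key: avoids paste() over tens of millions of rows
  g_lv <- unique(refs$age_group); c_lv <- unique(refs$channel)
  key_ref <- (match(refs$age_group, g_lv) - 1L) * length(c_lv) +
    match(refs$channel, c_lv)
  key <- (match(ag, g_lv) - 1L) * length(c_lv) + match(vitals$channel, c_lv)
  i <- match(key, key_ref)
  if (anyNA(i)) {
    bad <- unique(paste(ag[is.na(i)], vitals$channel[is.na(i)], sep = "/"))
    stop("missing reference range for: ", paste(bad, collapse = ", "))
  }
  out <- vitals[c("patient_id", "channel", "time_s")]
  out$zvalue <- (vitals$value - refs$ref_mean[i]) / refs$ref_sd[i]
  out
}

#' Run the full preprocessing chain on a cohort
#'
#' Convenience wrapper applying the fixed stage order
#' clean -> impute -> standardise.
#'
#' @inheritParams standardize_series
#' @param bounds Plausibility bounds.
#' @param policy Imputation policy, see [impute_series()].
#' @return Z-score data frame as from [standardize_series()], with
#'   attributes `n_removed` (cleaning) and `dropped` (unimputable series).
#' @export
preprocess_cohort <- function(vitals, ehr,
                              bounds = default_plausibility_bounds(),
                              refs = default_reference_ranges(),
                              policy = list()) {
  cleaned <- clean_series(vitals, bounds)
  n_removed <- attr(cleaned, "n_removed")
  imputed <- impute_series(cleaned, policy)
  dropped <- attr(imputed, "dropped")
  z <- standardize_series(imputed, ehr, refs)
  attr(z, "n_removed") <- n_removed
  attr(z, "dropped") <- dropped
  z
}
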