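# Window extraction and featurisation: class-balanced window samples
# carrying 13 per-channel statistics joined with 21 encoded static
# variables (112 features total).

#' Window extraction specification
#'
#' Non-survivor (minority-class) streams are oversampled with overlapping
#' windows advancing by `minority_step_points` grid points; survivor
#' streams yield consecutive non-overlapping windows. At 6% mortality
#' with 10-minute windows on a 1 Hz grid and a 50-point step this makes
#' the two sample classes approximately equal in number.
#'
#' @param window_minutes Window duration in minutes (> 0), default 10.
#' @param minority_step_points Step between successive minority-class
#'   window starts, in grid points (>= 1), default 50.
#' @param min_points_per_window Minimum observed points for a window to
#'   be kept; default `NULL` means a full window is required.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(window_minutes = 10, minority_step_points = 50,
                        min_points_per_window = NULL) {
  stopifnot(window_minutes > 0, minority_step_points >= 1)
  structure(list(window_minutes = window_minutes,
                 minority_step_points = as.integer(minority_step_points),
                 min_points_per_window = min_points_per_window),
            class = "window_spec")
}

#' Window start indices for one patient stream
#'
#' Windows are half-open `[start, start + w)` on the resampled grid.
#' Deceased patients: starts at grid indices 1, 1+s, 1+2s, ... while a
#' full window fits, giving `floor((L - w)/s) + 1` windows. Survivors:
#' consecutive disjoint windows, giving `floor(L / w)`. A stream shorter
#' than one window yields no windows (not an error).
#'
#' @param n_points Grid length L of the stream, in points.
#' @param outcome_deceased Logical; `TRUE` selects the overlapping
#'   minority-class scheme.
#' @param spec A [window_spec()].
#' @param sampling_interval_s Grid spacing in seconds (defines the window
#'   length in points, `w = round(window_minutes * 60 / interval)`).
#' @return Integer vector of 1-based start indices (possibly empty).
#' @export
#' @examples
#' window_starts(220, TRUE, window_spec(10, 50), sampling_interval_s = 5)
window_starts <- function(n_points, outcome_deceased, spec,
                          sampling_interval_s = 1) {
  w <- window_points(spec, sampling_interval_s)
  if (n_points < w) return(integer(0))
  if (outcome_deceased) {
    s <- spec$minority_step_points
    as.integer(seq.int(1L, n_points - w + 1L, by = s))
  } else {
    k <- n_points %/% w
    as.integer(seq.int(1L, by = w, length.out = k))
  }
}

#' @rdname window_starts
#' @return `window_points`: the window length in grid points.
#' @export
window_points <- function(spec, sampling_interval_s = 1) {
  as.integer(round(spec$window_minutes * 60 / sampling_interval_s))
}

#' Extract window samples from one patient's Z-score streams
#'
#' All channels must share the post-imputation common time grid. Windows
#' with fewer than `min_points_per_window` observed points are dropped.
#'
#' @param z Z-score data frame for a single patient
#'   (`patient_id, channel, time_s, zvalue`).
#' @param outcome_deceased Patient-level outcome (died within 30 days).
#' @param spec A [window_spec()].
#' @return List of windows, each a list with `start_s`, `end_s` and
#'   `zmat` (points x channels matrix).
#' @export
extract_windows <- function(z, outcome_deceased, spec = window_spec()) {
  stopifnot(length(unique(z$patient_id)) <= 1)
  if (nrow(z) == 0L) return(list())
  zw <- .z_wide(z)
  times <- zw$times
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  w <- window_points(spec, dt)
  starts <- window_starts(nrow(zw$mat), outcome_deceased, spec, dt)
  min_pts <- spec$min_points_per_window %||% w
  out <- lapply(starts, function(s) {
    rows <- s:(s + w - 1L)
    m <- zw$mat[rows, , drop = FALSE]
    if (sum(stats::complete.cases(m)) < min_pts) return(NULL)
    list(start_s = times[s], end_s = times[s] + w * dt, zmat = m)
  })
  out[!vapply(out, is.null, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long -> (times, points x channels matrix); channels in canonical order
.z_wide <- function(z) {
  chs <- intersect(vs_channels(), unique(z$channel))
  times <- sort(unique(z$time_s))
  mat <- matrix(NA_real_, nrow = length(times), ncol = length(chs),
                dimnames = list(NULL, chs))
  for (ch in chs) {
    d <- z[z$channel == ch, ]
    mat[match(d$time_s, times), ch] <- d$zvalue
  }
  list(times = times, mat = mat)
}

#' The thirteen per-window statistics
#'
#' Computed on one channel's Z-score vector within a window, in fixed
#' order: `mean`, `median`, `sd`, `min`, `max`, `range`, `iqr`,
#' `skewness`, `kurtosis` (excess), `shannon_entropy` (of counts over 16
#' equal-width bins spanning Z in `[-5, 5]`, natural log, values outside
#' clamped to the end bins), `sample_entropy` (SampEn with template
#' length 2 and tolerance 0.2 times the SD), `psd_power` (total
#' periodogram power of the
#' mean-removed series, which by Parseval equals the population
#' variance), `slope` (least-squares linear trend per second).
#'
#' Conventions for degenerate inputs: a constant vector has
#' `sd = range = slope = 0` and skewness, kurtosis, both entropies and
#' `psd_power` equal to 0.
#'
#' @param x Numeric vector of Z-scores (non-empty, no missing values).
#' @param dt Grid spacing in seconds (used by the slope).
#' @return Named numeric vector of length 13, all entries finite.
#' @export
window_statistics <- function(x, dt = 1) {
  stopifnot(length(x) >= 1, !anyNA(x))
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) sd(x) else 0
  xs <- sort.int(x, method = "quick")
  mn <- xs[1]; mx <- xs[n]
  # type-7 quantiles and median read off the sorted vector
  q7 <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
  }
  q <- c(q7(0.25), q7(0.75))
  med <- q7(0.5)
  xc <- x - m
  m2 <- mean(xc^2)
  if (m2 > 0) {
    skew <- mean(xc^3) / m2^1.5
    kurt <- mean(xc^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0  # constant-vector convention
  }
  # Shannon entropy over 16 equal-width bins on [-5, 5]
  bins <- pmin(pmax(floor((x + 5) / 10 * 16), 0), 15)
  p <- tabulate(bins + 1L, nbins = 16L)
  p <- p[p > 0] / n
  shannon <- -sum(p * log(p))
  sampen <- sample_entropy_cpp(x, 2L, 0.2 * s)
  # total periodogram power (Parseval: equals population variance)
  psd <- if (n > 1) sum(Mod(fft(xc))^2) / n^2 else 0
  slope <- if (n > 1 && m2 > 0) {
    t <- (seq_len(n) - 1) * dt
    sum((t - mean(t)) * xc) / sum((t - mean(t))^2)
  } else 0
  c(mean = m, median = med, sd = s, min = mn, max = mx,
    range = mx - mn, iqr = q[2] - q[1], skewness = skew, kurtosis = kurt,
    shannon_entropy = shannon, sample_entropy = sampen, psd_power = psd,
    slope = slope)
}

# matrix form of window_statistics(): one call per window computes all
# channels' 13 statistics column-wise (same formulas; equality with the
# per-vector path is covered by a property test). Returns the derived
# block as a named vector, channel-major.
.window_stats_mat <- function(zm, dt) {
  n <- nrow(zm); p <- ncol(zm)
  if (n < 2) {
    return(unlist(lapply(seq_len(p), function(j) window_statistics(zm[, j], dt)),
                  use.names = FALSE) |>
             setNames(as.vector(t(outer(colnames(zm), .stat_names, paste,
                                        sep = "_")))))
  }
  m <- colMeans(zm)
  xc <- zm - rep(m, each = n)
  m2 <- colMeans(xc^2)
  sdv <- sqrt(m2 * n / (n - 1))
  sorted <- apply(zm, 2, sort.int, method = "quick")
  q7 <- function(prob) {
    h <- (n - 1) * prob
    lo <- floor(h)
    sorted[lo + 1, ] + (h - lo) * (sorted[min(lo + 2, n), ] - sorted[lo + 1, ])
  }
  med <- q7(0.5); q25 <- q7(0.25); q75 <- q7(0.75)
  mn <- sorted[1, ]; mx <- sorted[n, ]
  pos <- m2 > 0
  skew <- ifelse(pos, colMeans(xc^3) / m2^1.5, 0)
  kurt <- ifelse(pos, colMeans(xc^4) / m2^2 - 3, 0)
  bins <- pmin(pmax(floor((zm + 5) / 10 * 16), 0), 15)
  cnt <- matrix(tabulate(as.vector(bins) + 1L + 16L * rep(0:(p - 1), each = n),
                         nbins = 16L * p), nrow = 16L)
  pm <- cnt / n
  sh <- -colSums(ifelse(pm > 0, pm * log(pm), 0))
  sampen <- vapply(seq_len(p), function(j) {
    sample_entropy_cpp(zm[, j], 2L, 0.2 * sdv[j])
  }, numeric(1))
  psd <- colSums(Mod(stats::mvfft(xc))^2) / n^2
  t0 <- (seq_len(n) - 1) * dt
  tc <- t0 - mean(t0)
  slope <- ifelse(pos, colSums(xc * tc) / sum(tc^2), 0)
  stats <- rbind(mean = m, median = med, sd = sdv, min = mn, max = mx,
                 range = mx - mn, iqr = q75 - q25, skewness = skew,
                 kurtosis = kurt, shannon_entropy = sh,
                 sample_entropy = sampen, psd_power = psd, slope = slope)
  setNames(as.vector(stats),
           as.vector(outer(.stat_names, colnames(zm),
                           function(s, ch) paste(ch, s, sep = "_"))))
}

.stat_names <- c("mean", "median", "sd", "min", "max", "range", "iqr",
                 "skewness", "kurtosis", "shannon_entropy",
                 "sample_entropy", "psd_power", "slope")

#' Names of the 112 model features, in contract order
#'
#' 21 static variables followed by 7 channels x 13 window statistics.
#' This ordering is the feature contract every trained model enforces.
#'
#' @return Character vector of length 112.
#' @export
feature_names <- function() {
  c(static_feature_names(),
    as.vector(t(outer(vs_channels(), .stat_names, paste, sep = "_"))))
}

#' @rdname feature_names
#' @return `static_feature_names`: the 21 static variable names.
#' @export
static_feature_names <- function() {
  c("age_months",
    paste0("age_group_", age_groups()),
    "weight_kg", "gender_male",
    paste0("diag_", .diagnosis_groups),
    "invasive_ventilation", "vaso_type_code", "inhaled_no",
    "pim3_risk", "critical_incident_code", "transport_minutes")
}

#' Encode one patient's static EHR fields
#'
#' Stable codebook: age group and diagnosis group are one-hot indicators;
#' `gender_male`, `invasive_ventilation`, `inhaled_no` are 0/1;
#' `vaso_type_code` is 0 none / 1 single / 2 multiple agents;
#' `critical_incident_code` is 0 none / 1 patient-related /
#' 2 equipment-related; `age_months`, `weight_kg`, `pim3_risk` and
#' `transport_minutes` pass through numerically.
#'
#' @param patient One-row data frame (a row of the EHR table).
#' @return Named numeric vector of length 21 in contract order.
#' @export
encode_static <- function(patient) {
  stopifnot(nrow(patient) == 1)
  vaso_levels <- c(none = 0, single = 1, multiple = 2)
  ci_levels <- c(none = 0, patient = 1, equipment = 2)
  if (!patient$vaso_type %in% names(vaso_levels)) {
    stop("unknown vaso_type: ", patient$vaso_type)
  }
  if (!patient$critical_incident %in% names(ci_levels)) {
    stop("unknown critical_incident: ", patient$critical_incident)
  }
  v <- c(patient$age_months,
         as.numeric(age_groups() == patient$age_group),
         patient$weight_kg,
         as.numeric(patient$gender == "male"),
         as.numeric(.diagnosis_groups == patient$diagnosis_group),
         as.numeric(patient$invasive_ventilation),
         unname(vaso_levels[patient$vaso_type]),
         as.numeric(patient$inhaled_no),
         patient$pim3_risk,
         unname(ci_levels[patient$critical_incident]),
         patient$transport_minutes)
  setNames(v, static_feature_names())
}

#' Assemble one window sample
#'
#' Fixed-order concatenation static || derived. All 7 channels must be
#' present in the window; a window missing a channel is rejected (the
#' cohort-level driver drops it with a logged reason).
#'
#' @param patient One-row EHR data frame.
#' @param zmat Points x channels Z-score matrix for the window.
#' @param dt Grid spacing in seconds.
#' @return Named numeric vector of length 112 in [feature_names()] order.
#' @export
assemble_sample <- function(patient, zmat, dt = 1) {
  missing_ch <- setdiff(vs_channels(), colnames(zmat))
  if (length(missing_ch)) {
    stop("window missing channel(s): ", paste(missing_ch, collapse = ", "))
  }
  c(encode_static(patient),
    .window_stats_mat(zmat[, vs_channels(), drop = FALSE], dt))
}

#' Featurise a preprocessed cohort into window samples
#'
#' Runs window extraction and feature assembly for every patient,
#' labelling each sample with the patient's 30-day outcome. Windows
#' missing a channel (e.g. the channel was unimputable for that patient)
#' are dropped and counted in the `dropped_windows` attribute; the
#' minority/majority sample ratio is recorded in attribute
#' `balance_ratio`.
#'
#' @param z Z-score data frame for the cohort ([preprocess_cohort()]).
#' @param ehr Static table including `died_30d`.
#' @param spec A [window_spec()].
#' @return Data frame: `patient_id`, `window_start_s`, `window_end_s`,
#'   `label` (0/1), then the 112 feature columns in contract order.
#' @export
featurize_cohort <- function(z, ehr, spec = window_spec()) {
  stopifnot(all(c("patient_id", "died_30d") %in% names(ehr)))
  o <- order(z$patient_id, method = "radix")
  if (is.unsorted(o)) z <- z[o, ]
  runs <- rle(z$patient_id)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dropped <- 0L
  feats <- list()
  pid_v <- character(0); start_v <- numeric(0); end_v <- numeric(0)
  lab_v <- integer(0)
  for (g in seq_along(starts)) {
    pid <- runs$values[g]
    zp <- z[starts[g]:ends[g], ]
    prow <- ehr[ehr$patient_id == pid, , drop = FALSE]
    if (nrow(prow) != 1L) next
    wins <- extract_windows(zp, prow$died_30d, spec)
    if (!length(wins)) next
    dt <- {
      ts <- sort(unique(zp$time_s))
      if (length(ts) > 1) stats::median(diff(ts)) else 1
    }
    static <- encode_static(prow)
    for (wn in wins) {
      if (length(setdiff(vs_channels(), colnames(wn$zmat))) > 0) {
        dropped <- dropped + 1L
        next
      }
      derived <- .window_stats_mat(wn$zmat[, vs_channels(), drop = FALSE], dt)
      feats[[length(feats) + 1L]] <- c(unname(static), unname(derived))
      pid_v <- c(pid_v, pid)
      start_v <- c(start_v, wn$start_s)
      end_v <- c(end_v, wn$end_s)
      lab_v <- c(lab_v, as.integer(prow$died_30d))
    }
  }
  if (!length(feats)) {
    fm <- matrix(numeric(0), nrow = 0, ncol = length(feature_names()))
  } else {
    fm <- do.call(rbind, feats)
  }
  colnames(fm) <- feature_names()
  out <- cbind(
    data.frame(patient_id = pid_v, window_start_s = start_v,
               window_end_s = end_v, label = lab_v,
               stringsAsFactors = FALSE),
    as.data.frame(fm))
  n_min <- sum(out$label == 1); n_maj <- sum(out$label == 0)
  attr(out, "balance_ratio") <- if (n_maj > 0) n_min / n_maj else NA_real_
  attr(out, "dropped_windows") <- dropped
  out
}

#' Extract the feature matrix from a samples table
#'
#' @param samples Data frame from [featurize_cohort()].
#' @return Numeric matrix with the 112 feature columns.
#' @export
feature_matrix <- function(samples) {
  as.matrix(samples[, feature_names(), drop = FALSE])
}
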