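# Synthetic transport-episode generator: static EHR table plus per-channel
# vital-sign streams with outcome-conditioned deterioration. Emulates the
# statistical structure the downstream pipeline assumes (≈6% 30-day
# mortality, median ≈67 min of monitoring, channel-specific missingness,
# moderate PIM3-alone discrimination) so every stage is testable without
# restricted hospital data.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 30-day
#' mortality ≈ 6% (deceased count is deterministic, `round(n * rate)`),
#' log-normal monitoring durations with median 67 min (IQR ≈ 41–104),
#' 1 Hz sampling, per-channel missingness at archival rates, a 14.9%
#' critical-incident rate, and a Z-space deterioration drift of −1.5 for
#' SpO2 and −1.0 for SBP in non-survivors.
#'
#' @param n_patients Number of transport episodes to generate.
#' @param mortality_rate 30-day mortality fraction in `[0,1]`; the deceased
#'   count is exactly `round(n_patients * mortality_rate)`.
#' @param sampling_interval_s Monitor sampling interval in seconds (> 0).
#'   The default of 1 s is the interval at which a 10-minute window spans
#'   600 points, making the 50-point minority step produce approximately
#'   class-balanced window samples at 6% mortality.
#' @param duration_meanlog,duration_sdlog Log-normal parameters (minutes)
#'   of monitoring duration; defaults target median 67 min. Durations are
#'   floored at 10 min (episodes with less archived monitoring are
#'   excluded from study cohorts).
#' @param missing_rates Named vector, per-channel probability that a point
#'   is missing after artifact injection (see [default_missing_rates()]).
#' @param outlier_rate Per-point probability of replacement by a value
#'   outside the channel's plausibility range.
#' @param deterioration_effect Named numeric, episode-averaged Z-score
#'   shift of non-survivors relative to survivors, per channel (channels
#'   not named get no outcome-conditioned drift). The shift is delivered
#'   as a linear drift that starts at 0 and reaches twice the configured
#'   value by handover, so the trajectory is progressively deteriorating
#'   while its mean displacement equals the configured effect.
#' @param incident_rate Probability of a critical incident during transport.
#' @param mortality_48h_frac Fraction of 30-day deaths occurring within
#'   48 h of PICU admission.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients,
                          mortality_rate = 0.06,
                          sampling_interval_s = 1,
                          duration_meanlog = log(67),
                          duration_sdlog = 0.65,
                          missing_rates = default_missing_rates(),
                          outlier_rate = 0.002,
                          deterioration_effect = c(SPO2 = -1.5, SBP = -1.0),
                          incident_rate = 0.149,
                          mortality_48h_frac = 20 / 74,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              mortality_rate = mortality_rate,
              sampling_interval_s = sampling_interval_s,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              missing_rates = missing_rates,
              outlier_rate = outlier_rate,
              deterioration_effect = deterioration_effect,
              incident_rate = incident_rate,
              mortality_48h_frac = mortality_48h_frac,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop("not a cohort_config")
  with(cfg, {
    if (is.na(n_patients) || n_patients < 1) stop("n_patients must be >= 1")
    if (mortality_rate < 0 || mortality_rate > 1) {
      stop("mortality_rate must lie in [0, 1]")
    }
    if (sampling_interval_s <= 0) stop("sampling_interval_s must be > 0")
    if (any(missing_rates < 0) || any(missing_rates > 1)) {
      stop("all channel missing rates must lie in [0, 1]")
    }
    if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate in [0, 1]")
    if (incident_rate < 0 || incident_rate > 1) stop("incident_rate in [0, 1]")
    bad <- setdiff(names(deterioration_effect), vs_channels())
    if (length(bad)) stop("unknown channel(s) in deterioration_effect: ",
                          paste(bad, collapse = ", "))
  })
  cfg
}

# Table-2-style structure of the study cohort (study column proportions).
.age_group_probs <- c(newborn = 0.379, infant = 0.205, preschool = 0.176,
                      school = 0.145, adolescent = 0.095)
.diagnosis_groups <- c("respiratory", "cardiovascular", "neurological",
                       "infection", "gastrointestinal", "trauma", "other")
.diagnosis_probs <- c(0.348, 0.257, 0.184, 0.064, 0.044, 0.013, 0.090)

# crude paediatric weight-for-age with log-normal individual variation
.weight_for_age <- function(age_months) {
  yrs <- age_months / 12
  ifelse(age_months <= 12, 3.5 + 0.5 * age_months,
         ifelse(yrs <= 10, 2 * (yrs + 4), pmin(70, 30 + 4 * (yrs - 10))))
}

#' Generate a synthetic transport cohort
#'
#' Draws `n_patients` transport episodes. Static fields follow the study
#' cohort's age-group, diagnosis and intervention structure; PIM3 risk is
#' drawn from outcome-conditioned Beta distributions (survivors
#' Beta(2, 50), deceased Beta(1.5, 18)) so that PIM3 alone has moderate
#' patient-level discrimination (AUROC ≈ 0.72 on large cohorts). Each
#' channel's trajectory is a mean-reverting (discretised
#' Ornstein–Uhlenbeck) process in Z-score space around a patient-specific
#' offset; non-survivors additionally drift linearly from 0 to
#' `deterioration_effect[channel]` Z over the episode. Z trajectories are
#' mapped to channel units through the age-group reference and clamped to
#' the plausibility range, so all raw values are in-range before artifact
#' injection.
#'
#' @param config A [cohort_config()].
#' @param refs Reference ranges (see [default_reference_ranges()]).
#' @param inject If `TRUE` (default) missingness and outliers are injected
#'   via [inject_artifacts()]; set `FALSE` for clean streams.
#' @return List with elements `ehr` (one row per patient) and `vitals`
#'   (long format: `patient_id`, `channel`, `time_s`, `value`; `NA` marks
#'   missing). Exactly `round(n_patients * mortality_rate)` patients have
#'   `died_30d = TRUE`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(20, seed = 42))
#' table(cohort$ehr$died_30d)
generate_cohort <- function(config, refs = default_reference_ranges(),
                            inject = TRUE) {
  validate_cohort_config(config)
  validate_reference_ranges(refs)
  set.seed(config$seed)
  n <- config$n_patients

  ids <- sprintf("P%04d", seq_len(n))
  age_group <- sample(names(.age_group_probs), n, replace = TRUE,
                      prob = .age_group_probs)
  lo <- c(newborn = 0, infant = 1, preschool = 12, school = 48,
          adolescent = 132)[age_group]
  hi <- c(newborn = 1, infant = 12, preschool = 48, school = 132,
          adolescent = 216)[age_group]
  age_months <- lo + runif(n) * (hi - lo)
  weight_kg <- .weight_for_age(age_months) * rlnorm(n, 0, 0.1)

  n_dec <- round(n * config$mortality_rate)
  died_30d <- rep(FALSE, n)
  died_30d[sample.int(n, n_dec)] <- TRUE
  died_48h <- rep(FALSE, n)
  if (n_dec > 0) {
    idx_dec <- which(died_30d)
    n48 <- round(n_dec * config$mortality_48h_frac)
    if (n48 > 0) died_48h[sample(idx_dec, n48)] <- TRUE
  }

  pim3 <- numeric(n)
  pim3[!died_30d] <- rbeta(sum(!died_30d), 2, 50)
  pim3[died_30d] <- rbeta(sum(died_30d), 1.5, 18)

  incident <- ifelse(runif(n) < config$incident_rate,
                     sample(c("patient", "equipment"), n, replace = TRUE),
                     "none")

  ehr <- data.frame(
    patient_id = ids,
    age_months = age_months,
    age_group = age_group,
    weight_kg = weight_kg,
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.462, 0.538)),
    diagnosis_group = sample(.diagnosis_groups, n, TRUE, .diagnosis_probs),
    invasive_ventilation = runif(n) < 0.724,
    vaso_type = sample(c("none", "single", "multiple"), n, TRUE,
                       prob = c(0.686, 0.250, 0.064)),
    inhaled_no = runif(n) < 0.025,
    pim3_risk = pim3,
    critical_incident = incident,
    transport_minutes = rlnorm(n, log(206), 0.334),
    died_30d = died_30d,
    died_48h = died_48h,
    stringsAsFactors = FALSE
  )

  dur_min <- pmax(10, rlnorm(n, config$duration_meanlog, config$duration_sdlog))
  dt <- config$sampling_interval_s
  len <- floor(dur_min * 60 / dt) + 1L

  # per-patient value blocks are accumulated as plain vectors and bound
  # once; a 600-patient cohort at 1 Hz is ~20M rows
  chs <- vs_channels()
  val_l <- vector("list", n)
  for (i in seq_len(n)) {
    z <- .simulate_z_paths(len[i], dt, died_30d[i], config$deterioration_effect)
    val_l[[i]] <- .z_to_values(z, age_group[i], refs)
  }
  nch <- length(chs)
  vitals <- data.frame(
    patient_id = rep(ids, times = nch * len),
    channel = unlist(lapply(len, function(L) rep(chs, each = L)),
                     use.names = FALSE),
    time_s = unlist(lapply(len, function(L) rep.int((seq_len(L) - 1L) * dt, nch)),
                    use.names = FALSE),
    value = unlist(val_l, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (inject) vitals <- inject_artifacts(vitals, config)
  list(ehr = ehr, vitals = vitals)
}

# Discretised OU in Z space: exact AR(1) with mean-reversion timescale
# 300 s and stationary SD 0.6 Z, plus a patient-level offset (SD 0.4 Z)
# and, for non-survivors, a linear drift to the terminal deterioration.
.simulate_z_paths <- function(len, dt, deceased, effect) {
  theta <- 1 / 300
  stat_sd <- 0.6
  a <- exp(-theta * dt)
  innov_sd <- stat_sd * sqrt(1 - a^2)
  chs <- vs_channels()
  z <- matrix(0, nrow = len, ncol = length(chs), dimnames = list(NULL, chs))
  frac <- if (len > 1) (seq_len(len) - 1) / (len - 1) else 0
  for (ch in chs) {
    offset <- rnorm(1, 0, 0.4)
    m <- rep(offset, len)
    if (deceased && ch %in% names(effect)) {
      # linear drift whose episode average equals the configured shift
      # (reaches 2 x effect by handover)
      m <- m + 2 * effect[[ch]] * frac
    }
    e <- rnorm(len, 0, innov_sd)
    z0 <- rnorm(1, m[1], stat_sd)
    # AR(1): z_t = a z_{t-1} + (1-a) m_t + e_t, run through the fast
    # recursive filter; initial state folded into the first input term
    x <- (1 - a) * m + e
    x[1] <- x[1] + a * z0
    z[, ch] <- stats::filter(x, a, method = "recursive")
  }
  z
}

# map Z trajectories to clamped channel units; returns the L x 7 value
# matrix flattened column-major (channel blocks in canonical order)
.z_to_values <- function(z, age_group, refs) {
  bounds <- default_plausibility_bounds()
  chs <- colnames(z)
  v <- z
  for (k in seq_along(chs)) {
    ch <- chs[k]
    r <- ref_lookup(refs, age_group, ch)
    b <- bounds[bounds$channel == ch, ]
    v[, k] <- pmin(b$hi, pmax(b$lo, r$mean + z[, ch] * r$sd))
  }
  as.vector(v)
}

#' Inject missingness and out-of-range artifacts into vital-sign streams
#'
#' Each point is independently replaced by `NA` with its channel's missing
#' rate, and (independently) replaced by a value outside the channel's
#' plausibility range with probability `outlier_rate`. Length and
#' timestamps are unchanged.
#'
#' @param vitals Long-format vital-sign data frame
#'   (`patient_id, channel, time_s, value`).
#' @param config A [cohort_config()] supplying `missing_rates` and
#'   `outlier_rate`. Randomness continues the caller's RNG stream, so call
#'   inside a seeded context for reproducibility ([generate_cohort()] does
#'   this automatically).
#' @return The data frame with artifacts applied.
#' @export
inject_artifacts <- function(vitals, config) {
  validate_cohort_config(config)
  stopifnot(all(c("patient_id", "channel", "time_s", "value") %in% names(vitals)))
  bad <- setdiff(unique(vitals$channel), vs_channels())
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  n <- nrow(vitals)
  if (n == 0L) return(vitals)

  bounds <- default_plausibility_bounds()
  # outliers first, then missingness, so a point can end up missing even
  # if it was selected as an outlier (missingness dominates)
  u_out <- runif(n)
  out_sel <- u_out < config$outlier_rate
  if (any(out_sel)) {
    idx <- which(out_sel)
    ch <- vitals$channel[idx]
    b <- bounds[match(ch, bounds$channel), ]
    span <- b$hi - b$lo
    above <- runif(length(idx)) < 0.5
    vitals$value[idx] <- ifelse(above,
                                b$hi + runif(length(idx), 0.02, 0.5) * span,
                                b$lo - runif(length(idx), 0.02, 0.5) * span)
  }
  rate <- unname(config$missing_rates)[match(vitals$channel,
                                             names(config$missing_rates))]
  rate[is.na(rate)] <- 0
  vitals$value[runif(n) < rate] <- NA_real_
  vitals
}

#' Write a cohort to CSV files
#'
#' Writes `ehr.csv` (one row per patient, fixed header) and `vitals.csv`
#' (long format `patient_id,channel,time_s,value`, empty field for
#' missing) into `dir`.
#'
#' @param cohort List with `ehr` and `vitals` as from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$ehr, file.path(dir, "ehr.csv"), row.names = FALSE)
  write.csv(cohort$vitals, file.path(dir, "vitals.csv"), row.names = FALSE,
            na = "")
  invisible(dir)
}

#' Read a cohort from CSV files written by [write_cohort_csv()]
#'
#' @param dir Directory containing `ehr.csv` and `vitals.csv`.
#' @return List with `ehr` and `vitals` data frames.
#' @export
read_cohort_csv <- function(dir) {
  ehr <- read.csv(file.path(dir, "ehr.csv"), stringsAsFactors = FALSE)
  vitals <- read.csv(file.path(dir, "vitals.csv"), stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  list(ehr = ehr, vitals = vitals)
}
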