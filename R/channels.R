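# Channel and age-group vocabulary shared across the pipeline.

#' Monitored vital-sign channels
#'
#' The seven continuously monitored channels: heart rate (bpm), systolic /
#' diastolic / mean blood pressure (mmHg), respiratory rate (breaths/min),
#' peripheral oxygen saturation (%), body temperature (degrees C).
#'
#' @return Character vector of channel codes, in the canonical order used
#'   throughout feature vectors.
#' @export
vs_channels <- function() {
  c("HR", "SBP", "DBP", "MBP", "RR", "SPO2", "TEMP")
}

#' Paediatric age groups
#'
#' Age bands used for Z-score standardisation and cohort structure:
#' newborn (<= 1 month), infant (1–12 months), pre-school child
#' (1–4 years), school child (4–11 years), adolescent (11–18 years).
#'
#' @return Character vector of age-group labels in ascending age order.
#' @export
age_groups <- function() {
  c("newborn", "infant", "preschool", "school", "adolescent")
}

#' Assign an age group from age in months
#'
#' @param age_months Numeric vector of ages in months (0–216).
#' @return Character vector of age-group labels.
#' @export
#' @examples
#' age_group_of(c(0.5, 6, 24, 90, 150))
age_group_of <- function(age_months) {
  stopifnot(is.numeric(age_months), all(age_months >= 0))
  cut(age_months,
      breaks = c(-Inf, 1, 12, 48, 132, Inf),
      labels = age_groups(),
      right = TRUE) |> as.character()
}

#' Default clinical plausibility bounds
#'
#' Closed intervals, in channel units, outside which a monitor reading is
#' considered clinically implausible (artifact) and removed during
#' cleaning: HR `[0,300]` bpm, SBP `[0,270]`, DBP `[0,250]`, MBP `[0,250]`
#' mmHg, RR `[0,180]` breaths/min, SpO2 `[0,100]` percent, temperature
#' `[20,45]` C.
#'
#' @return Data frame with columns `channel`, `lo`, `hi`.
#' @export
default_plausibility_bounds <- function() {
  data.frame(
    channel = vs_channels(),
    lo = c(0, 0, 0, 0, 0, 0, 20),
    hi = c(300, 270, 250, 250, 180, 100, 45),
    stringsAsFactors = FALSE
  )
}

#' Default per-channel missing-data rates
#'
#' Empirical missingness proportions observed in transport monitoring
#' archives, used as generator defaults for artifact injection.
#'
#' @return Named numeric vector (fractions, not percent) over channels.
#' @export
default_missing_rates <- function() {
  c(HR = 0.0285, SBP = 0.0925, DBP = 0.0930, MBP = 0.0876,
    RR = 0.0311, SPO2 = 0.0287, TEMP = 0.125)
}

#' Age-group reference ranges for Z-scoring
#'
#' Reference mean and SD per (age group, channel), in channel units.
#' These are synthetic placeholder values chosen to be paediatric-plausible
#' (e.g. newborn HR centred at 140 bpm, adolescent at 75 bpm); they ship
#' as an editable YAML config so a deployment can substitute published
#' centile-derived references without code changes. See
#' `system.file("extdata", "reference_ranges.yaml", package = "vitalrisk")`.
#'
#' @return Data frame with columns `age_group`, `channel`, `ref_mean`,
#'   `ref_sd` (one row per combination, SD strictly positive).
#' @export
default_reference_ranges <- function() {
  grp <- age_groups()
  tab <- list(
    HR   = list(mean = c(140, 120, 110, 95, 75),  sd = c(20, 20, 15, 15, 12)),
    SBP  = list(mean = c(70, 85, 95, 100, 115),   sd = c(10, 12, 12, 12, 12)),
    DBP  = list(mean = c(40, 50, 55, 60, 65),     sd = c(8, 9, 9, 9, 9)),
    MBP  = list(mean = c(50, 62, 68, 73, 80),     sd = c(8, 9, 9, 9, 9)),
    RR   = list(mean = c(45, 30, 24, 20, 15),     sd = c(8, 6, 5, 4, 3)),
    SPO2 = list(mean = c(97.5, 98, 98, 98, 98),   sd = c(1.5, 1.5, 1.5, 1.5, 1.5)),
    TEMP = list(mean = c(37, 37, 36.8, 36.8, 36.8), sd = c(0.5, 0.5, 0.5, 0.5, 0.5))
  )
  do.call(rbind, lapply(names(tab), function(ch) {
    data.frame(age_group = grp, channel = ch,
               ref_mean = tab[[ch]]$mean, ref_sd = tab[[ch]]$sd,
               stringsAsFactors = FALSE)
  }))
}

#' Read reference ranges from a YAML config
#'
#' Expected layout: top-level keys are age groups, each mapping channel to
#' `{mean: ..., sd: ...}`.
#'
#' @param path Path to a YAML file.
#' @return Data frame in the format of [default_reference_ranges()].
#' @export
read_reference_ranges <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(y), function(g) {
    chs <- y[[g]]
    do.call(rbind, lapply(names(chs), function(ch) {
      data.frame(age_group = g, channel = ch,
                 ref_mean = as.numeric(chs[[ch]]$mean),
                 ref_sd = as.numeric(chs[[ch]]$sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  validate_reference_ranges(out)
  out
}

#' Write reference ranges to a YAML config
#'
#' @param refs Data frame as returned by [default_reference_ranges()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_ranges <- function(refs, path) {
  validate_reference_ranges(refs)
  y <- lapply(split(refs, refs$age_group), function(d) {
    setNames(lapply(seq_len(nrow(d)), function(i) {
      list(mean = d$ref_mean[i], sd = d$ref_sd[i])
    }), d$channel)
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

validate_reference_ranges <- function(refs) {
  stopifnot(is.data.frame(refs),
            all(c("age_group", "channel", "ref_mean", "ref_sd") %in% names(refs)))
  if (any(refs$ref_sd <= 0)) {
    stop("reference SD must be strictly positive for every (age group, channel)")
  }
  invisible(refs)
}

# look up one (age_group, channel) reference; errors if absent
ref_lookup <- function(refs, age_group, channel) {
  i <- which(refs$age_group == age_group & refs$channel == channel)
  if (length(i) != 1L) {
    stop(sprintf("no reference range for age group '%s', channel '%s'",
                 age_group, channel))
  }
  list(mean = refs$ref_mean[i], sd = refs$ref_sd[i])
}
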