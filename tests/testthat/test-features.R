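# Window extraction counts, the 13 statistics, static encoding and
# sample assembly.

test_that("window start indices follow the class-specific schemes", {
  spec <- window_spec(window_minutes = 10, minority_step_points = 50)
  # 5-second grid: a 10-minute window spans 120 points
  st_d <- window_starts(220, TRUE, spec, sampling_interval_s = 5)
  expect_identical(st_d, c(1L, 51L, 101L))
  st_s <- window_starts(240, FALSE, spec, sampling_interval_s = 5)
  expect_identical(st_s, c(1L, 121L))
  expect_identical(window_starts(100, TRUE, spec, 5), integer(0))
  expect_identical(window_starts(100, FALSE, spec, 5), integer(0))
})

test_that("constant windows hit the forced statistic values", {
  s <- window_statistics(rep(1.7, 120))
  expect_identical(unname(s[c("sd", "range", "iqr", "slope", "skewness",
                              "kurtosis", "shannon_entropy",
                              "sample_entropy", "psd_power")]),
                   rep(0, 9))
  expect_equal(unname(s["mean"]), 1.7)
  expect_equal(unname(s["median"]), 1.7)
  expect_true(all(is.finite(s)))
})

test_that("alternating 0/1 window matches direct formulas and the sampen oracle", {
  x <- rep(c(0, 1), 60)
  s <- window_statistics(x)
  expect_equal(unname(s["mean"]), 0.5)
  expect_equal(unname(s["sd"]), sd(x))
  expect_equal(unname(s["sample_entropy"]),
               sampen_bruteforce(x, 2, 0.2 * sd(x)), tolerance = 1e-12)
})

test_that("sample entropy agrees with brute-force template matching", {
  set.seed(5)
  for (i in 1:8) {
    x <- rnorm(60)
    expect_equal(unname(window_statistics(x)["sample_entropy"]),
                 sampen_bruteforce(x), tolerance = 1e-12)
  }
})

test_that("ramp slope and Parseval total power are exact", {
  n <- 120; dt <- 5
  x <- seq(0, 1, length.out = n)
  s <- window_statistics(x, dt = dt)
  # ramp 0..1 over (n-1)*dt seconds
  expect_equal(unname(s["slope"]), 1 / ((n - 1) * dt), tolerance = 1e-12)
  expect_equal(unname(s["psd_power"]), mean((x - mean(x))^2), tolerance = 1e-9)

  set.seed(3)
  for (i in 1:5) {
    y <- rnorm(100)
    expect_equal(unname(window_statistics(y)["psd_power"]),
                 mean((y - mean(y))^2), tolerance = 1e-9)
  }
})

test_that("matrix fast path equals the per-vector statistics", {
  set.seed(9)
  for (i in 1:5) {
    zm <- matrix(rnorm(7 * 80), ncol = 7, dimnames = list(NULL, vs_channels()))
    fast <- vitalrisk:::.window_stats_mat(zm, dt = 2)
    slow <- unlist(lapply(vs_channels(), function(ch) {
      setNames(window_statistics(zm[, ch], dt = 2),
               paste(ch, names(window_statistics(zm[, ch], dt = 2)), sep = "_"))
    }))
    expect_equal(fast, slow[names(fast)], tolerance = 1e-12)
  }
})

test_that("static codebook encodes 21 variables with stable values", {
  p <- data.frame(patient_id = "p", age_months = 0.5, age_group = "newborn",
                  weight_kg = 3.4, gender = "male",
                  diagnosis_group = "cardiovascular",
                  invasive_ventilation = TRUE, vaso_type = "none",
                  inhaled_no = FALSE, pim3_risk = 0.033,
                  critical_incident = "none", transport_minutes = 210,
                  stringsAsFactors = FALSE)
  v <- encode_static(p)
  expect_identical(length(v), 21L)
  expect_identical(names(v), static_feature_names())
  expect_equal(unname(v["pim3_risk"]), 0.033)
  expect_equal(unname(v["age_group_newborn"]), 1)
  expect_equal(unname(v["diag_cardiovascular"]), 1)
  expect_equal(sum(v[paste0("age_group_", age_groups())]), 1)

  p2 <- p; p2$vaso_type <- "single"
  expect_false(encode_static(p)["vaso_type_code"] ==
                 encode_static(p2)["vaso_type_code"])
  p3 <- p; p3$vaso_type <- "unknown-drug"
  expect_error(encode_static(p3), "vaso_type")
})

test_that("assembled vectors have the documented 112-feature layout", {
  p <- data.frame(patient_id = "p", age_months = 30, age_group = "preschool",
                  weight_kg = 13, gender = "female",
                  diagnosis_group = "respiratory",
                  invasive_ventilation = FALSE, vaso_type = "multiple",
                  inhaled_no = TRUE, pim3_risk = 0.1,
                  critical_incident = "equipment", transport_minutes = 100,
                  stringsAsFactors = FALSE)
  set.seed(1)
  zm <- matrix(rnorm(7 * 120), ncol = 7, dimnames = list(NULL, vs_channels()))
  fv <- assemble_sample(p, zm)
  expect_identical(length(fv), 112L)
  expect_identical(names(fv), feature_names())
  expect_error(assemble_sample(p, zm[, 1:6]), "missing channel")
})

test_that("featurized samples stay within patients and inherit the outcome", {
  co <- small_cohort()
  z <- preprocess_cohort(co$vitals, co$ehr)
  samp <- featurize_cohort(z, co$ehr)
  expect_gt(nrow(samp), 0)
  lab <- co$ehr$died_30d[match(samp$patient_id, co$ehr$patient_id)]
  expect_identical(samp$label, as.integer(lab))
  # windows lie inside each patient's monitored interval
  dur <- tapply(z$time_s, z$patient_id, max)
  expect_true(all(samp$window_end_s <= dur[samp$patient_id] + 1))
  expect_true(all(samp$window_start_s >= 0))
  expect_false(anyNA(feature_matrix(samp)))
})

test_that("identical windows featurize identically", {
  p <- data.frame(patient_id = "p", age_months = 30, age_group = "preschool",
                  weight_kg = 13, gender = "female",
                  diagnosis_group = "other", invasive_ventilation = FALSE,
                  vaso_type = "none", inhaled_no = FALSE, pim3_risk = 0.05,
                  critical_incident = "none", transport_minutes = 90,
                  stringsAsFactors = FALSE)
  set.seed(2)
  zm <- matrix(rnorm(7 * 90), ncol = 7, dimnames = list(NULL, vs_channels()))
  expect_identical(assemble_sample(p, zm), assemble_sample(p, zm))
})
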