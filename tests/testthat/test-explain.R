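# Shapley attribution axioms, risk traces and transition detection.

lin_fn <- function(beta, intercept = 0) {
  function(X) intercept + as.numeric(X %*% beta)
}

test_that("a single-feature model attributes everything to that feature", {
  f <- function(X) 2 * X[, 1]
  bg <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "a"))
  att <- shapley_attributions(f, c(a = 1.5), bg, mode = "exact")
  expect_equal(unname(att$phi["a"]), att$prediction - att$base,
               tolerance = 1e-12)
})

test_that("exact attributions reproduce the linear-model closed form", {
  set.seed(31)
  p <- 8
  beta <- rnorm(p)
  nms <- paste0("f", 1:p)
  bg <- matrix(rnorm(40 * p), ncol = p, dimnames = list(NULL, nms))
  x <- setNames(rnorm(p), nms)
  att <- shapley_attributions(lin_fn(beta, 0.3), x, bg, mode = "exact")
  closed <- unname(beta * (as.numeric(x) - colMeans(bg)))
  expect_equal(unname(att$phi), closed, tolerance = 1e-9)
  expect_equal(att$base + sum(att$phi), att$prediction, tolerance = 1e-9)
})

test_that("exact mode satisfies local accuracy on a nonlinear model", {
  set.seed(32)
  f <- function(X) plogis(X[, 1] * X[, 2] - 0.5 * X[, 3]^2 + X[, 4])
  nms <- paste0("f", 1:5)
  bg <- matrix(rnorm(25 * 5), ncol = 5, dimnames = list(NULL, nms))
  for (i in 1:5) {
    x <- setNames(rnorm(5), nms)
    att <- shapley_attributions(f, x, bg, mode = "exact")
    expect_lt(abs(att$base + sum(att$phi) - att$prediction), 1e-9)
  }
})

test_that("ignored features receive exactly zero (dummy axiom)", {
  set.seed(33)
  f <- function(X) X[, 1]^2 + 3 * X[, 2]  # f3 ignored
  nms <- c("f1", "f2", "f3")
  bg <- matrix(rnorm(20 * 3), ncol = 3, dimnames = list(NULL, nms))
  att <- shapley_attributions(f, setNames(c(1, 2, 5), nms), bg, mode = "exact")
  expect_equal(unname(att$phi["f3"]), 0, tolerance = 1e-12)
})

test_that("identical duplicated features share credit equally (symmetry)", {
  set.seed(34)
  f <- function(X) X[, 1] + X[, 2]
  bg0 <- rnorm(20)
  bg <- cbind(a = bg0, b = bg0)
  att <- shapley_attributions(f, c(a = 2, b = 2), bg, mode = "exact")
  expect_equal(unname(att$phi["a"]), unname(att$phi["b"]), tolerance = 1e-12)
})

test_that("sampled mode keeps local accuracy and converges toward exact", {
  set.seed(35)
  p <- 6
  f <- function(X) plogis(X[, 1] * X[, 2] + 0.5 * X[, 3] - X[, 4]^2 / 3)
  nms <- paste0("f", 1:p)
  bg <- matrix(rnorm(30 * p), ncol = p, dimnames = list(NULL, nms))
  x <- setNames(rnorm(p), nms)
  exact <- shapley_attributions(f, x, bg, mode = "exact")$phi

  err_at <- function(n_perms) {
    e <- vapply(1:6, function(s) {
      a <- shapley_attributions(f, x, bg, mode = "sampled",
                                n_perms = n_perms, seed = s)
      expect_lt(abs(a$base + sum(a$phi) - a$prediction), 1e-9)
      expect_true(all(a$se >= 0))
      mean(abs(a$phi - exact))
    }, numeric(1))
    mean(e)
  }
  e1 <- err_at(150)
  e2 <- err_at(600)
  expect_lt(e2, e1)  # quadrupling permutations must shrink the error

  expect_error(shapley_attributions(f, x, bg, mode = "sampled", n_perms = 10),
               "n_perms")
  expect_error(shapley_attributions(f, x, bg[0, ], mode = "exact"),
               "background set is empty")
  big <- matrix(0, 2, 20, dimnames = list(NULL, paste0("g", 1:20)))
  expect_error(shapley_attributions(f, setNames(rep(0, 20), colnames(big)),
                                    big, mode = "exact"), "exact mode")
})

# build a trace object directly so transition logic is tested in isolation
mk_trace <- function(phi_list, risks = seq_along(phi_list) / 10) {
  structure(list(
    patient_id = "p",
    windows = data.frame(start_s = 600 * (seq_along(phi_list) - 1),
                         end_s = 600 * seq_along(phi_list),
                         risk = risks),
    attributions = lapply(phi_list, function(phi) {
      structure(list(phi = phi, base = 0.1,
                     prediction = 0.1 + sum(phi), se = NULL,
                     mode = "sampled"),
                class = "vr_attribution")
    })), class = "vr_risk_trace")
}

test_that("transition events fire only on sign flips toward non-survival", {
  allneg <- mk_trace(list(c(a = -0.1, b = -0.2), c(a = -0.05, b = -0.3)))
  expect_identical(nrow(detect_transitions(allneg)), 0L)

  flip <- mk_trace(list(c(a = -0.10, b = -0.1),
                        c(a = -0.10, b = -0.1),
                        c(a = 0.20, b = -0.1)))
  ev <- detect_transitions(flip)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$window_index, 3L)
  expect_identical(ev$feature, "a")
  expect_equal(ev$before, -0.10)
  expect_equal(ev$after, 0.20)

  both <- mk_trace(list(c(b = -0.1, a = -0.2), c(b = 0.3, a = 0.1)))
  ev2 <- detect_transitions(both)
  expect_identical(ev2$feature, c("a", "b"))  # alphabetical within a window

  # dead-zone suppresses marginal chatter
  chatter <- mk_trace(list(c(a = -0.001), c(a = 0.001)))
  expect_identical(nrow(detect_transitions(chatter)), 1L)
  expect_identical(nrow(detect_transitions(chatter, dead_zone = 0.01)), 0L)

  expect_error(detect_transitions(mk_trace(list(c(a = 1)))), "at least 2")
})

test_that("risk traces featurise consecutive intervals end to end", {
  co <- small_cohort()
  z <- preprocess_cohort(co$vitals, co$ehr)
  samp <- featurize_cohort(z, co$ehr)
  m <- tune_and_train(samp, model_spec("random_forest",
                                       search = list(
                                         num_trees = list(type = "int", lo = 150, hi = 150),
                                         mtry_frac = list(type = "unif", lo = 0.3, hi = 0.3),
                                         min_node_size = list(type = "int", lo = 5, hi = 5)),
                                       n_search = 1, seed = 1))
  bg <- background_from_samples(samp, n = 40, seed = 2)

  pid <- co$ehr$patient_id[!co$ehr$died_30d][1]
  zp <- z[z$patient_id == pid, ]
  zp <- zp[zp$time_s < 30 * 60, ]  # 30 minutes -> 3 intervals
  if (max(zp$time_s) >= 1799) {
    tr <- risk_trace(m, zp, co$ehr[co$ehr$patient_id == pid, ], bg,
                     n_perms = 100, seed = 5)
    expect_identical(nrow(tr$windows), 3L)
    expect_true(all(diff(tr$windows$start_s) == 600))
    for (a in tr$attributions) {
      expect_lt(abs(a$base + sum(a$phi) - a$prediction), 1e-9)
    }
    # export round trip
    jp <- withr::local_tempfile(fileext = ".json")
    cp <- withr::local_tempfile(fileext = ".csv")
    export_trace(tr, jp, cp)
    back <- jsonlite::read_json(jp)
    expect_identical(length(back$windows), 3L)
    tidy <- read.csv(cp)
    expect_identical(nrow(tidy), 3L * 112L)
  }

  short <- zp[zp$time_s < 120, ]
  expect_warning(
    tr0 <- risk_trace(m, short, co$ehr[co$ehr$patient_id == pid, ], bg,
                      n_perms = 100),
    "no complete interval")
  expect_identical(nrow(tr0$windows), 0L)
})
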