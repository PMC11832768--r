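# Metric formulas against independent oracles, bootstrap behaviour,
# baseline comparison.

test_that("AUROC handles separation, ties and the printed example", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  y <- c(1, 0, 1, 0, 0); s <- c(0.9, 0.8, 0.7, 0.3, 0.1)
  expect_equal(roc_auc(y, s), auc_bruteforce(y, s), tolerance = 1e-15)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(21)
  for (i in 1:20) {
    y <- rbinom(40, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- rnorm(40)
    a <- roc_auc(y, s)
    expect_equal(roc_auc(y, exp(s)), a, tolerance = 1e-12)
    expect_equal(roc_auc(y, rank(s)), a, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  y <- rbinom(150, 1, 0.2); y[1:2] <- c(0, 1)
  s <- rnorm(150) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("confusion metrics match textbook formulas and the printed 2x2", {
  m <- classification_metrics(c(1, 0), c(0.9, 0.1), threshold = 0.5)
  expect_equal(unname(m["mcc"]), 1.0)

  # TP=5, FP=3, FN=2, TN=90 laid out explicitly, MCC cross-checked
  # against the Pearson correlation of the binary vectors
  y <- c(rep(1, 5), rep(0, 3), rep(1, 2), rep(0, 90))
  s <- c(rep(1, 5), rep(1, 3), rep(0, 2), rep(0, 90))
  m2 <- classification_metrics(y, s, threshold = 0.5)
  expect_identical(attr(m2, "confusion"), c(tp = 5L, fp = 3L, fn = 2L, tn = 90L))
  expect_equal(unname(m2["mcc"]), cor(s, y), tolerance = 1e-12)
  expect_equal(unname(m2["ppv"]), 5 / 8)
  expect_equal(unname(m2["npv"]), 90 / 92)
  expect_equal(unname(m2["recall"]), 5 / 7)
  expect_equal(unname(m2["f1"]), 10 / 15)

  # label-independent predictions give MCC near zero
  set.seed(23)
  y0 <- rep(c(0, 1), 250)
  s0 <- runif(500)
  expect_lt(abs(unname(classification_metrics(y0, s0, 0.5)["mcc"])), 0.12)

  # degenerate denominator reports 0 and flags
  md <- classification_metrics(c(0, 0, 1), c(0.1, 0.1, 0.2), threshold = 0.9)
  expect_equal(unname(md["ppv"]), 0)
  expect_true("ppv" %in% attr(md, "degenerate"))
})

test_that("MCC magnitude is symmetric under class and prediction flips", {
  set.seed(24)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
    s <- runif(60)
    a <- classification_metrics(y, s, 0.5)["mcc"]
    b <- classification_metrics(1 - y, 1 - s, 0.5)["mcc"]
    expect_equal(abs(unname(a)), abs(unname(b)), tolerance = 1e-12)
  }
})

test_that("average precision equals stepwise accumulation", {
  set.seed(25)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.3); y[1] <- 1
    s <- round(runif(50), 2)  # force ties
    expect_equal(average_precision(y, s), ap_bruteforce(y, s),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap intervals are deterministic and collapse when degenerate", {
  y <- rep(c(0, 1), 30)
  s <- ifelse(y == 1, 0.9, 0.1)  # every resample has AUROC 1
  ci <- bootstrap_ci(y, s, roc_auc, n_boot = 200, seed = 3)
  expect_equal(unname(ci["lo"]), 1)
  expect_equal(unname(ci["hi"]), 1)

  set.seed(26)
  y2 <- rbinom(80, 1, 0.3); y2[1:2] <- c(0, 1)
  s2 <- rnorm(80) + y2
  ci1 <- bootstrap_ci(y2, s2, roc_auc, n_boot = 300, seed = 9)
  ci2 <- bootstrap_ci(y2, s2, roc_auc, n_boot = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1["lo"], ci1["hi"])
  expect_error(bootstrap_ci(y2, s2, roc_auc, n_boot = 50), "n_boot")
})

test_that("metrics report records its operating point", {
  set.seed(27)
  y <- rbinom(120, 1, 0.25); y[1:2] <- c(0, 1)
  s <- plogis(rnorm(120) + 1.5 * y)
  rep <- metrics_report(y, s, n_boot = 150, seed = 2)
  expect_setequal(rep$metric,
                  c("auroc", "mcc", "ppv", "npv", "recall", "f1", "ap"))
  expect_true(all(rep$lo <= rep$hi))
  thr <- attr(rep, "threshold")
  expect_true(thr >= 0 && thr <= 1)
  expect_identical(attr(rep, "n"), 120L)
  expect_identical(attr(rep, "n_events"), as.integer(sum(y)))
  expect_equal(thr, youden_threshold(y, s))
})

test_that("baseline comparison is symmetric for identical scores and exports rows", {
  set.seed(28)
  ids <- sprintf("P%02d", 1:50)
  y <- rbinom(50, 1, 0.2); y[1:2] <- c(0, 1)
  r <- plogis(rnorm(50) + y)
  model <- data.frame(patient_id = ids, risk = r, stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = ids, died_30d = as.logical(y),
                       stringsAsFactors = FALSE)
  cmp <- compare_to_baseline(model, model, labels, n_boot = 120, seed = 1)
  expect_equal(cmp$model$estimate, cmp$baseline$estimate, tolerance = 1e-12)
  expect_identical(nrow(cmp$scatter), 50L)
  expect_identical(sort(names(cmp$scatter)),
                   sort(c("patient_id", "model_risk", "pim3_risk", "outcome")))

  other <- model; other$patient_id[1] <- "QQ"
  expect_error(compare_to_baseline(model, other, labels), "mismatch")
})
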