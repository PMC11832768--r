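# Independent oracles and small fixtures used across tests. These stay
# deliberately naive (loops, enumeration) so they cannot share a bug with
# the implementation they check.

# AUROC by brute-force enumeration of all positive-negative pairs,
# ties counted half
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# average precision by direct stepwise accumulation over distinct
# thresholds, computed independently of the package's vectorised form
ap_bruteforce <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# sample entropy by literal template matching (triple loop),
# same convention as the compiled kernel: templates i = 1..n-m,
# Chebyshev distance, self-matches excluded, -log(A/B), 0 if degenerate
sampen_bruteforce <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n <= m + 1 || r <= 0) return(0)
  A <- 0; B <- 0
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

# toy two-feature separable samples table with many patients, for fast
# modeling tests; feature block padded to the full 112-column contract
toy_samples <- function(n_patients = 60, windows_per_patient = 3,
                        separation = 3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_patients))
  lab <- rep(c(0L, 1L), length.out = n_patients)
  rows <- n_patients * windows_per_patient
  fm <- matrix(rnorm(rows * length(feature_names()), 0, 0.1),
               nrow = rows, dimnames = list(NULL, feature_names()))
  pid <- rep(ids, each = windows_per_patient)
  y <- rep(lab, each = windows_per_patient)
  fm[, "SPO2_mean"] <- fm[, "SPO2_mean"] - separation * y
  fm[, "SBP_mean"] <- fm[, "SBP_mean"] - separation * y
  cbind(data.frame(patient_id = pid, window_start_s = 0,
                   window_end_s = 600, label = y,
                   stringsAsFactors = FALSE),
        as.data.frame(fm))
}

# small default-condition cohort shared by the slower integration tests;
# built once per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(80, seed = 421))
    }
    cache
  }
})
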