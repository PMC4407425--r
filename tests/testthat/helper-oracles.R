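# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# moving top-20% baseline, direct per-sample computation
oracle_baseline_T <- function(x, valid, window = 60, min_n = 12, frac = 0.2) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- seq(max(1, i - window), i - 1)
    if (i == 1) next
    w <- x[idx][valid[idx]]
    if (length(w) < min_n) next
    k <- ceiling(frac * length(w))
    out[i] <- mean(sort(w, decreasing = TRUE)[seq_len(k)])
  }
  out
}

# desaturation-event detection by scanning every sample: group below-baseline
# episodes, then look for the first long-enough sub-threshold stretch inside
oracle_detect <- function(x, valid, baseline, threshold, min_dur = 3) {
  ok <- valid & !is.na(baseline)
  events <- list()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (ok[i] && x[i] < baseline[i]) {
      j <- i
      while (j < n && ok[j + 1] && x[j + 1] < baseline[j + 1]) j <- j + 1
      # first run of >= min_dur consecutive sub-threshold samples in [i, j]
      run_start <- NA
      len <- 0
      found <- NULL
      for (t in i:j) {
        if (x[t] <= baseline[t] - threshold) {
          if (len == 0) run_start <- t
          len <- len + 1
          if (len == min_dur) { found <- run_start; }
        } else {
          if (!is.null(found)) break
          len <- 0
        }
      }
      if (!is.null(found)) {
        e <- found
        while (e < j && x[e + 1] <= baseline[e + 1] - threshold) e <- e + 1
        events[[length(events) + 1]] <-
          data.frame(start_s = found - 1, end_s = e - 1,
                     duration_s = e - found + 1, nadir_pct = min(x[i:j]))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(events)) {
    return(data.frame(start_s = integer(0), end_s = integer(0),
                      duration_s = integer(0), nadir_pct = numeric(0)))
  }
  do.call(rbind, events)
}

# AUC as the exhaustive O(n^2) pairwise concordance count, half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# artifact mask per the documented elimination rules, written as a plain scan
oracle_artifact_mask <- function(x, max_delta = 4, min_spo2 = 50) {
  n <- length(x)
  ok <- rep(TRUE, n)
  low <- x < min_spo2
  for (i in seq_len(n)) {
    if (low[i]) { ok[i] <- FALSE; next }
    ref <- NA
    for (j in rev(seq_len(i - 1))) {
      if (!low[j]) { ref <- x[j]; break }
    }
    if (!is.na(ref) && abs(x[i] - ref) > max_delta) ok[i] <- FALSE
  }
  ok
}

# a random short trace with planted square dips, drift, and invalid samples
random_test_trace <- function(seed, min_len = 120, max_len = 600) {
  set.seed(seed)
  n <- sample(min_len:max_len, 1)
  x <- 96 + cumsum(rnorm(n, 0, 0.15))
  x <- pmin(pmax(x, 70), 100)
  for (k in seq_len(sample(0:4, 1))) {
    start <- sample(seq_len(n - 12), 1)
    dur <- sample(2:10, 1)
    x[start:(start + dur - 1)] <- x[start:(start + dur - 1)] - runif(1, 2, 8)
  }
  x <- pmin(pmax(x, 60), 100)
  valid <- runif(n) > 0.05
  spo2_trace(x, valid = valid)
}
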