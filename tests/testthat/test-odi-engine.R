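test_that("the all-night baseline is the mean over valid samples", {
  tr <- spo2_trace(c(90, 100, 90, 100))
  expect_equal(baseline_all_night(tr), rep(95, 4))
  tr2 <- spo2_trace(c(96, 96, 40, 96), valid = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(baseline_all_night(tr2), rep(96, 4))
  tr2$valid[] <- FALSE
  expect_error(baseline_all_night(tr2), "no valid samples")
})

test_that("the moving baseline takes the top 20% of the preceding minute", {
  tr <- spo2_trace(rep(95, 120))
  b <- baseline_top20_preceding(tr)
  expect_true(all(is.na(b[1:12])))   # fewer than 12 preceding samples
  expect_equal(b[61], 95)
  # 48 samples at 90 and 12 at 95: the top ceil(0.2*60) = 12 values are the 95s
  x <- c(rep(90, 48), rep(95, 12), 92)
  b2 <- baseline_top20_preceding(spo2_trace(x))
  expect_equal(b2[61], 95)
})

test_that("the moving baseline matches its brute-force oracle", {
  for (s in 1:15) {
    tr <- random_test_trace(s + 100)
    expect_equal(baseline_top20_preceding(tr),
                 oracle_baseline_T(tr$spo2_pct, tr$valid))
  }
})

test_that("event detection honours threshold, duration, and run maximality", {
  # all-night baseline just under 95; 5-sample dip to 90, 4-point threshold
  x <- c(rep(95, 100), rep(90, 5), rep(95, 103))
  tr <- spo2_trace(x)
  ev <- detect_events(tr, odi_params(4, "A"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 5)
  expect_equal(ev$nadir_pct, 90)
  expect_equal(ev$start_s, 100)

  # two qualifying samples are too short
  x2 <- c(rep(95, 100), rep(88, 2), rep(95, 102))
  expect_equal(nrow(detect_events(spo2_trace(x2), odi_params(4, "A"))), 0)

  # a 3-point drop does not reach a 4-point threshold
  x3 <- c(rep(95, 100), rep(92, 3), rep(95, 101))
  expect_equal(nrow(detect_events(spo2_trace(x3), odi_params(4, "A"))), 0)
})

test_that("strict duration mode requires more than the minimum", {
  x <- c(rep(96, 200), rep(90, 3), rep(96, 200))
  tr <- spo2_trace(x)
  p_ge <- odi_params(4, "T", min_duration_s = 3)
  p_gt <- odi_params(4, "T", min_duration_s = 3, strict_gt = TRUE)
  expect_equal(nrow(detect_events(tr, p_ge)), 1)
  expect_equal(nrow(detect_events(tr, p_gt)), 0)
})

test_that("invalid samples break runs and never sit inside events", {
  x <- c(rep(96, 100), rep(90, 9), rep(96, 100))
  valid <- rep(TRUE, length(x))
  valid[105] <- FALSE  # splits the 9-s dip into 4 + 4
  tr <- spo2_trace(x, valid = valid)
  ev <- detect_events(tr, odi_params(4, "T"))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration_s, c(4, 4))
})

test_that("event detection matches the brute-force oracle on random traces", {
  for (s in 1:20) {
    tr <- remove_artifacts(random_test_trace(s + 300))
    for (thr in c(2, 3, 4)) {
      got <- detect_events(tr, odi_params(thr, "T"))
      want <- oracle_detect(tr$spo2_pct, tr$valid,
                            oracle_baseline_T(tr$spo2_pct, tr$valid), thr)
      expect_equal(got[, names(want)], want, ignore_attr = TRUE)
    }
    gotA <- detect_events(tr, odi_params(4, "A"))
    baseA <- rep(mean(tr$spo2_pct[tr$valid]), length(tr))
    wantA <- oracle_detect(tr$spo2_pct, tr$valid, baseA, 4)
    expect_equal(gotA[, names(wantA)], wantA, ignore_attr = TRUE)
  }
})

test_that("relative-percentage thresholds are available behind a flag", {
  # baseline ~94.9; a 4% relative threshold (~3.8 points) catches a dip that
  # the default absolute 4-point threshold does not
  x <- c(rep(95, 100), rep(91.1, 5), rep(95, 100))
  tr <- spo2_trace(x)
  expect_equal(nrow(detect_events(tr, odi_params(4, "A"))), 0)
  expect_equal(nrow(detect_events(tr, odi_params(4, "A", relative = TRUE))), 1)
})

test_that("forced square-wave events give the exact index values", {
  # 30 events of depth 6 and width 20 s on a flat 96 trace over 6 h
  x <- rep(96, 21600)
  onsets <- seq(300, by = 600, length.out = 30)
  for (o in onsets) x[o:(o + 19)] <- 90
  tr <- spo2_trace(x)
  res <- compute_odi(tr)
  expect_equal(res$valid_hours, 6)
  expect_equal(res$odi4a, 5.0)
  expect_equal(res$odi2, 5.0)
  expect_equal(res$odi3, 5.0)
  expect_equal(res$odi4t, 5.0)

  # flat trace: every index is zero
  flat <- compute_odi(spo2_trace(rep(96, 7200)))
  expect_equal(flat$odi4a + flat$odi4t + flat$odi3 + flat$odi2, 0)
})

test_that("duplicating a trace end-to-end leaves every index unchanged", {
  x <- rep(96, 10800)
  onsets <- seq(300, by = 700, length.out = 15)
  for (o in onsets) x[o:(o + 24)] <- 89
  one <- compute_odi(spo2_trace(x))
  two <- compute_odi(spo2_trace(c(x, x)))
  expect_equal(two$valid_hours, 2 * one$valid_hours)
  for (v in c("odi2", "odi3", "odi4t", "odi4a")) {
    expect_equal(two[[v]], one[[v]], tolerance = 1e-9)
  }
})

test_that("event counts are monotone in the threshold", {
  for (s in 1:10) {
    tr <- remove_artifacts(random_test_trace(s + 700))
    res <- compute_odi(tr)
    expect_lte(res$odi4t, res$odi3)
    expect_lte(res$odi3, res$odi2)
  }
})

test_that("each index uses its own event-count-over-hours identity", {
  tr <- remove_artifacts(random_test_trace(901))
  res <- compute_odi(tr)
  for (v in c("odi2", "odi3", "odi4t", "odi4a")) {
    expect_equal(res[[v]], res$n_events[[v]] / res$valid_hours, tolerance = 1e-12)
  }
})
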