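test_that("largest-remainder rounding reproduces the reference group sizes", {
  spec <- cohort_spec(n_patients = 616,
                      severity_mix = c(0.117, 0.206, 0.214, 0.463), seed = 3)
  cohort <- generate_cohort(spec)
  expect_equal(unname(table(factor(cohort$severity, severity_levels()))),
               c(72L, 127L, 132L, 285L), ignore_attr = TRUE)
})

test_that("degenerate severity mix yields an all-normal cohort", {
  cohort <- generate_cohort(cohort_spec(n_patients = 10,
                                        severity_mix = c(1, 0, 0, 0), seed = 1))
  expect_equal(nrow(cohort), 10)
  expect_true(all(cohort$severity == "normal"))
  expect_true(all(cohort$ahi < 5))
})

test_that("cohort draws respect physical ranges and severity bands", {
  cohort <- generate_cohort(cohort_spec(n_patients = 120, seed = 11))
  expect_true(all(cohort$age >= 20 & cohort$age <= 85))
  expect_true(all(cohort$ess >= 0 & cohort$ess <= 24))
  expect_true(all(cohort$bmi > 10 & cohort$nc > 20))
  expect_true(all(cohort$trt_min >= cohort$tst_min))
  expect_identical(as.character(classify_severity(cohort$ahi)),
                   cohort$severity)
})

test_that("cohort generation is deterministic and reproducible patient by patient", {
  spec <- cohort_spec(n_patients = 30, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # a wider cohort with the same base seed reproduces the shared patients
  wide <- generate_cohort(cohort_spec(n_patients = 40, seed = 42,
                                      severity_mix = c(1, 0, 0, 0)))
  narrow <- generate_cohort(cohort_spec(n_patients = 20, seed = 42,
                                        severity_mix = c(1, 0, 0, 0)))
  expect_equal(wide$ahi[1:20], narrow$ahi)
})

test_that("cohort_spec rejects invalid configurations", {
  expect_error(cohort_spec(severity_mix = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(cohort_spec(n_patients = 3), ">= 4")
})

test_that("plant_events produces the forced event count", {
  expect_equal(nrow(plant_events(30, 6, seed = 1)), 180)
  expect_equal(nrow(plant_events(0, 6, seed = 1)), 0)
  ev <- plant_events(15, 4, seed = 9)
  expect_true(all(ev$duration_s >= 10 & ev$duration_s <= 60))
  expect_true(all(diff(ev$onset_s) >= ev$duration_s[-nrow(ev)]))
})

test_that("event-depth mixture puts at least 80% of events past 4 points", {
  frac <- vapply(1:20, function(s) {
    ev <- plant_events(30, 6, seed = s)
    mean(ev$depth_pct > 4)
  }, 0)
  expect_true(all(frac >= 0.75))
  expect_gte(mean(frac), 0.8)
})

test_that("plant_events refuses densities that cannot be placed", {
  expect_error(plant_events(250, 6, seed = 1), "events/h")
})

test_that("a quiet trace with no events is constant at the resting level", {
  quiet <- oximeter_model(noise_sd = 0, artifact_spike_rate = 0, dropout_rate = 0)
  tr <- synthesize_trace(plant_events(0, 1, seed = 1), 3600, model = quiet,
                         seed = 5, resting_pct = 97)
  expect_equal(tr$spo2_pct, rep(97, 3600))
})

test_that("a planted event reaches its prescribed depth", {
  quiet <- oximeter_model(noise_sd = 0, artifact_spike_rate = 0, dropout_rate = 0)
  ev <- data.frame(onset_s = 300, duration_s = 30, depth_pct = 6, kind = "apnea")
  tr <- synthesize_trace(ev, 600, model = quiet, seed = 5, resting_pct = 97)
  expect_equal(min(tr$spo2_pct), 91, tolerance = 0.05)
  # the trough sits where it was planted
  expect_true(which.min(tr$spo2_pct) %in% 300:332)
})

test_that("synthesized artifacts are exactly the samples the cleaner flags", {
  model <- oximeter_model(noise_sd = 0.3, artifact_spike_rate = 6, dropout_rate = 1)
  tr <- synthesize_trace(plant_events(0, 6, seed = 2), 6 * 3600,
                         model = model, seed = 7)
  cleaned <- remove_artifacts(tr)
  # each downward spike invalidates itself and its successor, each dropout itself
  expect_equal(sum(!cleaned$valid), 2 * 36 + 6)
  expect_equal(valid_recording_hours(cleaned), 6 - (2 * 36 + 6) / 3600)
})

test_that("beat averaging is a fixed point on constant input and follows the closed form", {
  const <- spo2_trace(rep(95, 100))
  expect_equal(apply_beat_averaging(const, pulse = 60)$spo2_pct, rep(95, 100))

  # step response at 60 bpm: 1 beat/s, 4-beat window, alpha = 1 - exp(-1/4);
  # 4 beats (4 s) after the step the response has covered 1 - exp(-1)
  step <- spo2_trace(c(rep(90, 50), rep(96, 50)))
  y60 <- apply_beat_averaging(step, pulse = 60)$spo2_pct
  expect_equal(y60[54], 90 + 6 * (1 - exp(-1)), tolerance = 1e-9)

  # at 120 bpm the window is 8 beats, so 4 beats (= 2 s) after the step the
  # response is further behind
  y120 <- apply_beat_averaging(step, pulse = 120)$spo2_pct
  expect_lt(y120[52] - 90, y60[54] - 90)
  expect_equal(y120[52], 90 + 6 * (1 - exp(-0.5)), tolerance = 1e-9)
})

test_that("beat averaging validates the pulse series", {
  tr <- spo2_trace(rep(95, 10))
  expect_error(apply_beat_averaging(tr, pulse = c(rep(60, 9), 0)), "positive")
  expect_error(apply_beat_averaging(tr, pulse = rep(60, 5)), "mismatch")
})

test_that("synthesized traces are deterministic under a fixed seed", {
  ev <- plant_events(20, 2, seed = 4)
  a <- synthesize_trace(ev, 7200, seed = 10)
  b <- synthesize_trace(ev, 7200, seed = 10)
  expect_identical(a, b)
  c <- synthesize_trace(ev, 7200, seed = 11)
  expect_false(identical(a$spo2_pct, c$spo2_pct))
})
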