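#' Default per-severity group parameters
#'
#' Means and standard deviations, per severity group (normal, mild, moderate,
#' severe), of the demographic, anthropometric, questionnaire and sleep
#' variables the generator draws. Values mirror a large clinical sleep-center
#' validation cohort of 616 patients referred for suspected OSA; AHI
#' parameters (not tabulated per group in that reference, since AHI defines
#' the grouping) are chosen so the overall mixture mean falls near the
#' reference overall AHI of about 34 events/h.
#'
#' @return A data.frame with one row per `(variable, group)` and columns
#'   `variable`, `group`, `mean`, `sd`.
#' @export
default_group_params <- function() {
  groups <- severity_levels()
  v <- function(variable, means, sds) {
    data.frame(variable = variable, group = groups, mean = means, sd = sds,
               stringsAsFactors = FALSE)
  }
  rbind(
    v("age",           c(36.2, 42.1, 45.9, 48.4),     c(10.2, 11.5, 12.8, 12.5)),
    v("bmi",           c(23.88, 25.60, 26.18, 28.22), c(3.15, 3.75, 3.68, 4.33)),
    v("nc",            c(36.24, 37.53, 38.69, 40.79), c(3.25, 3.52, 3.19, 3.10)),
    v("ess",           c(7.67, 8.54, 9.19, 9.93),     c(5.16, 4.77, 5.25, 5.34)),
    v("ahi",           c(2.5, 9.5, 21.5, 56),         c(1.8, 2.8, 4.2, 22)),
    v("tst_min",       c(317.8, 331.3, 307.6, 297.5), c(56.3, 48.9, 58.5, 69.8)),
    v("latency_min",   c(27.6, 16.2, 22.4, 17.9),     c(33.0, 13.6, 23.2, 18.2)),
    v("arousal_index", c(19.3, 20.6, 26.6, 46.3),     c(10.8, 10.1, 11.2, 21.9)),
    v("hr_bpm",        c(70.31, 71.05, 72.64, 75.41), c(8.45, 10.61, 9.50, 11.97))
  )
}

#' Specification of a synthetic study population
#'
#' Bundles the generative parameters for a cohort of patients referred for
#' suspected obstructive sleep apnea: the severity mix, per-group means and
#' SDs of every drawn variable, per-group female fractions, and the global
#' seed from which each patient's private seed is derived.
#'
#' @param n_patients number of patients (>= 4, so each group can be covered).
#' @param severity_mix proportions of normal / mild / moderate / severe
#'   patients; must sum to 1.
#' @param group_params data.frame in the format of [default_group_params()].
#' @param female_fraction per-group probability that a patient is female.
#' @param seed integer; patient `i` draws from seed `seed + i`.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 40, seed = 7)
cohort_spec <- function(n_patients = 616,
                        severity_mix = c(normal = 0.117, mild = 0.206,
                                         moderate = 0.214, severe = 0.463),
                        group_params = default_group_params(),
                        female_fraction = c(0.444, 0.386, 0.235, 0.102),
                        seed = 1L) {
  if (abs(sum(severity_mix) - 1) > 1e-9) {
    stop("severity_mix must sum to 1", call. = FALSE)
  }
  if (any(severity_mix < 0 | severity_mix > 1)) {
    stop("severity_mix proportions must lie in [0, 1]", call. = FALSE)
  }
  if (n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  if (any(group_params$sd < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (any(female_fraction < 0 | female_fraction > 1)) {
    stop("female_fraction values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         severity_mix = severity_mix,
         group_params = group_params,
         female_fraction = female_fraction,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Largest-remainder apportionment of n into proportions p.
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    # ties broken by group order for determinism
    take <- order(-frac, seq_along(p))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# band of admissible AHI values per severity group
ahi_band <- function(group) {
  switch(group,
         normal = c(0, 5), mild = c(5, 15),
         moderate = c(15, 30), severe = c(30, Inf))
}

# normal draw rejected until it falls inside [lo, hi)
draw_in_band <- function(mean, sd, lo, hi, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x < hi) return(x)
  }
  # pathological parameters: fall back to a uniform draw inside the band
  runif(1, lo, min(hi, lo + 4 * sd + 1))
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per patient: severity group sizes by largest-remainder
#' rounding of the severity mix, per-group normal draws truncated to physical
#' ranges (age clipped to 20--85 years, BMI > 10, NC > 20 cm, ESS in 0--24),
#' and AHI rejection-sampled into the group's severity band so every record's
#' label is consistent with its AHI. Each patient uses the private seed
#' `spec$seed + i`, making the cohort reproducible patient by patient.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of class `cohort` with one row per patient:
#'   `patient_id`, `severity`, `sex`, `age`, `bmi`, `nc`, `ess`, `ahi`,
#'   `tst_min`, `latency_min`, `trt_min`, `arousal_index`, `arousal_count`,
#'   `hr_bpm`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 1))
#' table(cohort$severity)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- severity_levels()
  sizes <- largest_remainder(spec$n_patients, spec$severity_mix)
  severity <- rep(groups, times = sizes)
  gp <- spec$group_params
  par <- function(variable, group) {
    row <- gp[gp$variable == variable & gp$group == group, ]
    if (nrow(row) != 1) stop(sprintf("missing group parameters for %s/%s",
                                     variable, group), call. = FALSE)
    row
  }

  n <- spec$n_patients
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    g <- severity[i]
    gi <- match(g, groups)
    rec[[i]] <- with_seed(spec$seed + i, {
      band <- ahi_band(g)
      p <- function(v) par(v, g)
      ahi <- draw_in_band(p("ahi")$mean, p("ahi")$sd, band[1], band[2])
      tst <- clip(rnorm(1, p("tst_min")$mean, p("tst_min")$sd), 61, 540)
      latency <- clip(rnorm(1, p("latency_min")$mean, p("latency_min")$sd), 0, 240)
      ai <- clip(rnorm(1, p("arousal_index")$mean, p("arousal_index")$sd), 0, NULL)
      # recording continues past sleep: latency plus residual wake time
      trt <- tst + latency + runif(1, 5, 30)
      data.frame(
        patient_id = sprintf("P%04d", i),
        severity = g,
        sex = if (runif(1) < spec$female_fraction[gi]) "female" else "male",
        age = clip(rnorm(1, p("age")$mean, p("age")$sd), 20, 85),
        bmi = clip(rnorm(1, p("bmi")$mean, p("bmi")$sd), 10.1, NULL),
        nc = clip(rnorm(1, p("nc")$mean, p("nc")$sd), 20.1, NULL),
        ess = round(clip(rnorm(1, p("ess")$mean, p("ess")$sd), 0, 24)),
        ahi = ahi,
        tst_min = tst,
        latency_min = latency,
        trt_min = trt,
        arousal_index = ai,
        arousal_count = round(ai * tst / 60),
        hr_bpm = clip(rnorm(1, p("hr_bpm")$mean, p("hr_bpm")$sd), 40, 150),
        seed = spec$seed + i,
        stringsAsFactors = FALSE
      )
    })
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' Simulate the overnight SpO2 trace of one patient record
#'
#' Plants respiratory events at the record's AHI over its total sleep time
#' and renders the 1-Hz trace through the oximeter model, using the record's
#' heart rate as the (constant) pulse series and a trace seed offset from the
#' patient seed so event placement and feature draws use distinct streams.
#'
#' @param record one row of a [generate_cohort()] data.frame.
#' @param model an [oximeter_model()].
#' @return A list with elements `trace` ([spo2_trace()]) and `events`
#'   (the planted-event schedule).
#' @export
simulate_patient_trace <- function(record, model = oximeter_model()) {
  tst_h <- record$tst_min / 60
  trace_seed <- (record$seed %% 1000000000L) + 100003L
  events <- plant_events(record$ahi, tst_h, seed = trace_seed)
  duration <- round(record$tst_min * 60)
  trace <- synthesize_trace(events, duration, model = model,
                            seed = trace_seed + 1L,
                            pulse_bpm = record$hr_bpm)
  list(trace = trace, events = events)
}

#' Simulate a cohort and compute its oximetry indices
#'
#' End-to-end convenience used throughout validation: generates the cohort,
#' synthesizes each patient's trace, removes artifacts, and computes the four
#' desaturation indices.
#'
#' @param spec a [cohort_spec()].
#' @param model an [oximeter_model()].
#' @param variants which index variants to compute; any subset of
#'   `c("odi2", "odi3", "odi4t", "odi4a")`. Restricting to `"odi4a"` skips
#'   the moving-baseline computation and is considerably faster.
#' @return The cohort data.frame augmented with the requested ODI columns and
#'   `valid_hours`.
#' @export
simulate_odi_cohort <- function(spec, model = oximeter_model(),
                                variants = c("odi2", "odi3", "odi4t", "odi4a")) {
  cohort <- generate_cohort(spec)
  idx <- lapply(seq_len(nrow(cohort)), function(i) {
    sim <- simulate_patient_trace(cohort[i, ], model)
    tr <- remove_artifacts(sim$trace)
    res <- compute_odi(tr, variants = variants)
    c(unlist(res[variants]), valid_hours = res$valid_hours)
  })
  cbind(cohort, do.call(rbind, idx))
}
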