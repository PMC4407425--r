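#' Plant respiratory events for a prescribed AHI
#'
#' Generates the respiratory-event schedule (apneas and hypopneas) that an
#' overnight recording with a given apnea-hypopnea index should contain:
#' exactly `round(ahi * tst_hours)` events, onsets uniform over the sleep
#' period without overlap, durations uniform on 10--60 s (the ceiling
#' shortens with the respiratory cycle `3600/ahi` at high event densities,
#' as in severe disease), and desaturation depths drawn from a two-component
#' mixture in which a fraction `deep_fraction` of events fall more than 4
#' percentage points below the local baseline (the clinically scoreable
#' depth) and the remainder are shallower excursions of 1.5--4 points.
#'
#' @param ahi target apnea-hypopnea index, events per hour (>= 0).
#' @param tst_hours total sleep time in hours (> 0).
#' @param seed integer seed; the schedule is deterministic given
#'   `(ahi, tst_hours, seed)`.
#' @param deep_fraction fraction of events whose depth exceeds 4 points.
#' @param min_gap_s minimum gap between the end of one event and the onset of
#'   the next, seconds. The default of 10 s leaves room for resaturation to
#'   recross even the shallow 2-point threshold, so consecutive scored events
#'   remain distinct at every index variant.
#' @return A data.frame with columns `onset_s`, `duration_s`, `depth_pct`,
#'   `kind` (`"apnea"` or `"hypopnea"`), sorted by onset.
#' @export
#' @examples
#' ev <- plant_events(ahi = 30, tst_hours = 6, seed = 1)
#' nrow(ev)  # 180
plant_events <- function(ahi, tst_hours, seed, deep_fraction = 0.85,
                         min_gap_s = 10) {
  if (ahi < 0) stop("ahi must be >= 0", call. = FALSE)
  if (tst_hours <= 0) stop("tst_hours must be > 0", call. = FALSE)
  n <- round(ahi * tst_hours)
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      depth_pct = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  span <- tst_hours * 3600
  # onsets start after the first minute (so the moving baseline is defined)
  # and events must end 30 s before the recording stops
  lo <- 60
  hi <- span - 90
  # at high event densities the respiratory cycle shortens, so the duration
  # ceiling scales with the cycle length 3600/ahi (bounded to [12, 60] s)
  dur_max <- if (ahi > 0) min(60, max(12, 0.6 * 3600 / ahi)) else 60

  with_seed(seed, {
    duration <- round(runif(n, 10, dur_max))
    deep <- runif(n) < deep_fraction
    depth <- ifelse(deep, runif(n, 4.5, 10), runif(n, 1.5, 4))
    kind <- ifelse(depth >= 4 & runif(n) < 0.4, "hypopnea", "apnea")
    slack <- (hi - lo) - sum(duration) - min_gap_s * n
    if (slack < 0 || hi <= lo) {
      stop(sprintf(
        "cannot place %d events without overlap; maximum supported rate is about %.0f events/h",
        n, 3600 / (mean(duration) + min_gap_s)), call. = FALSE)
    }
    # distribute the free time over the n+1 inter-event gaps uniformly at
    # random (order statistics of n uniforms), keeping min_gap_s everywhere
    u <- sort(runif(n))
    extra <- diff(c(0, u, 1)) * slack
    onset <- lo + round(cumsum(extra[seq_len(n)]) +
                          cumsum(c(0, duration[-n] + min_gap_s)))
    data.frame(onset_s = onset, duration_s = duration, depth_pct = depth,
               kind = kind, stringsAsFactors = FALSE)
  })
}

#' Synthesize a 1-Hz SpO2 trace from planted events
#'
#' Renders each planted event as a desaturation trough (linear descent over
#' the first part of the event at no more than 3 points/s, a plateau at the
#' event depth, and exponential resaturation with a 3-s time constant after
#' the event ends), passes the clean signal through the oximeter's
#' beat-averaged response, adds Gaussian measurement noise, and injects the
#' two artifact classes: single-sample spikes (jumps exceeding 4 points) and
#' probe dropouts (readings below 50%).
#'
#' @param events event schedule from [plant_events()] (may be empty).
#' @param duration_s recording length in seconds (>= 60).
#' @param model an [oximeter_model()].
#' @param seed integer seed; output is deterministic given all arguments.
#' @param resting_pct resting (awake, unobstructed) saturation level; drawn
#'   uniformly from 96--98% when `NULL`.
#' @param pulse_bpm pulse rate, single value or per-sample vector; default 72.
#' @return An [spo2_trace()].
#' @export
synthesize_trace <- function(events, duration_s, model = oximeter_model(),
                             seed = 1L, resting_pct = NULL, pulse_bpm = 72) {
  if (duration_s < 60) {
    stop("duration_s must be >= 60 (moving baseline undefined on shorter traces)",
         call. = FALSE)
  }
  duration_s <- as.integer(duration_s)
  if (nrow(events) && any(events$onset_s + events$duration_s > duration_s)) {
    stop("all events must fit within duration_s", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(resting_pct)) resting_pct <- runif(1, 96, 98)
    # depression below resting level, elementwise max across events
    depression <- numeric(duration_s)
    if (nrow(events)) {
      for (e in seq_len(nrow(events))) {
        dur <- events$duration_s[e]
        depth <- events$depth_pct[e]
        onset <- events$onset_s[e]
        descent <- max(ceiling(0.3 * dur), ceiling(depth / 3))
        descent <- min(descent, dur)
        prof <- c(seq_len(descent) / descent * depth,        # descent
                  rep(depth, dur - descent))                 # plateau
        tail_len <- min(30L, duration_s - (onset + dur))
        if (tail_len > 0) {
          prof <- c(prof, depth * exp(-(seq_len(tail_len)) / 3))  # recovery
        }
        idx <- onset + seq_along(prof)  # onset is in seconds; sample i = second i-1
        depression[idx] <- pmax(depression[idx], prof)
      }
    }
    x <- resting_pct - depression
    tr <- spo2_trace(clip(x, 0, 100), pulse_bpm = pulse_bpm)
    tr <- apply_beat_averaging(tr, model = model)
    x <- tr$spo2_pct
    if (model$noise_sd > 0) x <- x + rnorm(duration_s, 0, model$noise_sd)

    hours <- duration_s / 3600
    n_spike <- round(model$artifact_spike_rate * hours)
    n_drop <- round(model$dropout_rate * hours)
    n_art <- n_spike + n_drop
    if (n_art > 0) {
      # artifact positions kept >= 3 s apart so each artifact is isolated
      cand <- seq(62L, duration_s - 2L)
      pos <- integer(0)
      while (length(pos) < n_art && length(cand)) {
        p <- cand[sample.int(length(cand), 1L)]
        pos <- c(pos, p)
        cand <- cand[abs(cand - p) > 3L]
      }
      if (length(pos) < n_art) stop("trace too short for requested artifact rates",
                                    call. = FALSE)
      spikes <- pos[seq_len(n_spike)]
      drops <- pos[n_spike + seq_len(n_drop)]
      # motion spikes point downward so the >4-point jump survives the
      # physical ceiling at 100%
      if (n_spike) x[spikes] <- x[spikes] - runif(n_spike, 5, 15)
      if (n_drop) x[drops] <- runif(n_drop, 20, 45)
    }
    spo2_trace(clip(x, 0, 100), pulse_bpm = tr$pulse_bpm)
  })
}
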