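#' Oximeter instrument model
#'
#' Parameters describing how the simulated finger-probe oximeter transforms
#' the true saturation signal: beat-based exponential averaging whose window
#' doubles at high pulse rates, additive measurement noise, and the two
#' artifact classes an automated preprocessor must remove (single-sample
#' spikes and probe-dropout readings below 50%).
#'
#' The averaging window is `averaging_beats_base` beats (default 4) for pulse
#' rates up to the first threshold, and doubles at each threshold crossed:
#' 8 beats above 112 bpm, 16 beats above 225 bpm with the defaults.
#'
#' @param averaging_beats_base base averaging window in beats (>= 1).
#' @param rate_thresholds strictly increasing pulse-rate thresholds (bpm) at
#'   which the window doubles.
#' @param noise_sd standard deviation of additive Gaussian measurement noise,
#'   in saturation percentage points.
#' @param artifact_spike_rate rate of injected single-sample spike artifacts,
#'   events per hour.
#' @param dropout_rate rate of injected probe-dropout samples (< 50%),
#'   events per hour.
#' @return An object of class `oximeter_model` (a named list).
#' @export
#' @examples
#' oximeter_model()
oximeter_model <- function(averaging_beats_base = 4L,
                           rate_thresholds = c(112, 225),
                           noise_sd = 0.3,
                           artifact_spike_rate = 2,
                           dropout_rate = 0.5) {
  if (averaging_beats_base < 1) stop("averaging_beats_base must be >= 1", call. = FALSE)
  if (length(rate_thresholds) && any(diff(rate_thresholds) <= 0)) {
    stop("rate_thresholds must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (artifact_spike_rate < 0 || dropout_rate < 0) {
    stop("artifact rates must be >= 0", call. = FALSE)
  }
  structure(
    list(averaging_beats_base = as.integer(averaging_beats_base),
         rate_thresholds = as.numeric(rate_thresholds),
         noise_sd = noise_sd,
         artifact_spike_rate = artifact_spike_rate,
         dropout_rate = dropout_rate),
    class = "oximeter_model"
  )
}

# window length in beats at a given instantaneous pulse rate
averaging_window_beats <- function(pulse_bpm, model) {
  doublings <- vapply(pulse_bpm, function(p) sum(p > model$rate_thresholds), 0)
  model$averaging_beats_base * 2^doublings
}

#' Apply beat-based exponential averaging
#'
#' Models the oximeter's internal smoothing: an exponential moving average
#' whose effective window is a fixed number of heart beats, so the smoothing
#' constant at 1-Hz sampling depends on the instantaneous pulse rate. The
#' per-sample constant is `alpha = 1 - exp(-beats_per_sample / window_beats)`
#' with `beats_per_sample = pulse_bpm / 60`; after exactly `window_beats`
#' beats of a step input the response has covered `1 - exp(-1)` of the step.
#'
#' @param raw an [spo2_trace()] carrying the unsmoothed signal.
#' @param pulse pulse rate in bpm: a single value or a per-sample vector.
#'   Defaults to the trace's own `pulse_bpm`, or 72 bpm if absent.
#' @param model an [oximeter_model()].
#' @return An `spo2_trace` of the same length with the smoothed signal.
#' @export
apply_beat_averaging <- function(raw, pulse = NULL, model = oximeter_model()) {
  stopifnot(inherits(raw, "spo2_trace"))
  n <- length(raw)
  if (is.null(pulse)) pulse <- if (is.null(raw$pulse_bpm)) 72 else raw$pulse_bpm
  if (length(pulse) == 1L) pulse <- rep(as.numeric(pulse), n)
  if (length(pulse) != n) stop("pulse series length mismatch", call. = FALSE)
  if (any(pulse <= 0)) stop("pulse values must be positive", call. = FALSE)
  window <- averaging_window_beats(pulse, model)
  alpha <- 1 - exp(-(pulse / 60) / window)
  y <- cpp_ema(raw$spo2_pct, alpha)
  spo2_trace(y, pulse_bpm = pulse, valid = raw$valid)
}
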