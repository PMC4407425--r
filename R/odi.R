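#' Desaturation-detection parameters
#'
#' An oxyhemoglobin desaturation index ODI*nb* is parameterized by a depth
#' threshold *n* (percentage points below baseline), a baseline convention
#' *b*, and a minimum event duration (fixed at 3 s here). Baseline `"A"` is
#' the all-night mean of the valid signal; baseline `"T"` is the mean of the
#' top 20% of valid values in the minute preceding each sample.
#'
#' @param threshold_pct depth threshold in percentage points (> 0).
#' @param baseline `"T"` (moving top-20% of the preceding minute) or `"A"`
#'   (all-night mean).
#' @param min_duration_s minimum event duration in seconds (>= 1).
#' @param relative if `TRUE`, interpret the threshold as a relative
#'   percentage of the baseline rather than an absolute drop in saturation
#'   points (the standard oximetry convention, and the default).
#' @param strict_gt if `TRUE`, require duration strictly greater than
#'   `min_duration_s` instead of at least `min_duration_s`.
#' @return An object of class `odi_params`.
#' @export
odi_params <- function(threshold_pct = 4, baseline = c("T", "A"),
                       min_duration_s = 3, relative = FALSE,
                       strict_gt = FALSE) {
  baseline <- match.arg(baseline)
  if (threshold_pct <= 0) stop("threshold_pct must be > 0", call. = FALSE)
  if (min_duration_s < 1) stop("min_duration_s must be >= 1", call. = FALSE)
  structure(list(threshold_pct = threshold_pct, baseline = baseline,
                 min_duration_s = as.integer(min_duration_s),
                 relative = relative, strict_gt = strict_gt),
            class = "odi_params")
}

#' All-night mean baseline
#'
#' @param trace an [spo2_trace()] with at least one valid sample.
#' @return A numeric vector (constant) of the same length as the trace:
#'   the mean saturation over all valid samples.
#' @export
baseline_all_night <- function(trace) {
  stopifnot(inherits(trace, "spo2_trace"))
  if (!any(trace$valid)) stop("no valid samples in trace", call. = FALSE)
  rep(mean(trace$spo2_pct[trace$valid]), length(trace))
}

#' Moving top-20% baseline of the preceding minute
#'
#' For each sample, the baseline is the mean of the top 20% (rounded up) of
#' valid saturation values in the half-open window covering the 60 s before
#' the sample. Where fewer than `min_window_samples` valid values precede a
#' sample, the baseline is undefined (`NA`) and no desaturation event may
#' include that sample. The default of 12 equals the top-20% count of a full
#' 60-sample window, so the baseline is never a mean over a tiny set.
#'
#' @param trace an [spo2_trace()].
#' @param window_s window length in seconds.
#' @param min_window_samples minimum number of valid samples required in the
#'   window for the baseline to be defined.
#' @param top_frac fraction of the window entering the mean.
#' @return Numeric vector of per-sample baselines, `NA` where undefined.
#' @export
baseline_top20_preceding <- function(trace, window_s = 60L,
                                     min_window_samples = 12L,
                                     top_frac = 0.2) {
  stopifnot(inherits(trace, "spo2_trace"))
  cpp_top_frac_baseline(trace$spo2_pct, trace$valid,
                        as.integer(window_s), as.integer(min_window_samples),
                        top_frac)
}

#' Detect oxyhemoglobin desaturation events
#'
#' A desaturation *episode* is a maximal run of consecutive valid,
#' baseline-defined samples strictly below the baseline; episodes are broken
#' by any invalid or baseline-undefined sample, so they never span artifact
#' gaps. An episode counts as an event at threshold *n* when it contains at
#' least `min_duration_s` consecutive samples at or below
#' `baseline - threshold` (or `baseline * (1 - threshold/100)` in relative
#' mode). Because episode boundaries do not depend on the threshold, event
#' counts are exactly monotone in it: every episode 4 points deep is a
#' fortiori 3 points deep. One event is reported per qualifying episode; its
#' extent is the episode's first qualifying sub-threshold run (so every
#' in-event sample satisfies the threshold), and its nadir is the episode
#' minimum. Durations are inclusive: a run of *k* 1-Hz samples lasts *k*
#' seconds.
#'
#' @param trace an [spo2_trace()] (artifact removal should have been applied).
#' @param params an [odi_params()].
#' @return A data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `nadir_pct`, `threshold_used`, in time order, one row per qualifying
#'   episode.
#' @export
#' @examples
#' tr <- spo2_trace(c(rep(96, 100), rep(90, 5), rep(96, 20)))
#' detect_events(tr, odi_params(4, baseline = "A"))
detect_events <- function(trace, params = odi_params()) {
  stopifnot(inherits(trace, "spo2_trace"), inherits(params, "odi_params"))
  if (length(trace) == 0L) stop("empty trace", call. = FALSE)
  base <- switch(params$baseline,
                 A = baseline_all_night(trace),
                 T = baseline_top20_preceding(trace))
  lim <- if (params$relative) base * (1 - params$threshold_pct / 100)
         else base - params$threshold_pct
  ok <- trace$valid & !is.na(base)
  excur <- ok & trace$spo2_pct < base
  qual <- ok & trace$spo2_pct <= lim
  min_len <- params$min_duration_s + as.integer(params$strict_gt)

  r <- rle(excur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    span <- starts[k]:ends[k]
    qr <- rle(qual[span])
    qe <- cumsum(qr$lengths)
    qs <- qe - qr$lengths + 1L
    hit <- which(qr$values & qr$lengths >= min_len)
    if (!length(hit)) next
    s <- span[qs[hit[1]]]
    e <- span[qe[hit[1]]]
    out[[length(out) + 1L]] <- data.frame(
      start_s = trace$time_s[s], end_s = trace$time_s[e],
      duration_s = e - s + 1L,
      nadir_pct = min(trace$spo2_pct[span]),
      threshold_used = params$threshold_pct)
  }
  if (!length(out)) {
    return(data.frame(start_s = integer(0), end_s = integer(0),
                      duration_s = integer(0), nadir_pct = numeric(0),
                      threshold_used = numeric(0)))
  }
  do.call(rbind, out)
}

#' Compute the four desaturation indices of a recording
#'
#' Runs event detection for the four standard variants -- ODI2 and ODI3
#' (thresholds 2 and 3 points, moving top-20% baseline), ODI4T (4 points,
#' moving baseline) and ODI4A (4 points, all-night mean baseline) -- and
#' divides each event count by the valid recording time in hours.
#'
#' @param trace an [spo2_trace()] after [remove_artifacts()].
#' @param min_duration_s minimum event duration, seconds.
#' @param denominator passed to [valid_recording_hours()].
#' @param variants subset of `c("odi2", "odi3", "odi4t", "odi4a")` to compute.
#' @return An object of class `odi_result`: a list with the requested index
#'   values (events/h), `valid_hours`, per-variant event counts `n_events`,
#'   and per-variant event tables `events`.
#' @export
#' @examples
#' tr <- spo2_trace(rep(96, 3600))
#' compute_odi(tr)$odi4a
compute_odi <- function(trace, min_duration_s = 3,
                        denominator = c("valid", "total"),
                        variants = c("odi2", "odi3", "odi4t", "odi4a")) {
  denominator <- match.arg(denominator)
  variants <- match.arg(variants, several.ok = TRUE)
  hours <- valid_recording_hours(trace, denominator)
  defs <- list(
    odi2 = odi_params(2, "T", min_duration_s),
    odi3 = odi_params(3, "T", min_duration_s),
    odi4t = odi_params(4, "T", min_duration_s),
    odi4a = odi_params(4, "A", min_duration_s)
  )
  events <- lapply(defs[variants], function(p) detect_events(trace, p))
  counts <- vapply(events, nrow, 0L)
  out <- as.list(counts / hours)
  out$valid_hours <- hours
  out$n_events <- counts
  out$events <- events
  structure(out, class = "odi_result")
}

#' @export
print.odi_result <- function(x, ...) {
  vars <- intersect(c("odi2", "odi3", "odi4t", "odi4a"), names(x))
  cat(sprintf("<odi_result> %.2f valid hours\n", x$valid_hours))
  for (v in vars) {
    cat(sprintf("  %-6s %7.2f events/h (%d events)\n",
                toupper(v), x[[v]], x$n_events[[v]]))
  }
  invisible(x)
}
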