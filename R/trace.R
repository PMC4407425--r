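#' Construct a 1-Hz SpO2 trace
#'
#' The fundamental container of the package: an overnight pulse-oximetry
#' recording sampled at 1 Hz, together with a per-sample validity mask that
#' downstream artifact removal manipulates. Time is implicit: sample `i`
#' corresponds to second `i - 1` of the recording.
#'
#' @param spo2_pct numeric vector of oxygen saturation values in percent
#'   (0--100 scale).
#' @param pulse_bpm optional numeric vector of pulse rate in beats per minute,
#'   same length as `spo2_pct`. A single value is recycled.
#' @param valid optional logical mask, same length; defaults to all `TRUE`.
#'
#' @return An object of class `spo2_trace`: a list with elements `time_s`
#'   (integer seconds starting at 0), `spo2_pct`, `pulse_bpm` (may be `NULL`),
#'   and `valid`.
#' @export
#' @examples
#' tr <- spo2_trace(c(96, 96, 95, 96))
#' tr$time_s
spo2_trace <- function(spo2_pct, pulse_bpm = NULL, valid = NULL) {
  spo2_pct <- as.numeric(spo2_pct)
  n <- length(spo2_pct)
  if (n == 0L) stop("empty trace", call. = FALSE)
  if (anyNA(spo2_pct)) stop("SpO2 values must not contain NA", call. = FALSE)
  if (any(spo2_pct < 0 | spo2_pct > 100)) {
    stop("SpO2 values must lie in [0, 100] percent", call. = FALSE)
  }
  if (!is.null(pulse_bpm)) {
    if (length(pulse_bpm) == 1L) pulse_bpm <- rep(as.numeric(pulse_bpm), n)
    if (length(pulse_bpm) != n) stop("pulse series length mismatch", call. = FALSE)
    if (any(pulse_bpm <= 0)) stop("pulse values must be positive", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n || !is.logical(valid) || anyNA(valid)) {
    stop("`valid` must be a logical mask matching the trace length", call. = FALSE)
  }
  structure(
    list(time_s = 0:(n - 1L), spo2_pct = spo2_pct,
         pulse_bpm = pulse_bpm, valid = valid),
    class = "spo2_trace"
  )
}

#' @export
length.spo2_trace <- function(x) length(x$spo2_pct)

#' @export
print.spo2_trace <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<spo2_trace> %d samples (%.2f h), %d valid (%.1f%%)\n",
              n, n / 3600, sum(x$valid), 100 * mean(x$valid)))
  cat(sprintf("  SpO2 range of valid samples: %.1f-%.1f%%\n",
              min(x$spo2_pct[x$valid]), max(x$spo2_pct[x$valid])))
  invisible(x)
}

#' @export
as.data.frame.spo2_trace <- function(x, ...) {
  data.frame(
    time_s = x$time_s,
    spo2_pct = x$spo2_pct,
    pulse_bpm = if (is.null(x$pulse_bpm)) NA_real_ else x$pulse_bpm,
    valid = x$valid
  )
}

#' Read / write SpO2 trace CSV files
#'
#' Traces are stored as plain CSV with columns `time_s,spo2_pct,pulse_bpm`
#' (and optionally `valid`). `time_s` must start at 0 and increase in 1-s
#' steps.
#'
#' @param path file path.
#' @param trace an [spo2_trace()] object.
#' @return `read_trace_csv()` returns an `spo2_trace`; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "spo2_pct") %in% names(d))) {
    stop("trace CSV must have columns time_s, spo2_pct", call. = FALSE)
  }
  if (d$time_s[1] != 0 || (nrow(d) > 1 && any(diff(d$time_s) != 1))) {
    stop("time_s must start at 0 and advance in 1-s steps", call. = FALSE)
  }
  pulse <- if ("pulse_bpm" %in% names(d) && !anyNA(d$pulse_bpm)) d$pulse_bpm else NULL
  valid <- if ("valid" %in% names(d)) as.logical(d$valid) else NULL
  spo2_trace(d$spo2_pct, pulse_bpm = pulse, valid = valid)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "spo2_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
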