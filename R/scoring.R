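#' Severity class labels, in order
#'
#' @return `c("normal", "mild", "moderate", "severe")`.
#' @export
severity_levels <- function() c("normal", "mild", "moderate", "severe")

validate_respiratory_events <- function(events) {
  needed <- c("kind", "onset_s", "duration_s")
  if (!all(needed %in% names(events))) {
    stop("respiratory events need columns kind, onset_s, duration_s", call. = FALSE)
  }
  short <- which(events$duration_s < 10)
  if (length(short)) {
    stop(sprintf("event(s) %s shorter than the 10-s minimum duration",
                 paste(utils::head(short, 5), collapse = ", ")), call. = FALSE)
  }
  if ("desat_pct" %in% names(events)) {
    hyp <- events$kind == "hypopnea" & !is.na(events$desat_pct)
    bad <- which(hyp & events$desat_pct < 4)
    if (length(bad)) {
      stop(sprintf("hypopnea event(s) %s lack the required >= 4%% desaturation",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(events)
}

#' Apnea-hypopnea index from a scored event list
#'
#' The AHI is the total number of apneas (central, mixed, or obstructive)
#' and hypopneas per hour of sleep. Events are validated against the scoring
#' definitions (duration of at least 10 s; hypopneas must carry a
#' desaturation of at least 4 points when the column is present).
#'
#' @param events data.frame of respiratory events with columns `kind`,
#'   `onset_s`, `duration_s` and optionally `desat_pct`.
#' @param tst_hours total sleep time in hours (> 0).
#' @return AHI in events per hour.
#' @export
#' @examples
#' ev <- data.frame(kind = "apnea", onset_s = c(0, 100), duration_s = 15)
#' compute_ahi(ev, tst_hours = 2)
compute_ahi <- function(events, tst_hours) {
  if (tst_hours <= 0) stop("tst_hours must be > 0", call. = FALSE)
  validate_respiratory_events(events)
  nrow(events) / tst_hours
}

#' Classify OSA severity from the AHI
#'
#' Severity bands use left-closed intervals: normal `[0, 5)`, mild `[5, 15)`,
#' moderate `[15, 30)`, severe `[30, Inf)`, so the boundary values 5, 15 and
#' 30 map to mild, moderate and severe respectively.
#'
#' @param ahi numeric vector of AHI values (>= 0).
#' @return Factor with levels [severity_levels()].
#' @export
#' @examples
#' classify_severity(c(4.99, 5, 15, 30, 34.07))
classify_severity <- function(ahi) {
  if (any(is.na(ahi)) || any(ahi < 0)) stop("ahi must be >= 0", call. = FALSE)
  cut(ahi, breaks = c(0, 5, 15, 30, Inf), labels = severity_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Arousal index
#'
#' Scored arousals per hour of sleep. Arousals are consumed as counts from
#' the polysomnogram scoring; no EEG analysis is performed here.
#'
#' @param count number of arousals (>= 0).
#' @param tst_hours total sleep time in hours (> 0).
#' @return Arousals per hour.
#' @export
arousal_index <- function(count, tst_hours) {
  if (any(tst_hours <= 0)) stop("tst_hours must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count / tst_hours
}

#' Read a respiratory-events CSV
#'
#' Expected columns: `patient_id,kind,onset_s,duration_s,desat_pct`.
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_respiratory_events(ev)
  ev
}
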