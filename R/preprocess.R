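#' Automated oximetry artifact elimination
#'
#' Flags as invalid (a) every sample below 50% saturation (probe dropout) and
#' (b) every sample whose change from its reference exceeds 4 percentage
#' points at the 1-s sampling interval (physiologically impossible slew, i.e.
#' motion artifact). The reference for the slew rule is the immediately
#' preceding sample's recorded value; if that sample was itself eliminated by
#' the dropout rule, the most recent retained value is used instead, so a
#' single dropout does not invalidate the sample after it. Values are never
#' altered, only masked, and the operation is idempotent.
#'
#' @param trace an [spo2_trace()].
#' @param max_delta maximum plausible change between consecutive samples,
#'   percentage points per second (default 4).
#' @param min_spo2 lowest plausible saturation reading (default 50).
#' @return The trace with its `valid` mask updated (a sample already invalid
#'   stays invalid).
#' @export
#' @examples
#' tr <- remove_artifacts(spo2_trace(c(96, 96, 45, 96)))
#' tr$valid  # TRUE TRUE FALSE TRUE
remove_artifacts <- function(trace, max_delta = 4, min_spo2 = 50) {
  stopifnot(inherits(trace, "spo2_trace"))
  x <- trace$spo2_pct
  n <- length(x)
  if (n == 0L) stop("empty trace", call. = FALSE)
  low <- x < min_spo2
  # index of the most recent non-dropout sample at or before each position
  idx <- seq_len(n)
  last_ok <- cummax(ifelse(low, 0L, idx))
  ref_idx <- c(0L, last_ok[-n])  # reference index for each sample (0 = none)
  jump <- rep(FALSE, n)
  has_ref <- ref_idx > 0L
  jump[has_ref] <- abs(x[has_ref] - x[ref_idx[has_ref]]) > max_delta
  trace$valid <- trace$valid & !low & !jump
  trace
}

#' Valid recording time in hours
#'
#' The denominator of every desaturation index: the artifact-free recording
#' time. With `denominator = "total"` the full trace length is used instead,
#' for sensitivity analyses of how the denominator convention affects the
#' indices.
#'
#' @param trace an [spo2_trace()], normally after [remove_artifacts()].
#' @param denominator `"valid"` (count of valid samples, default) or
#'   `"total"` (all samples).
#' @return Recording time in hours.
#' @export
valid_recording_hours <- function(trace, denominator = c("valid", "total")) {
  stopifnot(inherits(trace, "spo2_trace"))
  denominator <- match.arg(denominator)
  n <- if (denominator == "valid") sum(trace$valid) else length(trace)
  if (n == 0) stop("no valid samples in trace", call. = FALSE)
  n / 3600
}

#' Exclusion rules for cohort assembly
#'
#' @param min_trt_h minimum total recording time (hours) to keep a record.
#' @param min_tst_h minimum total sleep time (hours) to keep a record.
#' @param age_range admissible age range in years (inclusive).
#' @param flag_tst_h records with TST below this many hours stay in the
#'   primary dataset but are flagged out of the restricted dataset.
#' @return An object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(min_trt_h = 3, min_tst_h = 1,
                            age_range = c(20, 85), flag_tst_h = 4) {
  structure(list(min_trt_h = min_trt_h, min_tst_h = min_tst_h,
                 age_range = age_range, flag_tst_h = flag_tst_h),
            class = "exclusion_rules")
}

#' Apply the study exclusion cascade
#'
#' Removes records with insufficient recording time, insufficient sleep, or
#' age outside the admissible range; each exclusion is labelled with the
#' first matching reason, tested in that order (`"trt_lt_3h"`, `"tst_lt_1h"`,
#' `"age"`). Kept records additionally receive a logical `tst_ge_4h` column
#' marking membership in the restricted (sufficient-sleep) dataset; this is a
#' flag, not a removal, so both analysis datasets derive from one pass.
#'
#' @param cohort data.frame with at least `trt_min`, `tst_min`, `age`.
#' @param rules an [exclusion_rules()].
#' @return A list with elements `kept` (with `tst_ge_4h` added) and
#'   `excluded` (with a `reason` column).
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  stopifnot(is.data.frame(cohort),
            all(c("trt_min", "tst_min", "age") %in% names(cohort)))
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(reason) & cohort$trt_min < rules$min_trt_h * 60] <- "trt_lt_3h"
  reason[is.na(reason) & cohort$tst_min < rules$min_tst_h * 60] <- "tst_lt_1h"
  reason[is.na(reason) &
           (cohort$age < rules$age_range[1] | cohort$age > rules$age_range[2])] <- "age"
  kept <- cohort[is.na(reason), , drop = FALSE]
  excluded <- cohort[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  kept$tst_ge_4h <- kept$tst_min >= rules$flag_tst_h * 60
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Summarize sleep-architecture quantities of one recording
#'
#' @param trt_min total recording time, minutes.
#' @param tst_min total sleep time, minutes (<= `trt_min`).
#' @param latency_min sleep latency, minutes.
#' @param arousal_count number of scored arousals.
#' @return A one-row data.frame adding `sleep_efficiency` (TST/TRT) and
#'   `arousal_index` (arousals per hour of sleep).
#' @export
sleep_summary <- function(trt_min, tst_min, latency_min = NA_real_,
                          arousal_count = NA_integer_) {
  if (any(tst_min < 0) || any(trt_min <= 0) || any(tst_min > trt_min)) {
    stop("need 0 <= tst_min <= trt_min and trt_min > 0", call. = FALSE)
  }
  data.frame(trt_min = trt_min, tst_min = tst_min, latency_min = latency_min,
             arousal_count = arousal_count,
             arousal_index = arousal_count / (tst_min / 60),
             sleep_efficiency = tst_min / trt_min)
}
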