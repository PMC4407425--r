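#' Reference tables from a 616-patient clinical validation cohort
#'
#' Summary-level results of a large sleep-center validation cohort (616
#' patients referred for suspected OSA; 540 after restricting to total sleep
#' time of at least 4 h), used as worked-example inputs for the evaluation
#' functions and as the calibration targets of the synthetic-cohort
#' generator. Available tables:
#'
#' * `confusion_616`, `confusion_540` -- four-class confusion matrices of
#'   the cross-validated two-index SVM classifier on the full and the
#'   sufficient-sleep dataset (true classes in rows).
#' * `gender_by_severity` -- 2 x 4 contingency counts of sex by severity.
#' * `tst_by_severity` -- 2 x 4 counts of the TST < 4 h / TST >= 4 h split
#'   by severity.
#' * `group_summaries` -- per-severity-group n / mean / SD for the
#'   demographic, questionnaire and oximetry variables.
#' * `cutoffs` -- ROC-optimal single-index cutoffs (events/h) per screening
#'   task and dataset.
#'
#' The off-diagonal cells of the normal row of `confusion_616` are
#' reconstructed from the published row total, row sensitivity and the
#' reported normal-to-moderate-or-severe misclassification rate; every cell
#' entering a validation check is an exactly published count.
#'
#' @param name which table to return.
#' @return The requested table (matrix or data.frame).
#' @export
#' @examples
#' confusion_metrics(osa_reference_tables("confusion_540"))$overall_accuracy
osa_reference_tables <- function(name = c("confusion_616", "confusion_540",
                                          "gender_by_severity",
                                          "tst_by_severity",
                                          "group_summaries", "cutoffs")) {
  name <- match.arg(name)
  sev <- severity_levels()
  cm <- function(rows) matrix(rows, nrow = 4, byrow = TRUE,
                              dimnames = list(true = sev, pred = sev))
  switch(name,
    confusion_616 = cm(c(53, 18,  1,   0,
                         25, 80, 20,   2,
                          3, 48, 55,  26,
                          1, 11, 22, 251)),
    confusion_540 = cm(c(51, 17,  0,   0,
                         21, 85, 14,   1,
                          3, 39, 53,  19,
                          0, 10, 19, 208)),
    gender_by_severity = matrix(c(32, 49, 31, 29,
                                  40, 78, 101, 256), nrow = 2, byrow = TRUE,
                                dimnames = list(sex = c("female", "male"),
                                                severity = sev)),
    tst_by_severity = matrix(c(4, 6, 18, 48,
                               68, 121, 114, 237), nrow = 2, byrow = TRUE,
                             dimnames = list(tst = c("lt_4h", "ge_4h"),
                                             severity = sev)),
    group_summaries = {
      gp <- default_group_params()
      odi <- rbind(
        data.frame(variable = "odi2", group = sev,
                   mean = c(10.25, 19.81, 29.60, 56.11),
                   sd = c(7.18, 10.57, 12.31, 18.94)),
        data.frame(variable = "odi3", group = sev,
                   mean = c(3.10, 8.18, 15.54, 44.92),
                   sd = c(2.78, 6.02, 8.87, 22.37)),
        data.frame(variable = "odi4t", group = sev,
                   mean = c(1.28, 4.18, 9.52, 37.58),
                   sd = c(1.43, 3.80, 7.01, 23.66)),
        data.frame(variable = "odi4a", group = sev,
                   mean = c(1.14, 5.20, 12.01, 45.10),
                   sd = c(1.41, 3.94, 7.62, 24.97))
      )
      out <- rbind(gp[gp$variable != "ahi", ], odi)
      out$n <- rep(c(72, 127, 132, 285), nrow(out) / 4)
      rownames(out) <- NULL
      out
    },
    cutoffs = data.frame(
      task = rep(c("severe", "mod_severe"), each = 8),
      dataset = rep(rep(c("d616", "d540"), each = 4), 2),
      feature = rep(c("odi2", "odi3", "odi4t", "odi4a"), 4),
      cutoff = c(27.2, 18.4, 11.2, 13.7,
                 27.2, 18.4, 10.4, 13.7,
                 21.2, 9.5, 7.3, 8.5,
                 21.2, 9.5, 7.3, 7.3),
      stringsAsFactors = FALSE
    )
  )
}

#' Write the worked-example fixtures used by the test suite
#'
#' Writes, as small plain CSV files: the two reference confusion matrices,
#' the sex-by-severity and TST-by-severity contingency tables, the
#' per-group summary statistics, and three 10-minute toy SpO2 traces
#' (flat; one planted desaturation; artifact-laden with two spikes and one
#' dropout).
#'
#' @param out_dir directory to write into (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(x, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (nm in c("confusion_616", "confusion_540", "gender_by_severity",
               "tst_by_severity", "group_summaries", "cutoffs")) {
    w(osa_reference_tables(nm), paste0(nm, ".csv"))
  }
  quiet <- oximeter_model(noise_sd = 0, artifact_spike_rate = 0,
                          dropout_rate = 0)
  flat <- synthesize_trace(plant_events(0, 1, seed = 1), 600,
                           model = quiet, seed = 11, resting_pct = 96)
  one <- synthesize_trace(
    data.frame(onset_s = 300, duration_s = 20, depth_pct = 6, kind = "apnea"),
    600, model = quiet, seed = 12, resting_pct = 96)
  laden <- flat
  x <- laden$spo2_pct
  x[c(120, 350)] <- x[c(120, 350)] - 8  # two motion spikes
  x[480] <- 42                          # one probe dropout
  laden <- spo2_trace(x, pulse_bpm = laden$pulse_bpm)
  w(flat, "trace_flat.csv")
  w(one, "trace_single_event.csv")
  w(laden, "trace_artifacts.csv")
  invisible(paths)
}
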