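#' Pipeline configuration
#'
#' Bundles every stage's parameters plus the single global seed that drives
#' all randomness; a configuration without a seed is rejected so no run is
#' silently nondeterministic.
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_spec()] (its own seed is overridden by `seed`).
#' @param oximeter an [oximeter_model()].
#' @param svm an [svm_spec()] template (its seed is overridden by `seed`).
#' @param tasks subset of `c("severe", "mod_severe", "fourclass")`.
#' @param odi_min_duration_s minimum desaturation-event duration, seconds.
#' @param seed integer global seed (required).
#' @param write_traces if `TRUE`, write every per-patient trace CSV (large).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_spec(),
                            oximeter = oximeter_model(), svm = svm_spec(),
                            tasks = c("severe", "mod_severe", "fourclass"),
                            odi_min_duration_s = 3, seed = NULL,
                            write_traces = FALSE) {
  if (is.null(seed)) stop("pipeline_config requires an explicit seed", call. = FALSE)
  tasks <- match.arg(tasks, several.ok = TRUE)
  cohort$seed <- as.integer(seed)
  svm$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, cohort = cohort, oximeter = oximeter,
                 svm = svm, tasks = tasks,
                 odi_min_duration_s = odi_min_duration_s,
                 seed = as.integer(seed), write_traces = write_traces),
            class = "pipeline_config")
}

#' Run the full screening-validation pipeline
#'
#' Executes simulate -> preprocess -> desaturation indices -> classify ->
#' evaluate, writing each stage's table as CSV plus a JSON report and a
#' manifest recording seeds and row counts. Identical configuration and seed
#' give byte-identical outputs.
#'
#' Stages: (1) generate the cohort and each patient's overnight trace;
#' (2) apply artifact elimination and the exclusion cascade (recording time,
#' sleep time, age), flagging the sufficient-sleep subset; (3) compute ODI2,
#' ODI3, ODI4T, ODI4A per patient; (4) for each requested task fit the
#' cross-validated SVM on the standard two-index feature pair and, for the
#' binary tasks, ROC-optimal single-index cutoffs; (5) assemble accuracy /
#' sensitivity / specificity / AUC blocks and agreement statistics.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the cohort table, ODI table, per-task
#'   results, the report list, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("odiscreen")),
                   seed = config$seed, stages = list())
  note <- function(stage, rows, file) {
    manifest$stages[[stage]] <<- list(rows = rows, file = file)
    message(sprintf("[%s] %d rows -> %s", stage, rows, file))
  }

  # -- simulate ---------------------------------------------------------
  cohort <- generate_cohort(config$cohort)
  cohort_file <- file.path(config$out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_file, row.names = FALSE)
  note("simulate", nrow(cohort), "cohort.csv")

  # -- preprocess + odi -------------------------------------------------
  excl <- apply_exclusions(cohort)
  kept <- excl$kept
  odi_rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    sim <- simulate_patient_trace(kept[i, ], config$oximeter)
    tr <- remove_artifacts(sim$trace)
    if (config$write_traces) {
      write_trace_csv(tr, file.path(config$out_dir,
                                    paste0("trace_", kept$patient_id[i], ".csv")))
    }
    res <- compute_odi(tr, min_duration_s = config$odi_min_duration_s)
    odi_rows[[i]] <- data.frame(
      patient_id = kept$patient_id[i],
      odi2 = res$odi2, odi3 = res$odi3, odi4t = res$odi4t, odi4a = res$odi4a,
      valid_hours = res$valid_hours,
      n_events_odi2 = res$n_events[["odi2"]],
      n_events_odi3 = res$n_events[["odi3"]],
      n_events_odi4t = res$n_events[["odi4t"]],
      n_events_odi4a = res$n_events[["odi4a"]])
  }
  odi <- do.call(rbind, odi_rows)
  odi_file <- file.path(config$out_dir, "odi.csv")
  utils::write.csv(odi, odi_file, row.names = FALSE)
  note("odi", nrow(odi), "odi.csv")

  data <- merge(kept, odi, by = "patient_id", sort = TRUE)
  data <- data[order(data$patient_id), ]

  # -- classify + evaluate ----------------------------------------------
  report <- list(seed = config$seed, n = nrow(data))
  results <- list()
  for (task in config$tasks) {
    if (task == "fourclass") {
      y <- factor(data$severity, levels = severity_levels())
      fit <- svm_multiclass(data, y, config$svm)
    } else {
      y <- task_labels(data$severity, task)
      fit <- svm_crossval(data, y, config$svm)
    }
    utils::write.csv(fit$predictions,
                     file.path(config$out_dir,
                               paste0("predictions_", task, ".csv")),
                     row.names = FALSE)
    note(paste0("classify_", task), nrow(fit$predictions),
         paste0("predictions_", task, ".csv"))
    block <- list(
      accuracy = fit$metrics$overall_accuracy,
      sensitivity = as.list(fit$metrics$sensitivity),
      specificity = fit$metrics$specificity,
      auc = fit$auc)
    if (task != "fourclass") {
      cuts <- lapply(c("odi2", "odi3", "odi4t", "odi4a"), function(v) {
        opt <- optimize_cutoff(data[[v]], y, feature = v, task = task)
        list(feature = v, cutoff = opt$rule$cutoff,
             sensitivity = opt$sensitivity, specificity = opt$specificity,
             auc = opt$roc$auc)
      })
      names(cuts) <- c("odi2", "odi3", "odi4t", "odi4a")
      block$single_variable_cutoffs <- cuts
    }
    report[[task]] <- block
    results[[task]] <- fit
  }

  # agreement of the calibrated 4%-all-night index with the reference AHI
  cal <- linear_calibrate(data$odi4a, data$ahi)
  ba <- bland_altman(data$ahi, cal$fitted)
  report$agreement_odi4a <- list(r_squared = cal$r_squared,
                                 bias = ba$bias, loa = ba$loa_high)

  report_file <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note("evaluate", length(report), "report.json")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, excluded = excl$excluded, odi = odi,
                 results = results, report = report, manifest = manifest))
}
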