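#' Binary diagnostic label for a screening task
#'
#' The two screening tasks are `"severe"` (positive when AHI >= 30) and
#' `"mod_severe"` (positive when AHI >= 15, i.e. moderate or severe disease).
#'
#' @param severity factor or character vector of severity classes, or
#'   `NULL` when `ahi` is given.
#' @param task `"severe"` or `"mod_severe"`.
#' @param ahi optional numeric AHI vector used instead of `severity`.
#' @return Factor with levels `c("negative", "positive")`.
#' @export
task_labels <- function(severity = NULL, task = c("severe", "mod_severe"),
                        ahi = NULL) {
  task <- match.arg(task)
  if (is.null(severity)) severity <- classify_severity(ahi)
  pos_classes <- if (task == "severe") "severe" else c("moderate", "severe")
  factor(ifelse(as.character(severity) %in% pos_classes, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Fixed-cutoff diagnostic rule
#'
#' @param feature name of the index the rule thresholds (e.g. `"odi3"`).
#' @param cutoff decision threshold in events/h (> 0); a patient is called
#'   positive when the feature value is at or above the cutoff.
#' @param task which diagnosis the rule makes (`"severe"` or `"mod_severe"`).
#' @return An object of class `cutoff_rule`.
#' @export
cutoff_rule <- function(feature, cutoff, task = c("severe", "mod_severe")) {
  task <- match.arg(task)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(feature = feature, cutoff = cutoff, task = task),
            class = "cutoff_rule")
}

#' Apply a cutoff rule to a feature table
#'
#' @param features data.frame with a `patient_id` column (optional) and the
#'   rule's feature column.
#' @param rule a [cutoff_rule()].
#' @param truth optional true labels (factor `negative`/`positive`) to carry
#'   into the prediction set.
#' @return A prediction data.frame with columns `patient_id`, `true`,
#'   `pred`, `score` (the raw feature value), `fold` (`NA`).
#' @export
#' @examples
#' f <- data.frame(odi3 = c(25, 10))
#' cutoff_predict(f, cutoff_rule("odi3", 18.4, "severe"))
cutoff_predict <- function(features, rule, truth = NULL) {
  stopifnot(inherits(rule, "cutoff_rule"))
  if (!rule$feature %in% names(features)) {
    stop(sprintf("feature '%s' missing from the feature table", rule$feature),
         call. = FALSE)
  }
  x <- features[[rule$feature]]
  if (anyNA(x)) {
    ids <- if ("patient_id" %in% names(features)) {
      features$patient_id[is.na(x)]
    } else which(is.na(x))
    stop(sprintf("feature '%s' missing for patients: %s", rule$feature,
                 paste(utils::head(ids, 10), collapse = ", ")), call. = FALSE)
  }
  data.frame(
    patient_id = if ("patient_id" %in% names(features)) features$patient_id
                 else seq_along(x),
    true = if (is.null(truth)) NA_character_ else as.character(truth),
    pred = ifelse(x >= rule$cutoff, "positive", "negative"),
    score = x,
    fold = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' ROC-optimal cutoff by Youden's J
#'
#' Sweeps every midpoint between adjacent sorted unique score values as a
#' candidate cutoff (positive when `score >= cutoff`) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the higher cutoff, i.e. toward higher specificity.
#'
#' @param scores numeric feature values.
#' @param labels binary labels (see [roc_auc()] for accepted forms).
#' @param feature,task stored into the returned rule for bookkeeping.
#' @return List with `rule` (a [cutoff_rule()]), `j`, `sensitivity`,
#'   `specificity` (percent), and `roc` (the [roc_auc()] curve).
#' @export
optimize_cutoff <- function(scores, labels, feature = "score",
                            task = c("severe", "mod_severe")) {
  task <- match.arg(task)
  y <- as_binary_labels(labels)
  if (all(y) || !any(y)) stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2) stop("scores are non-discriminative (all identical)", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- sum(y); neg <- sum(!y)
  sens <- vapply(cand, function(c) sum(scores >= c & y) / pos, 0)
  spec <- vapply(cand, function(c) sum(scores < c & !y) / neg, 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[length(best)]  # highest cutoff among ties -> higher specificity
  list(rule = cutoff_rule(feature, cand[pick], task),
       j = j[pick],
       sensitivity = 100 * sens[pick],
       specificity = 100 * spec[pick],
       roc = roc_auc(scores, labels))
}

#' SVM model specification
#'
#' @param features feature column names used by the model; the default pair
#'   is the 2-point moving-baseline index together with the 4-point
#'   all-night index, the combination with the best agreement with AHI.
#' @param kernel `"rbf"`, `"linear"`, or `"polynomial2"` (degree-2
#'   polynomial).
#' @param cost_grid,gamma_grid hyperparameter grids searched on each
#'   training fold (`gamma_grid` applies to the RBF and polynomial kernels).
#' @param cv_folds number of outer cross-validation folds.
#' @param inner_folds folds of the inner grid-search cross-validation.
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(features = c("odi2", "odi4a"),
                     kernel = c("rbf", "linear", "polynomial2"),
                     cost_grid = c(0.1, 1, 10, 100),
                     gamma_grid = c(0.01, 0.1, 1),
                     cv_folds = 10L, inner_folds = 3L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!length(features)) stop("features must be non-empty", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(features = features, kernel = kernel,
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "svm_spec")
}

#' Stratified cross-validation folds
#'
#' Assigns each observation to one of `k` folds so that every class is
#' spread as evenly as possible across folds; fold sizes differ by at most
#' one within each class. Deterministic given `(labels, seed)`.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  load <- integer(k)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # cycle through folds from least-loaded to most-loaded so the class's
      # remainder lands where it keeps overall fold sizes within one
      ord <- order(load, sample.int(k))
      f <- ord[(seq_along(idx) - 1L) %% k + 1L]
      fold[idx] <- f
      load <- load + tabulate(f, nbins = k)
    }
  })
  fold
}

svm_kernel_args <- function(spec, cost, gamma) {
  switch(spec$kernel,
         linear = list(kernel = "linear", cost = cost),
         polynomial2 = list(kernel = "polynomial", degree = 2, coef0 = 1,
                            cost = cost, gamma = gamma),
         rbf = list(kernel = "radial", cost = cost, gamma = gamma))
}

svm_grid <- function(spec) {
  if (spec$kernel == "linear") {
    data.frame(cost = spec$cost_grid, gamma = NA_real_)
  } else {
    expand.grid(cost = spec$cost_grid, gamma = spec$gamma_grid)
  }
}

fit_svm <- function(x, y, spec, cost, gamma) {
  args <- c(list(x = as.matrix(x), y = y, scale = FALSE, probability = FALSE),
            svm_kernel_args(spec, cost, gamma))
  do.call(e1071::svm, args)
}

# accuracy of a hyperparameter combination by inner CV on the training fold
inner_cv_accuracy <- function(x, y, spec, cost, gamma, inner_fold) {
  correct <- 0L
  for (f in seq_len(max(inner_fold))) {
    tr <- inner_fold != f
    if (length(unique(y[tr])) < length(levels(y))) return(NA_real_)
    m <- fit_svm(x[tr, , drop = FALSE], y[tr], spec, cost, gamma)
    p <- predict(m, as.matrix(x[!tr, , drop = FALSE]))
    correct <- correct + sum(p == y[!tr])
  }
  correct / length(y)
}

#' Cross-validated SVM diagnosis
#'
#' Stratified k-fold cross-validation of a support-vector-machine classifier:
#' within each outer fold the features are standardized by the training-fold
#' mean and SD, hyperparameters are selected by an inner grid-search
#' cross-validation on the training fold only, and the held-out fold is
#' predicted by the refit model. Out-of-fold predictions are pooled into a
#' single prediction set, so every patient is predicted exactly once by a
#' model that never saw it. Works for binary and multiclass label sets
#' (multiclass uses libsvm's one-vs-one voting over all pairwise machines).
#'
#' @param features data.frame containing `spec$features` columns (and
#'   optionally `patient_id`).
#' @param labels factor of true classes.
#' @param spec an [svm_spec()].
#' @return List of class `svm_cv`: `predictions` (data.frame `patient_id`,
#'   `true`, `pred`, `score`, `fold`), `metrics` (a [confusion_metrics()]
#'   report), `auc` (binary tasks; `NA` otherwise), `chosen` (per-fold
#'   hyperparameters).
#' @export
svm_crossval <- function(features, labels, spec = svm_spec()) {
  stopifnot(inherits(spec, "svm_spec"))
  labels <- droplevels(as.factor(labels))
  missing_feats <- setdiff(spec$features, names(features))
  if (length(missing_feats)) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_feats, collapse = ", ")), call. = FALSE)
  }
  x_all <- as.data.frame(features[, spec$features, drop = FALSE])
  if (anyNA(x_all)) stop("feature values must not contain NA", call. = FALSE)
  n <- nrow(x_all)
  if (min(table(labels)) < spec$cv_folds) {
    stop(sprintf(
      "smallest class has %d patients, fewer than %d folds; use fewer folds",
      min(table(labels)), spec$cv_folds), call. = FALSE)
  }
  fold <- make_folds(labels, spec$cv_folds, spec$seed)
  grid <- svm_grid(spec)
  binary <- nlevels(labels) == 2
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  score <- rep(NA_real_, n)
  chosen <- vector("list", spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < nlevels(labels)) {
      stop(sprintf("class absent from training fold %d; use fewer folds", f),
           call. = FALSE)
    }
    mu <- colMeans(x_all[tr, , drop = FALSE])
    sg <- vapply(x_all[tr, , drop = FALSE], stats::sd, 0)
    sg[sg == 0] <- 1
    xs <- sweep(sweep(x_all, 2, mu, "-"), 2, sg, "/")
    inner_fold <- make_folds(labels[tr], spec$inner_folds,
                             spec$seed + 1000L + f)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      inner_cv_accuracy(xs[tr, , drop = FALSE], labels[tr], spec,
                        grid$cost[g], grid$gamma[g], inner_fold)
    }, 0)
    g <- which.max(acc)  # first maximum: deterministic tie-break in grid order
    chosen[[f]] <- data.frame(fold = f, cost = grid$cost[g],
                              gamma = grid$gamma[g], inner_accuracy = acc[g])
    m <- fit_svm(xs[tr, , drop = FALSE], labels[tr], spec,
                 grid$cost[g], grid$gamma[g])
    te <- which(!tr)
    p <- predict(m, as.matrix(xs[te, , drop = FALSE]), decision.values = binary)
    pred[te] <- p
    if (binary) {
      dv <- attr(p, "decision.values")[, 1]
      # orient decision values so larger = second (positive) level
      flip <- strsplit(colnames(attr(p, "decision.values")), "/")[[1]][1] ==
        levels(labels)[2]
      score[te] <- if (flip) dv else -dv
    }
  }
  predictions <- data.frame(
    patient_id = if ("patient_id" %in% names(features)) features$patient_id
                 else seq_len(n),
    true = as.character(labels),
    pred = as.character(pred),
    score = score,
    fold = fold,
    stringsAsFactors = FALSE
  )
  cm <- confusion_matrix(labels, pred, levels = levels(labels))
  structure(
    list(predictions = predictions,
         metrics = confusion_metrics(cm),
         auc = if (binary) roc_auc(score, labels)$auc else NA_real_,
         chosen = do.call(rbind, chosen)),
    class = "svm_cv"
  )
}

#' Four-class severity SVM
#'
#' Cross-validated multiclass diagnosis of the four severity groups
#' (normal / mild / moderate / severe) by one-vs-one voting over the six
#' pairwise support-vector machines, evaluated with the same stratified
#' k-fold procedure as [svm_crossval()].
#'
#' @param features feature data.frame.
#' @param severity factor with the four severity levels.
#' @param spec an [svm_spec()].
#' @return As [svm_crossval()].
#' @export
svm_multiclass <- function(features, severity, spec = svm_spec()) {
  severity <- factor(as.character(severity), levels = severity_levels())
  if (any(is.na(severity))) stop("unknown severity label", call. = FALSE)
  if (nlevels(droplevels(severity)) < 4) {
    stop("all four severity classes must be present", call. = FALSE)
  }
  svm_crossval(features, severity, spec)
}

#' @export
print.svm_cv <- function(x, ...) {
  cat("<svm_cv> pooled out-of-fold predictions\n")
  print(x$metrics)
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}
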