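#' Confusion matrix from paired labels
#'
#' @param true,pred vectors of true and predicted class labels.
#' @param levels class levels, in order; defaults to the union of observed
#'   labels.
#' @return An integer matrix with true classes in rows and predicted classes
#'   in columns.
#' @export
confusion_matrix <- function(true, pred, levels = NULL) {
  if (is.null(levels)) levels <- union(unique(as.character(true)),
                                       unique(as.character(pred)))
  tab <- table(factor(true, levels = levels), factor(pred, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(true = levels, pred = levels))
  m
}

#' Accuracy, sensitivity and misclassification rates of a confusion matrix
#'
#' Overall accuracy is the diagonal sum over the total; the sensitivity of a
#' class is its diagonal count over its row sum (for a binary task the
#' specificity is the sensitivity of the negative class); the
#' misclassification matrix holds, in percent, the fraction of each true
#' class assigned to each other class.
#'
#' @param cm square counts matrix, true classes in rows (as from
#'   [confusion_matrix()]).
#' @return An object of class `metrics_report`: list with
#'   `overall_accuracy`, `sensitivity` (per class), `specificity` (binary
#'   matrices only; sensitivity of the first/negative class),
#'   `misclassification` (percent matrix) and `n`.
#' @export
#' @examples
#' cm <- matrix(c(50, 5, 10, 35), 2, byrow = TRUE,
#'              dimnames = list(c("neg", "pos"), c("neg", "pos")))
#' confusion_metrics(cm)
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  if (any(cm < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  rs <- rowSums(cm)
  sens <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(sens) <- rownames(cm)
  mis <- 100 * sweep(cm, 1, ifelse(rs > 0, rs, NA_real_), "/")
  structure(
    list(overall_accuracy = 100 * sum(diag(cm)) / total,
         sensitivity = sens,
         specificity = if (nrow(cm) == 2) unname(sens[1]) else NA_real_,
         misclassification = mis,
         n = total,
         counts = cm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, overall accuracy %.2f%%\n",
              x$n, x$overall_accuracy))
  for (cl in names(x$sensitivity)) {
    cat(sprintf("  sensitivity %-9s %6.2f%%\n", cl, x$sensitivity[cl]))
  }
  if (!is.na(x$specificity)) cat(sprintf("  specificity %14.2f%%\n", x$specificity))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps all unique score values as thresholds (predict positive when
#' `score >= threshold`), returns the (FPR, TPR) operating points, and
#' integrates the AUC by the trapezoidal rule. Tied scores are grouped, so
#' the trapezoidal AUC equals the Mann-Whitney concordance probability with
#' half credit for ties.
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels binary labels; logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `fpr`, `tpr` (each starting at 0 and ending at 1), and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  pos <- sum(y); neg <- sum(!y)
  if (pos == 0 || neg == 0) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # group tied scores: cumulative counts at the end of each tie block
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(yy)[last]
  fp <- cumsum(!yy)[last]
  tpr <- c(0, tp / pos)
  fpr <- c(0, fp / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

# coerce labels to logical with TRUE = positive class
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels", call. = FALSE)
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) > 2) stop("labels must be binary", call. = FALSE)
  labels == u[length(u)]
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between a reference measurement and an estimate by
#' the mean difference (bias) and the 95% limits of agreement (bias plus or
#' minus 1.96 sample SD of the differences).
#'
#' @param reference,estimate numeric vectors of equal length (>= 3).
#' @return An object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, and the per-pair `means` and `differences`
#'   (reference minus estimate).
#' @export
bland_altman <- function(reference, estimate) {
  if (length(reference) != length(estimate)) stop("length mismatch", call. = FALSE)
  if (length(reference) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- reference - estimate
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 means = (reference + estimate) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% limits of agreement [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Calibrate oximetry indices against the reference AHI
#'
#' Ordinary least-squares regression of the reference AHI on one or more
#' desaturation indices; the fitted values are the calibrated AHI estimates
#' whose agreement with the reference is then assessed by [bland_altman()]
#' (by construction the calibrated estimates have zero mean difference).
#'
#' @param predictors numeric vector, matrix or data.frame of index values.
#' @param response numeric vector of reference AHI values.
#' @return List with `coefficients` (intercept first), `r_squared`, `fitted`,
#'   and the underlying `lm` fit.
#' @export
linear_calibrate <- function(predictors, response) {
  X <- as.data.frame(predictors)
  if (nrow(X) != length(response)) stop("length mismatch", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1) stop("too few observations", call. = FALSE)
  fit <- stats::lm(response ~ ., data = cbind(X, response = response))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("collinear predictors: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  list(coefficients = coef(fit),
       r_squared = summary(fit)$r.squared,
       fitted = unname(stats::fitted(fit)),
       fit = fit)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson statistic without continuity correction, with
#' `df = (rows - 1)(cols - 1)` and the usual asymptotic p-value.
#'
#' @param table matrix of contingency counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' chi_square_test(rbind(c(10, 20), c(30, 15)))$statistic
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Computes the one-way ANOVA F statistic from per-group `(n, mean, sd)`
#' summaries: the between-group sum of squares from the means and the
#' within-group sum of squares from the (sample, n-1 denominator) SDs. On raw
#' data this reproduces `aov()` exactly, but it also applies to published
#' summary tables where the raw data are unavailable.
#'
#' @param groups data.frame with columns `n`, `mean`, `sd` (one row per
#'   group; every `n >= 2`, every `sd >= 0`).
#' @return List with `f`, `df1`, `df2`, `p_value`, `ms_within`, `grand_mean`.
#' @export
#' @examples
#' g <- data.frame(n = c(10, 10), mean = c(1, 2), sd = c(0.5, 0.6))
#' anova_from_summary(g)$f
anova_from_summary <- function(groups) {
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
  if (nrow(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(groups$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(groups$sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  k <- nrow(groups)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, df1 = df1, df2 = df2, p_value = p,
       ms_within = msw, grand_mean = grand)
}

#' Post-hoc pairwise comparisons from group summaries
#'
#' All pairwise mean comparisons computed from the same `(n, mean, sd)`
#' summaries as [anova_from_summary()]. Each significant pair is reported in
#' the ordering notation `"(i) < (j)"`, where group numbers follow the row
#' order of `groups`.
#'
#' The default method is Games-Howell (a Welch-type comparison using
#' per-group variances against the studentized-range distribution), chosen
#' because severity-graded clinical variables are strongly heteroscedastic
#' -- the severe group's SD is often an order of magnitude above the normal
#' group's -- and a pooled-variance criterion then loses real differences
#' between the low-variance groups. `method = "scheffe"` gives the
#' classical pooled-MSE Scheffe test.
#'
#' @param groups data.frame with columns `n`, `mean`, `sd`.
#' @param alpha familywise significance level.
#' @param method `"games_howell"` (default) or `"scheffe"`.
#' @return An object of class `posthoc_orderings`: data.frame with one row
#'   per pair (`i`, `j`, `diff`, `statistic`, `critical`, `significant`,
#'   `label`), plus attribute `ordering` collecting the significant pairs.
#' @export
posthoc_orderings <- function(groups, alpha = 0.05,
                              method = c("games_howell", "scheffe")) {
  method <- match.arg(method)
  a <- anova_from_summary(groups)
  k <- nrow(groups)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    diff <- groups$mean[j] - groups$mean[i]
    if (method == "scheffe") {
      stat <- diff^2 / (a$ms_within * (1 / groups$n[i] + 1 / groups$n[j]))
      crit <- (k - 1) * stats::qf(1 - alpha, k - 1, a$df2)
    } else {
      vi <- groups$sd[i]^2 / groups$n[i]
      vj <- groups$sd[j]^2 / groups$n[j]
      stat <- abs(diff) / sqrt((vi + vj) / 2)
      df <- (vi + vj)^2 /
        (vi^2 / (groups$n[i] - 1) + vj^2 / (groups$n[j] - 1))
      crit <- stats::qtukey(1 - alpha, k, df)
    }
    sig <- is.finite(stat) && stat > crit
    lab <- if (!sig) "" else if (diff > 0) {
      sprintf("(%d) < (%d)", i, j)
    } else sprintf("(%d) < (%d)", j, i)
    data.frame(i = i, j = j, diff = diff, statistic = stat,
               critical = crit, significant = sig, label = lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "ordering") <- out$label[out$significant]
  class(out) <- c("posthoc_orderings", "data.frame")
  out
}
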