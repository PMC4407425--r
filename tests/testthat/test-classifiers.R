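test_that("cutoff rules are inclusive at the boundary", {
  rule <- cutoff_rule("odi3", 18.4, "severe")
  got <- cutoff_predict(data.frame(odi3 = c(19.0, 18.4, 18.39)), rule)
  expect_equal(got$pred, c("positive", "positive", "negative"))

  rule2 <- cutoff_rule("odi4a", 8.5, "mod_severe")
  expect_equal(cutoff_predict(data.frame(odi4a = 7.0), rule2)$pred, "negative")
})

test_that("missing feature values are reported with patient ids", {
  f <- data.frame(patient_id = c("A", "B"), odi2 = c(10, NA))
  expect_error(cutoff_predict(f, cutoff_rule("odi2", 20)), "B")
  expect_error(cutoff_predict(f, cutoff_rule("odi9", 20)), "odi9")
})

test_that("reference cutoffs are shipped for both tasks and datasets", {
  cuts <- osa_reference_tables("cutoffs")
  expect_equal(nrow(cuts), 16)
  sev1 <- cuts[cuts$task == "severe" & cuts$dataset == "d616", "cutoff"]
  expect_equal(sev1, c(27.2, 18.4, 11.2, 13.7))
  mod1 <- cuts[cuts$task == "mod_severe" & cuts$dataset == "d616", "cutoff"]
  expect_equal(mod1, c(21.2, 9.5, 7.3, 8.5))
})

test_that("Youden-optimal cutoff separates separated classes perfectly", {
  opt <- optimize_cutoff(c(1, 2, 9, 10), c(0, 0, 1, 1))
  expect_equal(opt$rule$cutoff, 5.5)
  expect_equal(opt$j, 1)
  expect_error(optimize_cutoff(rep(3, 10), rep(0:1, 5)), "non-discriminative")
  expect_error(optimize_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("optimized cutoff matches the exhaustive-search oracle", {
  set.seed(41)
  for (i in 1:10) {
    scores <- round(c(rnorm(12, 10, 4), rnorm(8, 16, 4)), 1)
    labels <- rep(c(FALSE, TRUE), c(12, 8))
    opt <- optimize_cutoff(scores, labels)
    u <- sort(unique(scores))
    cand <- (u[-1] + u[-length(u)]) / 2
    j <- vapply(cand, function(cc) {
      mean(scores[labels] >= cc) + mean(scores[!labels] < cc) - 1
    }, 0)
    expect_equal(opt$j, max(j), tolerance = 1e-12)
    expect_equal(opt$rule$cutoff, max(cand[j >= max(j) - 1e-12]))
  }
})

test_that("the optimized cutoff reproduces its reported operating point", {
  set.seed(42)
  scores <- c(rnorm(30, 12, 5), rnorm(20, 25, 6))
  truth <- factor(rep(c("negative", "positive"), c(30, 20)),
                  levels = c("negative", "positive"))
  opt <- optimize_cutoff(scores, truth)
  pred <- cutoff_predict(data.frame(score = scores), opt$rule, truth = truth)
  cm <- confusion_matrix(pred$true, pred$pred, c("negative", "positive"))
  m <- confusion_metrics(cm)
  expect_equal(unname(m$sensitivity["positive"]), opt$sensitivity)
  expect_equal(m$specificity, opt$specificity)
})

test_that("raising a cutoff trades sensitivity for specificity monotonically", {
  set.seed(43)
  scores <- rnorm(80, 10, 4)
  labels <- runif(80) < plogis((scores - 10) / 2)
  grid <- sort(unique(scores))
  sens <- vapply(grid, function(cc) mean(scores[labels] >= cc), 0)
  spec <- vapply(grid, function(cc) mean(scores[!labels] < cc), 0)
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("stratified folds are balanced and a pure function of labels and seed", {
  labels <- rep(c("a", "b"), c(33, 17))
  f1 <- make_folds(labels, 10, seed = 5)
  f2 <- make_folds(labels, 10, seed = 5)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(labels, 10, seed = 6)))
  for (cl in c("a", "b")) {
    sizes <- table(f1[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_lte(max(table(f1)) - min(table(f1)), 1)
})

make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  data.frame(f1 = x[, 1], f2 = x[, 2],
             label = rep(rownames(centers), each = n_per))
}

test_that("a linearly separable problem is solved perfectly in cross-validation", {
  d <- make_blobs(25, rbind(negative = c(0, 0), positive = c(8, 8)), seed = 44)
  spec <- svm_spec(features = c("f1", "f2"), kernel = "linear",
                   cost_grid = c(0.1, 1, 10), cv_folds = 5, seed = 3)
  fit <- svm_crossval(d, factor(d$label, c("negative", "positive")), spec)
  expect_equal(fit$metrics$overall_accuracy, 100)
  expect_equal(fit$auc, 1)
  # every patient predicted exactly once, fold sizes within one
  expect_equal(sort(fit$predictions$patient_id), seq_len(50))
  expect_lte(diff(range(table(fit$predictions$fold))), 1)
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- make_blobs(20, rbind(negative = c(0, 0), positive = c(2, 2)),
                  sd = 1.5, seed = 45)
  spec <- svm_spec(features = c("f1", "f2"), kernel = "rbf",
                   cost_grid = c(1, 10), gamma_grid = c(0.1, 1),
                   cv_folds = 5, seed = 9)
  f1 <- svm_crossval(d, factor(d$label), spec)
  f2 <- svm_crossval(d, factor(d$label), spec)
  expect_identical(f1$predictions, f2$predictions)
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    d <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
    y <- factor(rep(c("negative", "positive"), 30)[sample.int(60)])
    spec <- svm_spec(features = c("f1", "f2"), kernel = "linear",
                     cost_grid = 1, cv_folds = 5, inner_folds = 2,
                     seed = s)
    svm_crossval(d, y, spec)$metrics$overall_accuracy / 100
  }, 0)
  se <- sqrt(0.5 * 0.5 / 60)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("too few patients per class for the fold count is an error", {
  d <- make_blobs(6, rbind(negative = c(0, 0), positive = c(4, 4)), seed = 46)
  spec <- svm_spec(features = c("f1", "f2"), cv_folds = 10)
  expect_error(svm_crossval(d, factor(d$label), spec), "fewer folds")
})

test_that("four well-separated clusters give a near-diagonal confusion matrix", {
  centers <- rbind(normal = c(0, 0), mild = c(6, 0),
                   moderate = c(0, 6), severe = c(6, 6))
  d <- make_blobs(15, centers, sd = 0.6, seed = 47)
  spec <- svm_spec(features = c("f1", "f2"), kernel = "rbf",
                   cost_grid = c(1, 10), gamma_grid = c(0.1, 1),
                   cv_folds = 5, seed = 2)
  fit <- svm_multiclass(d, factor(d$label, severity_levels()), spec)
  expect_gte(fit$metrics$overall_accuracy, 95)
  expect_true(is.na(fit$auc))
  expect_error(svm_multiclass(d[d$label != "mild", ],
                              factor(d$label[d$label != "mild"],
                                     severity_levels()), spec),
               "four severity classes")
})

test_that("the two-index SVM keeps pace with the best single-index cutoff", {
  spec <- cohort_spec(n_patients = 160, seed = 19)
  cohort <- simulate_odi_cohort(spec)
  y <- task_labels(cohort$severity, "severe")
  sspec <- svm_spec(features = c("odi2", "odi4a"), kernel = "rbf",
                    cv_folds = 5, seed = 19)
  fit <- svm_crossval(cohort, y, sspec)
  single <- vapply(c("odi2", "odi3", "odi4t", "odi4a"), function(v) {
    opt <- optimize_cutoff(cohort[[v]], y, feature = v)
    pred <- cutoff_predict(cohort, opt$rule, truth = y)
    confusion_metrics(confusion_matrix(pred$true, pred$pred,
                                       c("negative", "positive")))$overall_accuracy
  }, 0)
  expect_gte(fit$metrics$overall_accuracy, max(single) - 2)
})
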