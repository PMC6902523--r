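# Metrics, ROC/AUC, the cross-validation protocol, and the benchmark table.

test_that("confusion metrics match the standard definitions", {
  # TP=3, FN=1, TN=4, FP=0
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(y, p)
  expect_equal(cm[["TPR"]], 0.75)
  expect_equal(cm[["TNR"]], 1.0)
  expect_equal(cm[["ACC"]], 0.875)
  expect_equal(cm[["F1"]], 2 * 1 * 0.75 / 1.75, tolerance = 1e-12)

  expect_equal(unname(confusion_metrics(c(0, 1), c(0, 1))[1:4]),
               c(1, 1, 1, 1))

  # all-negative prediction on balanced labels
  cm2 <- confusion_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(cm2[["TPR"]], 0)
  expect_equal(cm2[["TNR"]], 1)
  expect_equal(cm2[["ACC"]], 0.5)
  expect_true(is.na(cm2[["F1"]]))          # undefined, not silently 0
  expect_match(attr(cm2, "reasons")[["F1"]], "zero")

  expect_error(confusion_metrics(c(0, 1), c(0)), "mismatch")
})

test_that("AUC equals the all-pairs comparison oracle", {
  ra <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(ra$auc, 0.75)

  expect_equal(roc_auc(c(0, 1), c(0, 1))$auc, 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))   # rounding forces ties
    expect_equal(roc_auc(y, s)$auc, bf_auc(y, s), tolerance = 1e-12)
  }
})

test_that("the ROC is a monotone step curve from (0,0) to (1,1)", {
  set.seed(24)
  y <- rbinom(60, 1, 0.5); s <- runif(60)
  roc <- roc_auc(y, s)$roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("accuracy is the prevalence-weighted mix of TPR and TNR", {
  set.seed(25)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    p <- rbinom(n, 1, 0.5)
    cm <- confusion_metrics(y, p)
    prev <- mean(y)
    expect_equal(cm[["ACC"]], prev * cm[["TPR"]] + (1 - prev) * cm[["TNR"]],
                 tolerance = 1e-12)
  }
})

test_that("stratified folds preserve the class ratio within one sample", {
  set.seed(26)
  y <- rep(c(1L, 0L), c(84, 168))
  fold <- vitalhf:::stratified_folds(y, 10)
  expect_equal(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_true(abs(sum(y == 1 & fold == f) - 8.4) <= 1)
    expect_true(abs(sum(y == 0 & fold == f) - 16.8) <= 1)
  }
  # folds partition the data
  expect_equal(length(fold), 252L)

  # 252 samples under the 80/20 + 10-fold scheme: folds of 20 or 21
  test_idx <- vitalhf:::stratified_split(y, 0.2)
  expect_equal(length(test_idx), round(0.2 * 84) + round(0.2 * 168))
  tr <- setdiff(seq_along(y), test_idx)
  expect_true(length(tr) %in% c(201L, 202L))
  fold2 <- vitalhf:::stratified_folds(y[tr], 10)
  expect_true(all(table(fold2) %in% 20:21))
})

test_that("run_cv is deterministic and reports per-fold and test metrics", {
  coh <- small_cohort(n_pos = 12, n_neg = 20, effect = 2, seed = 30,
                      duration_min = 60)
  sf <- correlation_filter(stat_feature_matrix(coh))
  y <- unname(cohort_labels(coh))
  cv <- cv_config(n_folds = 5, seed = 8)
  r1 <- run_cv(sf, y, classifiers = c("nb", "lr"), cv = cv)
  r2 <- run_cv(sf, y, classifiers = c("nb", "lr"), cv = cv)
  expect_identical(r1$table, r2$table)
  expect_equal(nrow(r1$table), 2L)
  expect_true(all(c("TPR", "TNR", "F1", "ACC", "AUC") %in% names(r1$table)))
  expect_equal(nrow(r1$fold_metrics$nb), 5L)
  expect_true(all(r1$table$AUC >= 0 & r1$table$AUC <= 1))

  expect_error(run_cv(sf, y, classifiers = "nb",
                      cv = cv_config(n_folds = 20)), "fewer folds")
})

test_that("the end-to-end benchmark emits 8 + 8 + 1 representation rows", {
  coh <- small_cohort(n_pos = 10, n_neg = 20, effect = 2, seed = 33,
                      duration_min = 60)
  bm <- benchmark_all(coh, cv = cv_config(n_folds = 5, seed = 4),
                      cnn_epochs = 3)
  tab <- bm$table
  expect_equal(sum(tab$representation == "statistical"), 8L)
  expect_equal(sum(tab$representation == "text"), 8L)
  expect_equal(sum(tab$representation == "image"), 1L)
  expect_true(all(tab$AUC >= 0 & tab$AUC <= 1))
  expect_s3_class(bm$cnn, "cnn_model")
  # the signal is recovered by the best classifier of each representation
  best <- tapply(tab$AUC, tab$representation, max)
  expect_true(all(best[c("statistical", "text")] > 0.5))
})
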