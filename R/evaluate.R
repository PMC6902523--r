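# Cross-validation protocol, confusion metrics, ROC/AUC, and the end-to-end
# benchmark that produces the representation x classifier results table.

#' Confusion-matrix metrics at the 0.5 probability threshold
#'
#' Sensitivity (TPR), specificity (TNR), F1 and accuracy.  A metric whose
#' denominator is zero is returned as `NA` with the reason in the `reasons`
#' attribute, never silently coerced to 0.
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 predictions.
#' @return named numeric vector `c(TPR, TNR, F1, ACC)`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  reasons <- character(0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else {
    reasons["TPR"] <- "no positive cases"; NA_real_ }
  tnr <- if (tn + fp > 0) tn / (tn + fp) else {
    reasons["TNR"] <- "no negative cases"; NA_real_ }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(tpr) && (prec + tpr) > 0)
    2 * prec * tpr / (prec + tpr)
  else { reasons["F1"] <- "precision + recall is zero or undefined"
    NA_real_ }
  acc <- (tp + tn) / length(y_true)
  out <- c(TPR = tpr, TNR = tnr, F1 = f1, ACC = acc)
  attr(out, "reasons") <- reasons
  out
}

#' ROC curve and AUC
#'
#' The ROC is the monotone step curve swept over score thresholds from high
#' to low (tied scores move diagonally); the AUC is its trapezoidal area,
#' equal to the probability that a random positive outscores a random
#' negative with ties counted one half.
#'
#' @param y_true 0/1 labels with both classes present.
#' @param y_score real-valued scores (higher = more positive).
#' @return list with `roc` (data.frame `fpr`, `tpr` from (0,0) to (1,1)) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(y_score)) stop("length mismatch")
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(y_score, decreasing = TRUE)
  ys <- y_true[o]; ss <- y_score[o]
  # collapse tied scores into single sweep steps
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[last_of_tie]
  fp <- cumsum(1 - ys)[last_of_tie]
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Cross-validation configuration
#'
#' The study protocol: a stratified 80/20 train/test split, then 10-fold
#' stratified cross-validation inside the training portion (9:1
#' train:validation per fold); the final model is refit on the full training
#' portion and scored once on the held-out 20%.
#'
#' @param test_fraction held-out fraction (default 0.2).
#' @param n_folds folds within the training portion (default 10).
#' @param threshold probability threshold for the confusion metrics
#'   (default 0.5).
#' @param seed RNG seed for the splits and the classifiers.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(test_fraction = 0.2, n_folds = 10L, threshold = 0.5,
                      seed = 1L) {
  structure(list(test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 threshold = threshold, seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified fold ids in 1..k; class ratio per fold within +-1 sample, and
# the fold-assignment cycle continues across classes so overall fold sizes
# also differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  offset <- 0L
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

# Stratified test-split indices.
stratified_split <- function(y, test_fraction) {
  test <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(test_fraction * length(idx)))
  }))
  sort(test)
}

#' Run the cross-validation protocol over a feature matrix
#'
#' @param features numeric matrix / data.frame (rows = patients).
#' @param labels 0/1 vector aligned with rows.
#' @param classifiers classifier names (see [hf_classifier()]).
#' @param cv a [cv_config()].
#' @param test_idx optional fixed test-row indices (to share one split
#'   across representations); default drawn from `cv$seed`.
#' @return an object of class `eval_report`: `table` (one row per classifier:
#'   TPR/TNR/F1/ACC/AUC on the held-out test split), `fold_metrics`
#'   (per-classifier data.frame of per-fold validation metrics), `roc`
#'   (named list of ROC curves) and the configuration.
#' @export
run_cv <- function(features, labels, classifiers = CLASSIFIER_NAMES,
                   cv = cv_config(), test_idx = NULL) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(x) == length(y))
  if (min(table(y)) < cv$n_folds)
    stop("smallest class has fewer samples than folds; use fewer folds")
  set.seed(cv$seed)
  if (is.null(test_idx)) test_idx <- stratified_split(y, cv$test_fraction)
  train_idx <- setdiff(seq_len(nrow(x)), test_idx)
  fold <- stratified_folds(y[train_idx], cv$n_folds)
  tab <- NULL
  fold_metrics <- list(); rocs <- list()
  for (m in classifiers) {
    fm <- NULL
    for (f in seq_len(cv$n_folds)) {
      tr <- train_idx[fold != f]; va <- train_idx[fold == f]
      fitf <- hf_classifier(x[tr, , drop = FALSE], y[tr], m,
                            seed = cv$seed + f)
      pv <- predict(fitf, x[va, , drop = FALSE])
      cm <- confusion_metrics(y[va], as.integer(pv >= cv$threshold))
      aucv <- if (length(unique(y[va])) == 2L) roc_auc(y[va], pv)$auc
      else NA_real_
      fm <- rbind(fm, data.frame(fold = f, TPR = cm["TPR"], TNR = cm["TNR"],
                                 F1 = cm["F1"], ACC = cm["ACC"], AUC = aucv,
                                 row.names = NULL))
    }
    fold_metrics[[m]] <- fm
    fit <- hf_classifier(x[train_idx, , drop = FALSE], y[train_idx], m,
                         seed = cv$seed)
    pt <- predict(fit, x[test_idx, , drop = FALSE])
    cm <- confusion_metrics(y[test_idx], as.integer(pt >= cv$threshold))
    ra <- roc_auc(y[test_idx], pt)
    rocs[[m]] <- ra$roc
    tab <- rbind(tab, data.frame(method = m, TPR = cm["TPR"],
                                 TNR = cm["TNR"], F1 = cm["F1"],
                                 ACC = cm["ACC"], AUC = ra$auc,
                                 row.names = NULL))
  }
  structure(list(table = tab, fold_metrics = fold_metrics, roc = rocs,
                 cv = cv, test_idx = test_idx, n = nrow(x)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("<eval_report> held-out test metrics\n")
  print(cbind(x$table[1], round(x$table[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' End-to-end benchmark of the three representations
#'
#' Runs the statistical, text and image pipelines on one cohort with a shared
#' stratified 80/20 split: the statistical and text feature matrices go
#' through [run_cv()] with the full classifier suite, the grid tensors are
#' classified by the CNN trained on the shared training portion.  The
#' returned table is the representation-by-classifier analogue of the study's
#' results table (8 statistical rows, 8 text rows, 1 image row).
#'
#' @param cohort a `vital_cohort`.
#' @param classifiers classifier set for the tabular representations.
#' @param cv a [cv_config()].
#' @param k LDA topic count (default 5).
#' @param m,n grid dimensions (default 16).
#' @param cnn_epochs CNN epoch cap (default 50).
#' @param lda_seed seed for the LDA fit (default `cv$seed`).
#' @return object of class `benchmark_report`: `table` with a
#'   `representation` column, per-representation `reports`, the CNN model
#'   (training-curve history inside), and provenance `config`.
#' @export
benchmark_all <- function(cohort, classifiers = CLASSIFIER_NAMES,
                          cv = cv_config(), k = 5L, m = 16L, n = 16L,
                          cnn_epochs = 50L, lda_seed = cv$seed) {
  coh <- complete_records(cohort, quiet = TRUE)
  y <- unname(cohort_labels(coh))
  set.seed(cv$seed)
  test_idx <- stratified_split(y, cv$test_fraction)
  train_idx <- setdiff(seq_along(y), test_idx)

  sf <- correlation_filter(stat_feature_matrix(coh))
  rep_stat <- run_cv(sf, y, classifiers, cv, test_idx = test_idx)

  corpus <- build_corpus(coh)
  topics <- topic_feature_matrix(corpus, k = k, seed = lda_seed)
  rep_text <- run_cv(topics, y, classifiers, cv, test_idx = test_idx)

  tensors <- grid_tensor_cohort(coh, m = m, n = n)
  spec <- cnn_spec(epochs = cnn_epochs, seed = cv$seed)
  cnn <- train_cnn(tensors[train_idx, , , , drop = FALSE], y[train_idx],
                   spec)
  pt <- predict(cnn, tensors[test_idx, , , , drop = FALSE])
  cm <- confusion_metrics(y[test_idx], as.integer(pt >= cv$threshold))
  ra <- roc_auc(y[test_idx], pt)
  img_tab <- data.frame(method = "grcnn", TPR = cm["TPR"], TNR = cm["TNR"],
                        F1 = cm["F1"], ACC = cm["ACC"], AUC = ra$auc,
                        row.names = NULL)

  tab <- rbind(cbind(representation = "statistical", rep_stat$table),
               cbind(representation = "text", rep_text$table),
               cbind(representation = "image", img_tab))
  structure(list(table = tab,
                 reports = list(statistical = rep_stat, text = rep_text),
                 image_roc = ra$roc, cnn = cnn,
                 config = list(cv = unclass(cv), k = k, m = m, n = n,
                               cnn_epochs = cnn_epochs,
                               classifiers = classifiers)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  cat("<benchmark_report>\n")
  print(cbind(x$table[1:2], round(x$table[-(1:2)], digits)),
        row.names = FALSE)
  invisible(x)
}
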