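# The package's front door: fit a heart-failure risk model on a cohort under
# one of the three representations, returning a classed object with the
# usual print/summary/predict/residuals methods.

#' Fit a perioperative heart-failure risk model
#'
#' Trains one representation pipeline end-to-end on a labeled cohort:
#' * `"statistical"`: 90 moment/quantile features per patient,
#'   correlation-filtered, then the chosen classifier (default `"gbdt"`,
#'   the study's best performer on this representation);
#' * `"text"`: PAA + SAX + rule-engine phrases, LDA topic proportions
#'   (k = 5), then the chosen classifier (default `"nb"`);
#' * `"image"`: per-channel grid tensors classified by the compact CNN
#'   (`classifier` is ignored).
#'
#' @param cohort a `vital_cohort` of complete records.
#' @param representation `"statistical"`, `"text"` or `"image"`.
#' @param classifier classifier name for the tabular representations.
#' @param k LDA topic count (text representation).
#' @param m,n grid dimensions (image representation).
#' @param cnn CNN settings, a [cnn_spec()] (image representation).
#' @param seed RNG seed.
#' @param ... passed to [hf_classifier()] as `params`.
#' @return an object of class `hf_model`.
#' @export
hf_fit <- function(cohort, representation = c("statistical", "text", "image"),
                   classifier = NULL, k = 5L, m = 16L, n = 16L,
                   cnn = cnn_spec(), seed = 1L, ...) {
  representation <- match.arg(representation)
  coh <- complete_records(cohort, quiet = TRUE)
  y <- unname(cohort_labels(coh))
  fit <- switch(
    representation,
    statistical = {
      classifier <- classifier %||% "gbdt"
      feats <- correlation_filter(stat_feature_matrix(coh))
      clf <- hf_classifier(feats, y, classifier, params = list(...),
                           seed = seed)
      list(classifier = clf, features = colnames(feats),
           dropped = attr(feats, "dropped"), x = feats)
    },
    text = {
      classifier <- classifier %||% "nb"
      corpus <- build_corpus(coh)
      topics <- topic_feature_matrix(corpus, k = k, seed = seed)
      clf <- hf_classifier(topics, y, classifier, params = list(...),
                           seed = seed)
      list(classifier = clf, lda = attr(topics, "model"), x = topics)
    },
    image = {
      classifier <- "grcnn"
      tensors <- grid_tensor_cohort(coh, m = m, n = n)
      cnn$seed <- seed
      list(cnn = train_cnn(tensors, y, cnn), m = m, n = n)
    })
  structure(c(fit, list(representation = representation,
                        classifier_name = classifier, y = y,
                        patient_ids = names(cohort_labels(coh)),
                        seed = seed)),
            class = "hf_model")
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("<hf_model> %s representation, %s classifier, %d patients\n",
              x$representation, x$classifier_name, length(x$y)))
  invisible(x)
}

#' @export
summary.hf_model <- function(object, ...) {
  p <- fitted_probs(object)
  cm <- confusion_metrics(object$y, as.integer(p >= 0.5))
  auc <- roc_auc(object$y, p)$auc
  cat(sprintf("Heart-failure risk model (%s / %s)\n",
              object$representation, object$classifier_name))
  cat(sprintf("  %d patients (%d positive)\n", length(object$y),
              sum(object$y == 1)))
  if (object$representation == "statistical")
    cat(sprintf("  %d features after correlation filter (%d dropped)\n",
                length(object$features), length(object$dropped)))
  if (object$representation == "text")
    cat(sprintf("  %d topics over a %d-phrase vocabulary\n",
                object$lda$k, length(object$lda$vocab)))
  if (object$representation == "image")
    cat(sprintf("  CNN trained %d epochs (best %d)\n",
                nrow(object$cnn$history), object$cnn$best_epoch))
  cat(sprintf("  in-sample: TPR %.3f TNR %.3f ACC %.3f AUC %.3f\n",
              cm["TPR"], cm["TNR"], cm["ACC"], auc))
  invisible(object)
}

fitted_probs <- function(object, cohort = NULL) {
  if (is.null(cohort)) {
    if (object$representation == "image") {
      # recompute from stored weights is cheap only with tensors; refuse
      stop("in-sample image probabilities require the cohort; ",
           "call predict(model, cohort)")
    }
    return(predict(object$classifier, object$x))
  }
  predict(object, cohort)
}

#' Predict heart-failure probabilities for a cohort
#'
#' Applies the fitted representation pipeline to new patients: statistical
#' features are restricted to the filtered training columns; text documents
#' are folded into the trained topic model via [infer_topics()]; grid
#' tensors go through the trained CNN.
#'
#' @param object an `hf_model`.
#' @param newdata a `vital_cohort`.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @return named numeric vector (patient ids).
#' @export
predict.hf_model <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  coh <- complete_records(newdata, quiet = TRUE)
  ids <- names(cohort_labels(coh))
  p <- switch(
    object$representation,
    statistical = {
      feats <- stat_feature_matrix(coh)[, object$features, drop = FALSE]
      predict(object$classifier, feats)
    },
    text = {
      corpus <- build_corpus(coh)
      th <- t(vapply(corpus, function(d)
        infer_topics(object$lda, d, seed = object$seed),
        numeric(object$lda$k)))
      predict(object$classifier, th)
    },
    image = {
      tensors <- grid_tensor_cohort(coh, m = object$m, n = object$n)
      predict(object$cnn, tensors)
    })
  names(p) <- ids
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
residuals.hf_model <- function(object, cohort = NULL, ...) {
  object$y - fitted_probs(object, cohort)
}

#' Diagnostic plot for a fitted heart-failure risk model
#'
#' For the image representation, the CNN train/validation loss and accuracy
#' curves; otherwise the in-sample ROC curve.
#'
#' @param x an `hf_model`.
#' @param ... passed to the underlying plotting call.
#' @export
plot.hf_model <- function(x, ...) {
  if (x$representation == "image") {
    plot_training_curves(x$cnn, ...)
  } else {
    p <- fitted_probs(x)
    ra <- roc_auc(x$y, p)
    plot_roc(list(model = ra$roc),
             main = sprintf("In-sample ROC (%s/%s), AUC = %.3f",
                            x$representation, x$classifier_name, ra$auc),
             ...)
  }
  invisible(x)
}
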