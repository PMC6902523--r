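# Base-graphics reporting plots: ROC curves, the feature-correlation heat
# map, and CNN training curves.

#' Plot one or more ROC curves
#'
#' @param rocs named list of data.frames with `fpr`, `tpr` columns (e.g. the
#'   `roc` field of an `eval_report`).
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(rocs, main = "ROC", ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)", main = main, ...)
  cols <- grDevices::rainbow(length(rocs))
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$fpr, rocs[[i]]$tpr, col = cols[i], lwd = 2)
  if (!is.null(names(rocs)))
    graphics::legend("bottomright", legend = names(rocs), col = cols,
                     lwd = 2, cex = 0.8, bty = "n")
  invisible(NULL)
}

#' Feature-correlation heat map
#'
#' Pearson correlation of every feature pair, dark = strong; the analogue of
#' inspecting which of the 90 statistical derivatives are redundant before
#' filtering.
#'
#' @param features numeric matrix / data.frame.
#' @param ... passed to [graphics::image()].
#' @export
plot_correlation_heatmap <- function(features, ...) {
  x <- as.matrix(features)
  keep <- apply(x, 2, stats::sd) > 0
  cm <- stats::cor(x[, keep, drop = FALSE])
  p <- ncol(cm)
  graphics::image(seq_len(p), seq_len(p), abs(cm)[, p:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE,
                  main = "Absolute feature correlation", ...)
  invisible(cm)
}

#' CNN training curves (loss and accuracy, train vs validation)
#'
#' @param model a `cnn_model`.
#' @param ... passed to the plot calls.
#' @export
plot_training_curves <- function(model, ...) {
  h <- model$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 lwd = 2, xlab = "Epoch", ylab = "Cross-entropy loss",
                 ylim = range(c(h$train_loss, h$val_loss)),
                 main = "Loss", ...)
  graphics::lines(h$epoch, h$val_loss, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  graphics::plot(h$epoch, h$train_acc, type = "l", col = "steelblue",
                 lwd = 2, xlab = "Epoch", ylab = "Accuracy",
                 ylim = range(c(h$train_acc, h$val_acc)),
                 main = "Accuracy", ...)
  graphics::lines(h$epoch, h$val_acc, col = "firebrick", lwd = 2)
  invisible(h)
}
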