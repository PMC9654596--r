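#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from raw confusion-matrix counts:
#' accuracy = (TP + TN) / (TP + FP + TN + FN), precision = TP / (TP + FP),
#' recall = TP / (FN + TP), F1 = 2 * precision * recall /
#' (precision + recall). A degenerate denominator (e.g. no positive
#' predictions) yields 0 for the affected metric together with an
#' \code{undefined} flag -- never a silent drop.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1} and logical \code{undefined} (any degenerate denominator).
#' @examples
#' metrics_from_counts(1, 1, 1, 1)  # 0.5 across the board
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  undefined <- FALSE
  precision <- if (tp + fp == 0) { undefined <- TRUE; 0 } else tp / (tp + fp)
  recall    <- if (fn + tp == 0) { undefined <- TRUE; 0 } else tp / (fn + tp)
  f1 <- if (precision + recall == 0) { undefined <- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = precision, recall = recall, f1 = f1,
       undefined = undefined)
}

#' Evaluate a classifier on labeled tensors
#'
#' Produces a per-class one-vs-rest evaluation report: confusion counts,
#' precision, recall, F1 and support for each class, plus overall
#' accuracy.
#'
#' @param net A \code{cnn_net} (or fitted \code{eeg_cnn}, whose scaler is
#'   NOT applied here -- pass tensors on the scale the network was
#'   trained on).
#' @param tensors List with \code{x} and one-hot \code{y}.
#' @return An object of class \code{eval_report}: data frame
#'   \code{per_class}, overall \code{accuracy}, \code{n}, and the raw
#'   predicted classes.
#' @export
evaluate <- function(net, tensors) {
  if (inherits(net, "eeg_cnn")) net <- net$net
  stopifnot(inherits(net, "cnn_net"))
  n <- dim(tensors$x)[1L]
  if (is.null(n) || n == 0L) {
    stop("validation error: empty evaluation set", call. = FALSE)
  }
  p <- predict_probs(net, tensors$x)
  pred <- max.col(p) - 1L
  truth <- max.col(tensors$y) - 1L
  per_class <- do.call(rbind, lapply(0:1, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    m <- metrics_from_counts(tp, fp, tn, fn)
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               support = sum(truth == cl), undefined = m$undefined)
  }))
  structure(list(per_class = per_class,
                 accuracy = mean(pred == truth),
                 n = n, predicted = pred, truth = truth),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("evaluation on %d rows: accuracy %.4f\n", x$n, x$accuracy))
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc[, c("class", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  if (any(x$per_class$undefined)) {
    cat("note: degenerate denominator in at least one class (metric set to 0)\n")
  }
  invisible(x)
}
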