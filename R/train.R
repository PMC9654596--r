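#' Training hyper-parameters
#'
#' Defaults are the study settings: 100 epochs, batches of 100, Adam with
#' categorical cross-entropy, rectified-linear hidden activations and a
#' soft-max output.
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param seed Seed controlling shuffling, drop-out masks and weight
#'   initialization.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 100L, batch_size = 100L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by mini-batch Adam
#'
#' Minimizes categorical cross-entropy. With \code{epochs = 0} the model
#' is returned unchanged with an empty trace. The per-epoch accuracy
#' trace covers the training rows and, when supplied, the validation
#' tensors; following the study protocol the held-out test set doubles as
#' the validation set (pass a separate set for a three-way protocol).
#'
#' @param net A \code{cnn_net} from \code{\link{build_model}} or
#'   \code{\link{cnn_build}}.
#' @param tensors List with \code{x} [n x width x 1] and one-hot \code{y}
#'   [n x 2], as from \code{\link{to_model_tensors}}.
#' @param config A \code{\link{train_config}}.
#' @param validation Optional tensors list for per-epoch validation
#'   accuracy.
#' @param verbose Print per-epoch progress.
#' @return List with \code{net} (trained) and \code{history} (data frame
#'   epoch / loss / train_acc / val_acc).
#' @export
train_model <- function(net, tensors, config = train_config(),
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "cnn_net"), inherits(config, "train_config"))
  n <- dim(tensors$x)[1L]
  stopifnot(nrow(tensors$y) == n)
  if (anyNA(tensors$x)) stop("validation error: NaN/NA in inputs", call. = FALSE)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  if (config$epochs == 0L) return(list(net = net, history = history))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  state <- adam_init(net)
  t_step <- 0L
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq.int(1L, n, by = config$batch_size)) {
      idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- tensors$x[idx, , , drop = FALSE]
      yb <- tensors$y[idx, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      p <- fw$out
      ep_loss <- ep_loss - sum(log(pmax(p[yb == 1], 1e-12)))
      ep_correct <- ep_correct + sum(max.col(p) == max.col(yb))
      if (!is.finite(ep_loss)) {
        stop("training aborted: non-finite loss at epoch ", ep, call. = FALSE)
      }
      grads <- nn_backward(net, fw$caches, (p - yb) / nrow(yb))
      t_step <- t_step + 1L
      upd <- adam_step(net, grads, state, t_step, lr = config$lr,
                       beta1 = config$beta1, beta2 = config$beta2,
                       eps = config$eps)
      net <- upd$net; state <- upd$state
    }
    val_acc <- NA_real_
    if (!is.null(validation)) {
      vp <- predict_probs(net, validation$x)
      val_acc <- mean(max.col(vp) == max.col(validation$y))
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, train_acc = ep_correct / n,
      val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f train %.4f val %s", ep,
                      ep_loss / n, ep_correct / n,
                      ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc))))
    }
  }
  list(net = net, history = history)
}

# Batched inference (bounded memory for large evaluation sets).
predict_probs <- function(net, x, batch = 4096L) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  n <- dim(x)[1L]
  out <- matrix(NA_real_, n, net$output_units)
  for (b0 in seq.int(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    out[idx, ] <- nn_forward(net, x[idx, , , drop = FALSE], training = FALSE)$out
  }
  out
}

#' Fit an emotion classifier to a feature matrix
#'
#' The high-level fitting interface: takes an (optionally extended)
#' feature matrix, standardizes it, binarizes the target rating, splits
#' train/test, builds the requested architecture variant and trains it.
#' Returns a fitted-model object with \code{print}, \code{summary},
#' \code{predict}, \code{plot} and \code{coef} methods.
#'
#' @param features A \code{feature_matrix} (see
#'   \code{\link{extract_features}}, \code{\link{extend_features}}).
#' @param target \code{"valence"} or \code{"arousal"}.
#' @param variant Architecture variant (default \code{"M2"}).
#' @param train_fraction Train split fraction (default 0.75).
#' @param config A \code{\link{train_config}}.
#' @param split_unit \code{"window-row"} (study protocol) or
#'   \code{"trial"} (leakage-free alternative).
#' @param standardize_on \code{"all"} (study protocol: statistics fitted
#'   before splitting, which leaks test moments into training) or
#'   \code{"train"} (fit on training rows only).
#' @return An object of class \code{eeg_cnn}: the trained \code{net},
#'   \code{history}, split indices, fitted scaler statistics and the
#'   held-out \code{\link{evaluate}} report.
#' @export
eeg_cnn <- function(features, target = c("valence", "arousal"),
                    variant = "M2", train_fraction = 0.75,
                    config = train_config(),
                    split_unit = c("window-row", "trial"),
                    standardize_on = c("all", "train")) {
  stopifnot(inherits(features, "feature_matrix"))
  target <- match.arg(target)
  split_unit <- match.arg(split_unit)
  standardize_on <- match.arg(standardize_on)

  n <- nrow(features$values)
  trials <- interaction(features$provenance$participant,
                        features$provenance$trial, drop = TRUE)
  idx <- split_indices(n, train_fraction, seed = config$seed, unit = split_unit,
                       trials = as.integer(trials))
  std <- if (standardize_on == "all") standardize_features(features)
         else standardize_features(features, rows = idx$train)
  tensors <- to_model_tensors(std$M, target)
  tr <- list(x = tensors$x[idx$train, , , drop = FALSE],
             y = tensors$y[idx$train, , drop = FALSE])
  te <- list(x = tensors$x[idx$test, , , drop = FALSE],
             y = tensors$y[idx$test, , drop = FALSE])
  net <- build_model(variant, input_width = ncol(features$values),
                     seed = config$seed)
  fit <- train_model(net, tr, config, validation = te)
  report <- evaluate(fit$net, te)
  structure(list(net = fit$net, history = fit$history, target = target,
                 variant = variant, split = idx, scaler = std$stats,
                 feature_names = features$feature_names,
                 config = config, report = report),
            class = "eeg_cnn")
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf("Residual 1D-CNN emotion classifier (%s) for %s\n",
              x$variant, x$target))
  cat(sprintf("  %s trainable parameters; %d training epochs\n",
              format(count_params(x$net), big.mark = ","),
              nrow(x$history)))
  cat(sprintf("  train rows: %d  test rows: %d\n",
              length(x$split$train), length(x$split$test)))
  cat(sprintf("  held-out accuracy: %.4f\n", x$report$accuracy))
  invisible(x)
}

#' @export
summary.eeg_cnn <- function(object, ...) {
  print(object)
  cat("\nArchitecture:\n")
  summary(object$net)
  cat("\nHeld-out evaluation:\n")
  print(object$report)
  invisible(object)
}

#' @export
predict.eeg_cnn <- function(object, newdata,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  values <- if (inherits(newdata, "feature_matrix")) newdata$values else as.matrix(newdata)
  values <- standardize_features(values, stats = object$scaler)$M
  p <- predict_probs(object$net, values)
  colnames(p) <- c("class0", "class1")
  if (type == "prob") p else as.integer(max.col(p) == 2L)
}

#' @export
plot.eeg_cnn <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_acc, type = "b", pch = 16,
                 ylim = range(c(h$train_acc, h$val_acc), na.rm = TRUE),
                 xlab = "epoch", ylab = "accuracy",
                 main = sprintf("%s on %s: training trace", x$variant, x$target), ...)
  if (any(!is.na(h$val_acc))) {
    graphics::lines(h$epoch, h$val_acc, type = "b", pch = 1, lty = 2)
    graphics::legend("bottomright", c("train", "validation"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
coef.eeg_cnn <- function(object, ...) {
  stats::setNames(
    lapply(object$net$layers, function(ly)
      if (is.null(ly$W)) NULL else list(W = ly$W, b = ly$b)),
    vapply(object$net$layers, `[[`, character(1), "type"))
}
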