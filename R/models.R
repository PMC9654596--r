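#' The five 1D-CNN architecture variants
#'
#' The parameter-reduction ladder: from the heavy M1 (4 convolution +
#' 3 dense layers, 4.38 M parameters) down to the lightest C1D2
#' (1 convolution + 2 dense, 18.7 k). All variants except C1D2 carry a
#' residual connection. Dense-layer counts include the 2-way soft-max
#' output layer. The expected trainable-parameter counts at the standard
#' extended input width of 73 are the architecture fingerprints enforced
#' by the test suite.
#'
#' @return Data frame with columns \code{id}, \code{conv_layers},
#'   \code{dense_layers}, \code{residual}, \code{expected_params}.
#' @export
model_variants <- function() {
  data.frame(
    id = c("M1", "C3D2", "C2D2", "M2", "C1D2"),
    conv_layers  = c(4L, 3L, 2L, 2L, 1L),
    dense_layers = c(3L, 2L, 2L, 1L, 2L),
    residual = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    expected_params = c(4381410L, 70130L, 59298L, 29538L, 18706L),
    stringsAsFactors = FALSE
  )
}

variant_layers <- function(id, residual = TRUE) {
  res <- function(...) if (residual) list(...) else list()
  switch(id,
    M1 = c(
      list(layer_conv1d(16, 3, "valid"),
           layer_conv1d(64, 5, "same"),
           layer_maxpool1d(2),
           layer_conv1d(256, 5, "valid"),
           layer_maxpool1d(2)),
      res(layer_checkpoint("r1")),
      list(layer_conv1d(256, 5, "same")),
      res(layer_residual_add("r1")),
      list(layer_flatten(),
           layer_dropout(0.25),
           layer_dense(1024, "relu"),
           layer_dropout(0.5),
           layer_dense(32, "relu"),
           layer_dense(2, "softmax"))),
    C3D2 = c(
      list(layer_conv1d(32, 5, "same"),
           layer_maxpool1d(2),
           layer_conv1d(128, 5, "valid"),
           layer_maxpool1d(2)),
      res(layer_checkpoint("r1")),
      list(layer_conv1d(64, 3, "same")),
      res(layer_residual_add("r1")),
      list(layer_flatten(),
           layer_dropout(0.25),
           layer_dense(16, "relu"),
           layer_dense(2, "softmax"))),
    C2D2 = c(
      list(layer_conv1d(96, 7, "valid"),
           layer_maxpool1d(2)),
      res(layer_checkpoint("r1")),
      list(layer_conv1d(32, 7, "same")),
      res(layer_residual_add("r1")),
      list(layer_flatten(),
           layer_dropout(0.25),
           layer_dense(32, "relu"),
           layer_dense(2, "softmax"))),
    M2 = c(
      list(layer_conv1d(24, 3, "same"),
           layer_maxpool1d(2)),
      res(layer_checkpoint("r1")),
      list(layer_conv1d(128, 7, "same")),
      res(layer_residual_add("r1")),
      list(layer_maxpool1d(2),
           layer_flatten(),
           layer_dropout(0.25),
           layer_dense(2, "softmax"))),
    C1D2 = list(
      layer_conv1d(32, 6, "same"),
      layer_maxpool1d(2),
      layer_flatten(),
      layer_dropout(0.25),
      layer_dense(16, "relu"),
      layer_dense(2, "softmax")),
    stop("configuration error: unknown variant '", id,
         "' (use one of M1, C3D2, C2D2, M2, C1D2)", call. = FALSE)
  )
}

#' Build one of the five classifier variants
#'
#' Constructs the variant's layer graph at a given input width and
#' initializes its weights. All hidden activations are rectified-linear,
#' the output is a 2-way soft-max, and drop-out regularization sits
#' between the flattening and dense stages (adding no parameters).
#' Residual skips add an earlier activation into a later convolution
#' output, through a 1x1 projection where the channel counts differ
#' (M2, C2D2, C3D2) and as a pure identity where they match (M1).
#'
#' @param variant Variant id: \code{"M1"}, \code{"C3D2"}, \code{"C2D2"},
#'   \code{"M2"} or \code{"C1D2"}.
#' @param input_width Number of input feature columns (default 73, the
#'   70 band powers plus three extension ratings).
#' @param seed Weight-initialization seed.
#' @param residual Set \code{FALSE} to omit the skip connection (used to
#'   verify the skip is genuinely wired; C1D2 has none either way).
#' @return A \code{cnn_net}.
#' @examples
#' count_params(build_model("M2"))  # 29538
#' @export
build_model <- function(variant, input_width = 73L, seed = 1L, residual = TRUE) {
  layers <- variant_layers(variant, residual = residual)
  net <- cnn_build(layers, input_width = input_width, seed = seed)
  net$variant <- variant
  net
}

#' @export
print.cnn_net <- function(x, ...) {
  cat(sprintf("<cnn_net%s: input %d x %d, %s trainable parameters>\n",
              if (is.null(x$variant)) "" else paste0(" ", x$variant),
              x$input_width, x$input_channels,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Layer-by-layer summary of a network
#'
#' @param object A \code{cnn_net}.
#' @param ... Unused.
#' @return Data frame with one row per layer: type, output shape and
#'   parameter count (printed, returned invisibly).
#' @export
summary.cnn_net <- function(object, ...) {
  rows <- lapply(object$layers, function(ly) {
    shape <- if (ly$out_shape[2L] == 0L) sprintf("(%d)", ly$out_shape[1L])
             else sprintf("(%d, %d)", ly$out_shape[1L], ly$out_shape[2L])
    data.frame(layer = ly$type,
               detail = switch(ly$type,
                 conv1d = sprintf("%d filters, kernel %d, %s", ly$filters, ly$kernel, ly$padding),
                 dense = sprintf("%d units, %s", ly$units, ly$activation),
                 maxpool = sprintf("pool %d", ly$pool),
                 dropout = sprintf("rate %g", ly$rate),
                 residual_add = if (isTRUE(ly$projection)) "1x1 projection" else "identity",
                 ""),
               output_shape = shape,
               params = length(ly$W) + length(ly$b))
  })
  out <- do.call(rbind, rows)
  print(out)
  cat(sprintf("total trainable parameters: %s\n",
              format(count_params(object), big.mark = ",")))
  invisible(out)
}

#' Parameter-to-data ratio
#'
#' Parameters as a percentage of the dataset size,
#' \code{params / dataset_size * 100}. The reference dataset-size
#' constant used alongside the published ratios back-computes to about
#' 384,000 rows and is exposed here as an explicit default rather than
#' tied to any array in the pipeline.
#'
#' @param params Trainable parameter count (or a \code{cnn_net}).
#' @param dataset_size Number of data rows (default 384000).
#' @return Percentage.
#' @examples
#' param_data_ratio(29538)  # about 7.69
#' @export
param_data_ratio <- function(params, dataset_size = 384000) {
  if (inherits(params, "cnn_net")) params <- count_params(params)
  if (!is.numeric(dataset_size) || dataset_size <= 0) {
    stop("arithmetic error: dataset_size must be positive", call. = FALSE)
  }
  params / dataset_size * 100
}
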