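# Minimal 1-d convolutional network engine: declarative layer descriptors
# compiled to a parameterized graph with hand-written forward/backward
# passes and an Adam optimizer. Activations flow as [batch, length,
# channels] arrays; convolutions are evaluated as im2col matrix products
# so the heavy lifting stays inside BLAS.

#' Layer descriptors
#'
#' Declarative building blocks compiled by \code{\link{cnn_build}}. A
#' residual skip is expressed as a \code{layer_checkpoint()} marking where
#' the skip branches off and a matching \code{layer_residual_add()} where
#' it rejoins; when the channel counts at the two points differ, a
#' width-matching 1x1 convolution projection (with bias) is inserted on
#' the skip path automatically.
#'
#' @param filters Number of convolution filters.
#' @param kernel Kernel width in samples.
#' @param padding \code{"same"} (zero-padded, length-preserving) or
#'   \code{"valid"}.
#' @param activation \code{"relu"}, \code{"linear"} or (dense only)
#'   \code{"softmax"}.
#' @param pool Pooling width (non-overlapping max pooling).
#' @param units Dense layer width.
#' @param rate Dropout rate in [0, 1).
#' @param id Checkpoint identifier linking a residual add to its source.
#' @return A layer descriptor (list), to be passed to \code{\link{cnn_build}}.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel, padding = c("same", "valid"),
                         activation = "relu") {
  padding <- match.arg(padding)
  list(type = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), padding = padding, activation = activation)
}

#' @rdname layers
#' @export
layer_maxpool1d <- function(pool = 2L) list(type = "maxpool", pool = as.integer(pool))

#' @rdname layers
#' @export
layer_flatten <- function() list(type = "flatten")

#' @rdname layers
#' @export
layer_dense <- function(units, activation = c("relu", "softmax", "linear")) {
  list(type = "dense", units = as.integer(units),
       activation = match.arg(activation))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_checkpoint <- function(id = "skip") list(type = "checkpoint", id = id)

#' @rdname layers
#' @export
layer_residual_add <- function(id = "skip") list(type = "residual_add", id = id)

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Compile layer descriptors into a network
#'
#' Walks the descriptor list, infers activation shapes from the input
#' width, initializes weights (He-scaled Gaussian) and wires residual
#' projections where channel counts differ across a skip.
#'
#' @param layers List of layer descriptors (see \code{\link{layers}}).
#' @param input_width Input length (number of feature columns).
#' @param input_channels Input channels (default 1).
#' @param seed Seed for weight initialization; the caller's RNG state is
#'   preserved.
#' @return An object of class \code{cnn_net}.
#' @export
cnn_build <- function(layers, input_width, input_channels = 1L, seed = 1L) {
  stopifnot(input_width >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  L <- as.integer(input_width); C <- as.integer(input_channels)
  ckpt_shape <- list()
  compiled <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly$in_shape <- c(L, C)
    switch(ly$type,
      conv1d = {
        k <- ly$kernel
        Lout <- if (ly$padding == "same") L else L - k + 1L
        if (Lout < 1L) stop("layer ", i, ": window shrinks below 1", call. = FALSE)
        ly$W <- he_init(k * C, ly$filters, k * C)
        ly$b <- numeric(ly$filters)
        L <- Lout; C <- ly$filters
      },
      maxpool = {
        L <- L %/% ly$pool
        if (L < 1L) stop("layer ", i, ": pooled length below 1", call. = FALSE)
      },
      flatten = {
        L <- L * C; C <- 0L   # C = 0 marks 2-d (flattened) activations
      },
      dense = {
        if (C != 0L) stop("dense layer requires flattened input", call. = FALSE)
        ly$W <- he_init(L, ly$units, L)
        ly$b <- numeric(ly$units)
        L <- ly$units
      },
      dropout = NULL,
      checkpoint = {
        ckpt_shape[[ly$id]] <- c(L, C)
      },
      residual_add = {
        src <- ckpt_shape[[ly$id]]
        if (is.null(src)) stop("residual_add without checkpoint '", ly$id, "'", call. = FALSE)
        if (src[1L] != L) {
          stop("residual skip spans a length change (", src[1L], " -> ", L,
               "); place the add before pooling", call. = FALSE)
        }
        if (src[2L] != C) {   # width-matching projection, 1x1 conv with bias
          ly$W <- he_init(src[2L], C, src[2L])
          ly$b <- numeric(C)
          ly$projection <- TRUE
        } else {
          ly$projection <- FALSE
        }
      },
      stop("unknown layer type: ", ly$type, call. = FALSE)
    )
    ly$out_shape <- c(L, C)
    compiled[[i]] <- ly
  }
  if (C != 0L) stop("network must end flattened (dense output)", call. = FALSE)
  structure(list(layers = compiled, input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 output_units = L),
            class = "cnn_net")
}

#' Count trainable parameters
#'
#' Total number of trainable weights and biases across all layers,
#' including residual projections.
#'
#' @param net A \code{cnn_net} (or fitted model wrapping one).
#' @return Integer parameter count.
#' @export
count_params <- function(net) {
  if (inherits(net, "eeg_cnn")) net <- net$net
  stopifnot(inherits(net, "cnn_net"))
  sum(vapply(net$layers, function(ly)
    length(ly$W) + length(ly$b), numeric(1)))
}

# --- forward / backward -----------------------------------------------------

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# im2col: padded activations [B, Lp, C] -> [B*Lout, k*C]; column (t-1)*C + c
# holds channel c at kernel tap t.
im2col <- function(xp, k, Lout) {
  B <- dim(xp)[1L]; C <- dim(xp)[3L]
  cols <- vector("list", k)
  for (t in seq_len(k)) {
    cols[[t]] <- matrix(xp[, t:(t + Lout - 1L), , drop = FALSE], nrow = B * Lout)
  }
  do.call(cbind, cols)
}

conv_pad <- function(x, k, padding) {
  if (padding == "valid" || k == 1L) return(x)
  B <- dim(x)[1L]; L <- dim(x)[2L]; C <- dim(x)[3L]
  pl <- (k - 1L) %/% 2L
  pr <- k - 1L - pl
  xp <- array(0, dim = c(B, L + pl + pr, C))
  xp[, pl + seq_len(L), ] <- x
  xp
}

nn_forward <- function(net, x, training = FALSE) {
  # x: [B, L, C] array (or [B, L] matrix treated as C = 1)
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  caches <- vector("list", length(net$layers))
  ckpt <- list()
  a <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    cache <- list()
    switch(ly$type,
      conv1d = {
        B <- dim(a)[1L]
        Lout <- ly$out_shape[1L]
        xp <- conv_pad(a, ly$kernel, ly$padding)
        Xc <- im2col(xp, ly$kernel, Lout)
        z <- add_bias(Xc %*% ly$W, ly$b)
        cache$Xc <- Xc; cache$dim_in <- dim(a); cache$dim_pad <- dim(xp)
        a <- array(z, dim = c(B, Lout, ly$filters))
        if (ly$activation == "relu") { cache$pos <- a > 0; a <- a * cache$pos }
      },
      maxpool = {
        p <- ly$pool; B <- dim(a)[1L]; C <- dim(a)[3L]
        Lout <- ly$out_shape[1L]
        segs <- lapply(seq_len(p), function(j)
          a[, seq.int(j, by = p, length.out = Lout), , drop = FALSE])
        m <- segs[[1L]]
        which_max <- array(1L, dim = dim(m))
        if (p > 1L) for (j in 2:p) {
          upd <- segs[[j]] > m
          m[upd] <- segs[[j]][upd]
          which_max[upd] <- j
        }
        cache$which_max <- which_max; cache$dim_in <- dim(a)
        a <- m
      },
      flatten = {
        cache$dim_in <- dim(a)
        a <- matrix(a, nrow = dim(a)[1L])
      },
      dense = {
        z <- add_bias(a %*% ly$W, ly$b)
        cache$X <- a
        if (ly$activation == "relu") {
          cache$pos <- z > 0; a <- z * cache$pos
        } else if (ly$activation == "softmax") {
          z <- z - apply(z, 1L, max)
          e <- exp(z)
          a <- e / rowSums(e)
          cache$probs <- a
        } else a <- z
      },
      dropout = {
        if (training && ly$rate > 0) {
          mask <- (stats::runif(length(a)) >= ly$rate) / (1 - ly$rate)
          dim(mask) <- dim(a)
          cache$mask <- mask
          a <- a * mask
        }
      },
      checkpoint = {
        ckpt[[ly$id]] <- a
      },
      residual_add = {
        s <- ckpt[[ly$id]]
        if (ly$projection) {
          B <- dim(s)[1L]; Ls <- dim(s)[2L]
          sm <- matrix(s, nrow = B * Ls)
          proj <- add_bias(sm %*% ly$W, ly$b)
          cache$sm <- sm; cache$dim_s <- dim(s)
          a <- a + array(proj, dim = dim(a))
        } else {
          a <- a + s
        }
      }
    )
    caches[[i]] <- cache
  }
  list(out = a, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  # returns list of per-layer gradients (dW, db) aligned with net$layers
  grads <- vector("list", length(net$layers))
  skip_grad <- list()
  d <- dout
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cache <- caches[[i]]
    switch(ly$type,
      conv1d = {
        B <- cache$dim_in[1L]
        if (ly$activation == "relu") d <- d * cache$pos
        Lout <- ly$out_shape[1L]
        dm <- matrix(d, nrow = B * Lout)
        grads[[i]] <- list(dW = crossprod(cache$Xc, dm), db = colSums(dm))
        dXc <- tcrossprod(dm, ly$W)
        dxp <- array(0, dim = cache$dim_pad)
        C <- cache$dim_in[3L]
        for (t in seq_len(ly$kernel)) {
          dxp[, t:(t + Lout - 1L), ] <- dxp[, t:(t + Lout - 1L), , drop = FALSE] +
            array(dXc[, (t - 1L) * C + seq_len(C)], dim = c(B, Lout, C))
        }
        if (ly$padding == "same" && ly$kernel > 1L) {
          pl <- (ly$kernel - 1L) %/% 2L
          d <- dxp[, pl + seq_len(cache$dim_in[2L]), , drop = FALSE]
        } else d <- dxp
      },
      maxpool = {
        p <- ly$pool
        dx <- array(0, dim = cache$dim_in)
        Lout <- dim(d)[2L]
        for (j in seq_len(p)) {
          sel <- cache$which_max == j
          slice <- array(0, dim = dim(d))
          slice[sel] <- d[sel]
          dx[, seq.int(j, by = p, length.out = Lout), ] <- slice
        }
        d <- dx
      },
      flatten = {
        d <- array(d, dim = cache$dim_in)
      },
      dense = {
        if (ly$activation == "relu") d <- d * cache$pos
        # softmax gradient is supplied directly as dout at the loss
        grads[[i]] <- list(dW = crossprod(cache$X, d), db = colSums(d))
        d <- tcrossprod(d, ly$W)
      },
      dropout = {
        if (!is.null(cache$mask)) d <- d * cache$mask
      },
      checkpoint = {
        sg <- skip_grad[[ly$id]]
        if (!is.null(sg)) d <- d + sg
      },
      residual_add = {
        if (ly$projection) {
          B <- cache$dim_s[1L]; Ls <- cache$dim_s[2L]
          dm <- matrix(d, nrow = B * Ls)
          grads[[i]] <- list(dW = crossprod(cache$sm, dm), db = colSums(dm))
          skip_grad[[ly$id]] <- array(tcrossprod(dm, ly$W), dim = cache$dim_s)
        } else {
          skip_grad[[ly$id]] <- d
        }
        # main-path gradient passes through unchanged
      }
    )
  }
  grads
}

#' Forward pass returning class probabilities
#'
#' @param net A \code{cnn_net}.
#' @param x Input array [n x width x 1] (or matrix [n x width]).
#' @return Matrix [n x output_units] of soft-max probabilities.
#' @export
cnn_forward <- function(net, x) {
  stopifnot(inherits(net, "cnn_net"))
  nn_forward(net, x, training = FALSE)$out
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(net = net, state = state)
}
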