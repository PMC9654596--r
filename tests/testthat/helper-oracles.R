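# Shared fixtures and independent oracles, built in code at test time.

# Small synthetic recording for I/O and feature tests.
tiny_recording <- function(n_trials = 2L, n_channels = 3L, n_samples = 64L,
                           seed = 7L) {
  set.seed(seed)
  eeg_recording(
    data = array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples)),
    ratings = matrix(runif(n_trials * 4, 1, 9), n_trials, 4),
    sample_rate = 128, participant_id = "tiny")
}

# Direct O(N^2) DFT magnitudes (one-sided), independent of stats::fft.
direct_dft_mag <- function(x) {
  N <- length(x)
  k <- 0:(N %/% 2)
  E <- exp(-2i * pi * outer(k, 0:(N - 1)) / N)
  Mod(as.vector(E %*% x))
}

# Band power recomputed from the direct DFT.
direct_band_power <- function(x, Fs, bands) {
  mag <- direct_dft_mag(x)
  vapply(bands, function(b) {
    k <- 0:(length(x) %/% 2)
    f <- k * Fs / length(x)
    sel <- f >= b$low & f < b$high
    if (!any(sel)) 0 else sum(mag[sel])
  }, numeric(1))
}

# Brute-force window enumeration under the strict inclusion rule.
enumerate_starts <- function(L, W, S) {
  s <- seq.int(0L, max(L, 1L), by = S)
  s[s + W < L]
}

# Naive 1-d convolution (cross-correlation, Keras orientation) oracle.
naive_conv1d <- function(x, W, b, padding) {
  # x: [L, C]; W: [k*C, f] with column (t-1)*C + c; returns [Lout, f]
  C <- ncol(x); k <- nrow(W) / C; f <- ncol(W)
  if (padding == "same") {
    pl <- (k - 1) %/% 2; pr <- k - 1 - pl
    x <- rbind(matrix(0, pl, C), x, matrix(0, pr, C))
  }
  Lout <- nrow(x) - k + 1
  out <- matrix(0, Lout, f)
  for (pos in seq_len(Lout)) {
    patch <- as.vector(t(x[pos:(pos + k - 1), , drop = FALSE]))  # tap-major
    out[pos, ] <- patch %*% W + b
  }
  out
}

# Finite-difference gradient of the cross-entropy loss wrt every parameter.
numeric_grads <- function(net, x, y, eps = 1e-6) {
  lossfn <- function(n) {
    p <- eegcnn:::nn_forward(n, x, training = FALSE)$out
    -sum(log(p[y == 1]))
  }
  lapply(seq_along(net$layers), function(i) {
    ly <- net$layers[[i]]
    if (is.null(ly$W)) return(NULL)
    dW <- ly$W * 0
    for (j in seq_along(dW)) {
      np <- net; np$layers[[i]]$W[j] <- np$layers[[i]]$W[j] + eps
      nm <- net; nm$layers[[i]]$W[j] <- nm$layers[[i]]$W[j] - eps
      dW[j] <- (lossfn(np) - lossfn(nm)) / (2 * eps)
    }
    db <- ly$b * 0
    for (j in seq_along(db)) {
      np <- net; np$layers[[i]]$b[j] <- np$layers[[i]]$b[j] + eps
      nm <- net; nm$layers[[i]]$b[j] <- nm$layers[[i]]$b[j] - eps
      db[j] <- (lossfn(np) - lossfn(nm)) / (2 * eps)
    }
    list(dW = dW, db = db)
  })
}

# A hand-weighted threshold classifier on a single input column: predicts
# class 1 iff the input value is positive. Used as a controllable
# "perfect predictor" for evaluation tests.
threshold_net <- function() {
  net <- cnn_build(list(layer_flatten(), layer_dense(2, "softmax")),
                   input_width = 1L)
  net$layers[[2L]]$W <- matrix(c(-10, 10), nrow = 1)
  net$layers[[2L]]$b <- c(0, 0)
  net
}
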