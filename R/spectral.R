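#' Plan sliding-window offsets over a trial
#'
#' Windows of \code{W} samples advance by \code{S} samples from offset 0.
#' A window starting at \code{s} is included iff \code{s + W < L}
#' (strictly): this is the inclusion rule that reproduces the published
#' window counts for every window size from 4 to 1024 samples over
#' 8064-sample trials with step 16 (e.g. 488 windows at W = 256, 440 at
#' W = 1024).
#'
#' @param L Trial length in samples.
#' @param W Window size in samples.
#' @param S Step size in samples.
#' @return An object of class \code{window_plan} with zero-based
#'   \code{starts}, and fields \code{L}, \code{W}, \code{S}.
#' @examples
#' length(plan_windows(8064, 256, 16)$starts)  # 488
#' @export
plan_windows <- function(L, W, S) {
  if (!is.numeric(W) || W < 1 || !is.numeric(S) || S < 1) {
    stop("configuration error: W and S must be positive", call. = FALSE)
  }
  L <- as.integer(L); W <- as.integer(W); S <- as.integer(S)
  starts <- if (L > W) seq.int(0L, L - W - 1L, by = S) else integer(0)
  structure(list(starts = starts, L = L, W = W, S = S), class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan: L=%d W=%d S=%d -> %d windows>\n",
              x$L, x$W, x$S, length(x$starts)))
  invisible(x)
}

#' Number of windows per trial
#'
#' @param L,W,S As in \code{\link{plan_windows}}.
#' @return Integer window count.
#' @export
n_windows <- function(L, W, S) length(plan_windows(L, W, S)$starts)

#' Band power of a single window
#'
#' The window is Fourier-transformed (no taper, no detrending) and each
#' band aggregates the one-sided FFT magnitudes |X[k]| over its bins from
#' \code{\link{band_bins}}. An empty bin set yields 0 power. Summed (not
#' averaged) magnitudes are used; the choice only rescales columns and is
#' neutralized by standardization downstream.
#'
#' @param window_signal Numeric vector of exactly \code{W} samples.
#' @param Fs Sampling rate in Hz.
#' @param bands List of \code{\link{band_spec}} objects.
#' @return Named numeric vector of per-band powers.
#' @examples
#' w <- sin(2 * pi * 10 * (0:255) / 128)  # 10 Hz, on-bin for W = 256
#' band_power(w, 128, default_bands())    # concentrates in alpha
#' @export
band_power <- function(window_signal, Fs, bands = default_bands()) {
  W <- length(window_signal)
  if (W < 1) stop("validation error: empty window", call. = FALSE)
  mag <- Mod(stats::fft(window_signal))
  vapply(bands, function(b) {
    k <- band_bins(W, Fs, b)
    if (length(k) == 0L) 0 else sum(mag[k + 1L])
  }, numeric(1))
}

# Vectorized band powers for all windows of one channel within one trial.
# signal: numeric vector (length L); returns matrix [n_windows x n_bands].
channel_band_powers <- function(signal, plan, Fs, bands) {
  ns <- length(plan$starts)
  bins <- lapply(bands, function(b) band_bins(plan$W, Fs, b))
  out <- matrix(0, nrow = ns, ncol = length(bands))
  if (ns == 0L) return(out)
  idx <- outer(seq_len(plan$W), plan$starts, `+`)   # W x n_windows
  mag <- Mod(stats::mvfft(matrix(signal[idx], nrow = plan$W)))
  for (j in seq_along(bins)) {
    k <- bins[[j]]
    if (length(k) == 1L) out[, j] <- mag[k + 1L, ]
    else if (length(k) > 1L) out[, j] <- colSums(mag[k + 1L, , drop = FALSE])
  }
  out
}

#' Extract a sliding-window band-power feature matrix
#'
#' Applies \code{\link{band_power}} to every planned window of every
#' selected channel of every trial. Rows are ordered trial-major, then
#' start-ascending; columns are channel-major
#' (\code{<electrode>_<band>}), 70 columns for the default 14 channels x
#' 5 bands. Each row carries its source trial's four ratings and window
#' provenance.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param channels Electrode names to use (default
#'   \code{\link{default_channels}()}).
#' @param bands Band bank (default \code{\link{default_bands}()}).
#' @param W Window size in samples (default 256).
#' @param S Step size in samples (default 16).
#' @param channel_map Full electrode ordering of the recording's channels
#'   (default \code{\link{geneva_channels}()}).
#' @return An object of class \code{feature_matrix}: list with
#'   \code{values} (windows x features), \code{ratings} (windows x 4),
#'   \code{provenance} (participant, trial, start per window),
#'   \code{feature_names}.
#' @export
extract_features <- function(rec, channels = default_channels(),
                             bands = default_bands(), W = 256L, S = 16L,
                             channel_map = geneva_channels()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ch_idx <- resolve_channels(channels, channel_map)
  if (max(ch_idx) > dim(rec$data)[2L]) {
    stop("validation error: channel index beyond recording channels", call. = FALSE)
  }
  d <- dim(rec$data)
  plan <- plan_windows(d[3L], W, S)
  npt <- length(plan$starts)
  band_names <- vapply(bands, function(b) b$name, character(1))
  feat_names <- as.vector(t(outer(channels, band_names, paste, sep = "_")))
  n_rows <- npt * d[1L]
  values <- matrix(0, nrow = n_rows, ncol = length(feat_names),
                   dimnames = list(NULL, feat_names))
  for (tr in seq_len(d[1L])) {
    rows <- (tr - 1L) * npt + seq_len(npt)
    for (ci in seq_along(ch_idx)) {
      cols <- (ci - 1L) * length(bands) + seq_along(bands)
      values[rows, cols] <- channel_band_powers(rec$data[tr, ch_idx[ci], ],
                                                plan, rec$sample_rate, bands)
    }
  }
  ratings <- rec$ratings[rep(seq_len(d[1L]), each = npt), , drop = FALSE]
  provenance <- data.frame(participant = rec$participant_id,
                           trial = rep(seq_len(d[1L]), each = npt),
                           start = rep(plan$starts, d[1L]))
  structure(list(values = values, ratings = ratings, provenance = provenance,
                 feature_names = feat_names, window = plan$W, step = plan$S),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d windows x %d features (W=%d, S=%d)>\n",
              nrow(x$values), ncol(x$values), x$window, x$step))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Stack feature matrices from several participants
#'
#' @param ... \code{feature_matrix} objects (or one list of them).
#' @return A combined \code{feature_matrix}.
#' @export
rbind_features <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1L]], "feature_matrix")) ms <- ms[[1L]]
  stopifnot(all(vapply(ms, inherits, logical(1), "feature_matrix")))
  fn <- ms[[1L]]$feature_names
  stopifnot(all(vapply(ms, function(m) identical(m$feature_names, fn), logical(1))))
  structure(list(values = do.call(rbind, lapply(ms, `[[`, "values")),
                 ratings = do.call(rbind, lapply(ms, `[[`, "ratings")),
                 provenance = do.call(rbind, lapply(ms, `[[`, "provenance")),
                 feature_names = fn,
                 window = ms[[1L]]$window, step = ms[[1L]]$step),
            class = "feature_matrix")
}

#' Column standardization (z-scoring)
#'
#' Transforms every feature column to mean 0 and standard deviation 1 and
#' returns the fitted statistics for reuse on new data. A zero-variance
#' column gets a substitute scale of 1 (with a warning) so it maps to all
#' zeros rather than NaN.
#'
#' By default the statistics are fitted on the full matrix before any
#' train/test split, matching the published order of operations; note this
#' leaks test-set means/variances into training. Fit on the training rows
#' only (\code{rows =}) for a leakage-free protocol.
#'
#' @param M A \code{feature_matrix} or plain numeric matrix.
#' @param stats Optional previously fitted statistics (list with
#'   \code{center}, \code{scale}) to apply instead of fitting.
#' @param rows Optional row indices to fit the statistics on.
#' @return List with \code{M} (same class as input, standardized) and
#'   \code{stats} (\code{center}, \code{scale}).
#' @export
standardize_features <- function(M, stats = NULL, rows = NULL) {
  values <- if (inherits(M, "feature_matrix")) M$values else as.matrix(M)
  if (is.null(stats)) {
    if (nrow(values) < 2L) stop("need at least 2 rows to fit statistics", call. = FALSE)
    fit_rows <- if (is.null(rows)) seq_len(nrow(values)) else rows
    center <- colMeans(values[fit_rows, , drop = FALSE])
    scale <- apply(values[fit_rows, , drop = FALSE], 2L, stats::sd)
    # population (1/n) convention, as standard ML scalers use
    scale <- scale * sqrt((length(fit_rows) - 1) / length(fit_rows))
    if (any(scale == 0)) {
      warning("zero-variance column(s): substituting scale 1 for ",
              paste(colnames(values)[scale == 0], collapse = ", "))
      scale[scale == 0] <- 1
    }
    stats <- list(center = center, scale = scale)
  }
  out <- sweep(sweep(values, 2L, stats$center, `-`), 2L, stats$scale, `/`)
  if (inherits(M, "feature_matrix")) {
    M$values <- out
    M$standardized <- TRUE
  } else {
    M <- out
  }
  list(M = M, stats = stats)
}

#' Invert a standardization
#'
#' @param values Standardized numeric matrix.
#' @param stats Fitted statistics from \code{\link{standardize_features}}.
#' @return Matrix on the original scale.
#' @export
unstandardize_features <- function(values, stats) {
  sweep(sweep(values, 2L, stats$scale, `*`), 2L, stats$center, `+`)
}
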