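#' Window-count algebra for the full-cohort scale
#'
#' For each window size, the number of feature rows produced by the
#' sliding-window plan over \code{n_participants} x \code{n_trials}
#' trials of \code{trial_length} samples at the given step, and the exact
#' train/test row counts of a seeded row-level split. Pure arithmetic --
#' no data is touched -- reproducing the published totals (e.g. 468,480 /
#' 156,160 at W = 256 for 32 participants, 75/25).
#'
#' @param windows Window sizes in samples.
#' @param n_participants,n_trials Cohort shape (defaults 32 x 40).
#' @param trial_length Samples per trial (default 8064).
#' @param step Step size in samples (default 16).
#' @param sample_rate Hz, for the time-slice column (default 128).
#' @param train_fraction Split fraction (default 0.75).
#' @return Data frame: window, time_slice_s, n_windows_per_trial, total,
#'   train_size, test_size.
#' @examples
#' window_count_table(c(256, 1024))
#' @export
window_count_table <- function(windows = c(4, 8, 16, 32, 64, 128, 256, 512, 1024),
                               n_participants = 32L, n_trials = 40L,
                               trial_length = 8064L, step = 16L,
                               sample_rate = 128, train_fraction = 0.75) {
  per_trial <- vapply(windows, function(w) n_windows(trial_length, w, step),
                      integer(1))
  total <- per_trial * as.integer(n_participants) * as.integer(n_trials)
  train <- as.integer(round(train_fraction * total))
  data.frame(window = windows,
             time_slice_s = windows / sample_rate,
             n_windows_per_trial = per_trial,
             total = total,
             train_size = train,
             test_size = total - train)
}

#' Window-size sweep: accuracy versus EEG length
#'
#' Re-extracts features at each window size from the supplied recordings,
#' appends the three complementary ratings (FE-3), and trains + evaluates
#' the given variant on a row-level split. Longer windows give finer
#' spectral resolution (resolution = sample rate / window size), so
#' accuracy is expected to rise with window size; very short windows
#' cannot resolve the lower bands at all.
#'
#' @param recordings List of \code{\link{eeg_recording}} objects.
#' @param windows Window sizes in samples.
#' @param config A \code{\link{train_config}}.
#' @param target Rating to classify (default \code{"valence"}).
#' @param variant Architecture (default \code{"M2"}).
#' @param step Step size (default 16).
#' @param train_fraction Split (default 0.75).
#' @return Data frame: window, time_slice_s, train_size, test_size,
#'   test_accuracy, seed.
#' @export
run_window_sweep <- function(recordings,
                             windows = c(4, 8, 16, 32, 64, 128, 256, 512, 1024),
                             config = train_config(),
                             target = "valence", variant = "M2",
                             step = 16L, train_fraction = 0.75) {
  stopifnot(all(vapply(recordings, inherits, logical(1), "eeg_recording")))
  rows <- lapply(windows, function(w) {
    feats <- rbind_features(lapply(recordings, extract_features, W = w, S = step))
    feats <- extend_features(feats, "FE-3", target)
    fit <- eeg_cnn(feats, target = target, variant = variant,
                   train_fraction = train_fraction, config = config)
    data.frame(window = w,
               time_slice_s = w / recordings[[1L]]$sample_rate,
               train_size = length(fit$split$train),
               test_size = length(fit$split$test),
               test_accuracy = fit$report$accuracy,
               seed = config$seed)
  })
  do.call(rbind, rows)
}

#' Train-fraction sweep: accuracy versus training-set size
#'
#' Trains and evaluates the given variant at several train/test splits of
#' one extended feature matrix, reporting per-class train/test counts and
#' final-epoch train/test accuracy.
#'
#' @param features An extended \code{feature_matrix}.
#' @param fractions Train fractions (default the study grid).
#' @param config A \code{\link{train_config}}.
#' @param target Rating to classify (default \code{"valence"}).
#' @param variant Architecture (default \code{"M2"}).
#' @return Data frame: fraction, train/test sizes, per-class counts,
#'   train_accuracy, test_accuracy, seed.
#' @export
run_split_sweep <- function(features, fractions = c(0.8, 0.75, 0.5, 0.2, 0.1),
                            config = train_config(), target = "valence",
                            variant = "M2") {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- binarize_rating(features$ratings[, target])
  rows <- lapply(fractions, function(f) {
    fit <- eeg_cnn(features, target = target, variant = variant,
                   train_fraction = f, config = config)
    data.frame(fraction = f,
               train_size = length(fit$split$train),
               test_size = length(fit$split$test),
               train_class0 = sum(labels[fit$split$train] == 0L),
               train_class1 = sum(labels[fit$split$train] == 1L),
               test_class0 = sum(labels[fit$split$test] == 0L),
               test_class1 = sum(labels[fit$split$test] == 1L),
               train_accuracy = utils::tail(fit$history$train_acc, 1L),
               test_accuracy = fit$report$accuracy,
               seed = config$seed)
  })
  do.call(rbind, rows)
}
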