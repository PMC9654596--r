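#' Construct a validated EEG recording
#'
#' One participant's recording: a trials x channels x samples signal array
#' plus a trials x 4 matrix of self-assessment ratings (valence, arousal,
#' dominance, liking, each on the 1--9 scale). The canonical DEAP-style
#' shape is 40 x 40 x 8064 at 128 Hz (63 s per trial), but any consistent
#' shape is accepted so that small fixtures can be built in tests.
#'
#' @param data Numeric 3-d array \code{[n_trials, n_channels, n_samples]}.
#' @param ratings Numeric matrix \code{[n_trials, 4]}, values in [1, 9],
#'   columns valence, arousal, dominance, liking.
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param participant_id Identifier (default \code{"s01"}).
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, ratings, sample_rate = 128, participant_id = "s01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-d array [trials x channels x samples]", call. = FALSE)
  }
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 4L || nrow(ratings) != dim(data)[1L]) {
    stop(sprintf("ratings must be a %d x 4 matrix (one row per trial)",
                 dim(data)[1L]), call. = FALSE)
  }
  if (anyNA(ratings) || any(ratings < 1) || any(ratings > 9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  colnames(ratings) <- c("valence", "arousal", "dominance", "liking")
  structure(list(data = data, ratings = ratings,
                 sample_rate = sample_rate,
                 participant_id = as.character(participant_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_recording %s: %d trials x %d channels x %d samples @ %g Hz>\n",
              x$participant_id, d[1L], d[2L], d[3L], x$sample_rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Test a recording against the canonical DEAP-style shape
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @return \code{TRUE} when the recording is 40 trials x 40 channels x
#'   8064 samples at 128 Hz.
#' @export
is_deap_shaped <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  identical(dim(rec$data), c(40L, 40L, 8064L)) && rec$sample_rate == 128
}

#' Write a recording to disk
#'
#' Two on-disk dialects are supported. \code{"rds"} serializes the full
#' recording as an R list (the natural analogue of the original
#' distribution's serialized per-participant dictionary, and the only
#' practical format for full-size arrays). \code{"fixture"} writes an open
#' plain-text directory container -- \code{meta.yaml}, \code{labels.csv}
#' and a long-format \code{data.csv} -- intended for small synthetic
#' fixtures that must remain human-readable.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Target file (\code{"rds"}) or directory (\code{"fixture"}).
#' @param dialect \code{"rds"} or \code{"fixture"}.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("rds", "fixture")) {
  stopifnot(inherits(rec, "eeg_recording"))
  dialect <- match.arg(dialect)
  if (dialect == "rds") {
    saveRDS(list(data = rec$data, labels = rec$ratings,
                 sample_rate = rec$sample_rate,
                 participant_id = rec$participant_id), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(rec$data)
  yaml::write_yaml(list(participant_id = rec$participant_id,
                        sample_rate = rec$sample_rate,
                        n_trials = d[1L], n_channels = d[2L],
                        n_samples = d[3L]),
                   file.path(path, "meta.yaml"))
  utils::write.csv(data.frame(trial = seq_len(d[1L]), rec$ratings),
                   file.path(path, "labels.csv"), row.names = FALSE)
  # long format: one row per (trial, channel), samples across columns
  flat <- matrix(aperm(rec$data, c(3L, 2L, 1L)), nrow = d[1L] * d[2L],
                 ncol = d[3L], byrow = TRUE)
  idx <- expand.grid(channel = seq_len(d[2L]), trial = seq_len(d[1L]))
  out <- data.frame(trial = idx$trial, channel = idx$channel, flat)
  names(out) <- c("trial", "channel", paste0("t", seq_len(d[3L])))
  utils::write.csv(out, file.path(path, "data.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of \code{\link{write_recording}}; validates shapes and
#' rating ranges on load, so a malformed file is rejected rather than
#' silently propagated.
#'
#' @param path File (\code{"rds"}) or directory (\code{"fixture"}).
#' @param dialect \code{"rds"} or \code{"fixture"}.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_recording <- function(path, dialect = c("rds", "fixture")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels)) {
      stop("format error: rds recording must contain 'data' and 'labels'",
           call. = FALSE)
    }
    return(eeg_recording(obj$data, obj$labels,
                         sample_rate = if (is.null(obj$sample_rate)) 128 else obj$sample_rate,
                         participant_id = if (is.null(obj$participant_id)) "s01" else obj$participant_id))
  }
  meta_f <- file.path(path, "meta.yaml")
  lab_f  <- file.path(path, "labels.csv")
  dat_f  <- file.path(path, "data.csv")
  if (!all(file.exists(meta_f, lab_f, dat_f))) {
    stop("format error: fixture container needs meta.yaml, labels.csv, data.csv",
         call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_f)
  lab  <- utils::read.csv(lab_f)
  dat  <- utils::read.csv(dat_f)
  nt <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  if (nrow(dat) != nt * nc || ncol(dat) != ns + 2L) {
    stop("validation error: data.csv shape disagrees with meta.yaml", call. = FALSE)
  }
  ord <- order(dat$trial, dat$channel)
  vals <- as.matrix(dat[ord, -(1:2), drop = FALSE])
  data <- aperm(array(t(vals), dim = c(ns, nc, nt)), c(3L, 2L, 1L))
  eeg_recording(data, as.matrix(lab[order(lab$trial), -1L, drop = FALSE]),
                sample_rate = meta$sample_rate,
                participant_id = meta$participant_id)
}
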