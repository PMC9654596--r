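#' Configuration for the synthetic EEG generator
#'
#' Describes a DEAP-shaped participant whose per-band signal power carries a
#' planted, controllable dependence on the trial's emotion ratings. Each
#' channel is synthesized as band-limited noise -- white noise spectrally
#' shaped into each band of \code{bands}, with the band's amplitude set by
#' \code{band_gains} applied to the trial's ratings -- plus a broadband
#' noise floor. Band-limited noise (rather than pure tones) keeps a
#' realistic within-band spread in the FFT features.
#'
#' @param n_trials,n_channels,n_samples Array shape; defaults are the
#'   canonical 40 x 40 x 8064.
#' @param sample_rate Hz; default 128.
#' @param bands Band bank, default \code{\link{default_bands}()}. Every
#'   upper band edge must lie at or below the Nyquist frequency.
#' @param band_gains Named list, one function per band, each mapping the
#'   4-vector of ratings (valence, arousal, dominance, liking) to an
#'   amplitude multiplier. Defaults couple alpha/high-beta/gamma to valence
#'   and theta/low-beta to arousal with slopes that keep amplitudes
#'   positive over the whole 1--9 scale.
#' @param noise_floor Broadband noise amplitude relative to the band
#'   components (default 0.2).
#' @param rating_law \code{"uniform"}: all four ratings independent uniform
#'   on [1, 9]. \code{"two_cluster"}: the target rating is drawn from
#'   \code{clusters} (a separable two-class design), the other three
#'   remain independent uniform.
#' @param target Rating driven by the two-cluster law (default
#'   \code{"valence"}).
#' @param clusters Two rating values used by \code{"two_cluster"}
#'   (default \code{c(2, 8)}).
#' @param seed Integer master seed; per-participant, per-trial and
#'   per-channel substreams are derived from it so identical configuration
#'   always reproduces identical arrays.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_trials = 40L, n_channels = 40L, n_samples = 8064L,
                         sample_rate = 128, bands = default_bands(),
                         band_gains = default_band_gains(),
                         noise_floor = 0.2,
                         rating_law = c("uniform", "two_cluster"),
                         target = "valence", clusters = c(2, 8),
                         seed = 1L) {
  rating_law <- match.arg(rating_law)
  hi <- max(vapply(bands, function(b) b$high, numeric(1)))
  if (hi > sample_rate / 2) {
    stop(sprintf("configuration error: band edge %g Hz above Nyquist (%g Hz)",
                 hi, sample_rate / 2), call. = FALSE)
  }
  if (!setequal(names(band_gains), names(bands))) {
    stop("band_gains must name exactly the bands in `bands`", call. = FALSE)
  }
  stopifnot(target %in% c("valence", "arousal", "dominance", "liking"),
            length(clusters) == 2L, all(clusters >= 1), all(clusters <= 9),
            noise_floor >= 0)
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 sample_rate = sample_rate, bands = bands,
                 band_gains = band_gains, noise_floor = noise_floor,
                 rating_law = rating_law, target = target,
                 clusters = clusters, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default rating-to-amplitude couplings
#'
#' Linear gains centred at 1 for the scale midpoint (rating 5), with slopes
#' below 1 so the amplitude stays positive across the full 1--9 range:
#' alpha is driven hardest by valence, theta and low beta by arousal,
#' high beta and gamma more weakly by valence. Giving every band some
#' dependence means even very short analysis windows (which can resolve
#' only the upper bands) retain part of the planted signal.
#'
#' @return Named list of functions, one per default band.
#' @export
default_band_gains <- function() {
  lin <- function(which, slope) {
    force(which); force(slope)
    function(r) 1 + slope * (r[[which]] - 5) / 4
  }
  list(theta     = lin("arousal", 0.6),
       alpha     = lin("valence", 0.8),
       low_beta  = lin("arousal", 0.5),
       high_beta = lin("valence", 0.4),
       gamma     = lin("valence", 0.3))
}

# Derived substream seed, kept inside the 32-bit integer range.
substream_seed <- function(seed, participant, trial = 0L, channel = 0L) {
  (as.double(seed) * 48271 + participant * 1299721 +
     trial * 7919 + channel) %% 2147483647
}

draw_ratings <- function(config, participant) {
  set.seed(substream_seed(config$seed, participant, 0L, 0L))
  r <- matrix(stats::runif(config$n_trials * 4, 1, 9),
              nrow = config$n_trials, ncol = 4,
              dimnames = list(NULL, c("valence", "arousal", "dominance", "liking")))
  if (config$rating_law == "two_cluster") {
    r[, config$target] <- sample(config$clusters, config$n_trials, replace = TRUE)
  }
  r
}

#' Generate one synthetic participant
#'
#' Fully reproducible from \code{config$seed} and \code{participant}:
#' ratings are drawn once per trial (mirroring per-video labels) and each
#' (trial, channel) signal comes from its own derived substream, so any
#' slice can be regenerated without regenerating the rest. The caller's
#' RNG state is left untouched.
#'
#' @param config A \code{\link{synth_config}}.
#' @param participant Integer participant number (default 1); also used to
#'   derive the participant's substreams.
#' @return An \code{\link{eeg_recording}}.
#' @examples
#' rec <- generate_participant(synth_config(n_trials = 2, n_channels = 3,
#'                                          n_samples = 256, seed = 7))
#' dim(rec)
#' @export
generate_participant <- function(config, participant = 1L) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  n <- config$n_samples
  fs <- config$sample_rate
  # per-bin frequency of the full (two-sided) DFT, mirrored above Nyquist
  i <- 0:(n - 1L)
  freq <- pmin(i, n - i) * fs / n
  band_mask <- lapply(config$bands, function(b) freq >= b$low & freq < b$high)

  ratings <- draw_ratings(config, participant)
  data <- array(0, dim = c(config$n_trials, config$n_channels, n))
  for (tr in seq_len(config$n_trials)) {
    amps <- vapply(names(config$bands), function(bn)
      config$band_gains[[bn]](as.list(ratings[tr, ])), numeric(1))
    if (any(amps < 0)) {
      stop("configuration error: negative band amplitude from band_gains",
           call. = FALSE)
    }
    gain <- rep(config$noise_floor, n)
    for (bi in seq_along(band_mask)) {
      gain[band_mask[[bi]]] <- gain[band_mask[[bi]]] + amps[[bi]]
    }
    for (ch in seq_len(config$n_channels)) {
      set.seed(substream_seed(config$seed, participant, tr, ch))
      z <- stats::rnorm(n)
      data[tr, ch, ] <- Re(stats::fft(stats::fft(z) * gain, inverse = TRUE)) / n
    }
  }
  eeg_recording(data, ratings, sample_rate = fs,
                participant_id = sprintf("synth%02d", participant))
}
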