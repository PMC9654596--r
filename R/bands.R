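#' Define a named frequency band
#'
#' A band is a half-open frequency interval \code{[low, high)} in Hz.
#' Half-open edges guarantee that adjacent bands in a bank never claim the
#' same FFT bin twice.
#'
#' @param name Band name, e.g. \code{"alpha"}.
#' @param low Lower edge in Hz (inclusive). Must be > 0, so the DC bin can
#'   never fall inside a band.
#' @param high Upper edge in Hz (exclusive). Must be > \code{low}.
#' @return An object of class \code{band_spec}.
#' @examples
#' band_spec("alpha", 8, 12)
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || low <= 0 || high <= low) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: [%g, %g) Hz>\n", x$name, x$low, x$high))
  invisible(x)
}

#' The default five-band bank
#'
#' Theta 4--8, alpha 8--12, low beta 12--16, high beta 16--25 and gamma
#' 25--45 Hz. The whole bank sits inside the 4--45 Hz pass-band of
#' DEAP-style preprocessed EEG.
#'
#' @return A named list of five \code{\link{band_spec}} objects.
#' @export
default_bands <- function() {
  list(
    theta     = band_spec("theta",      4,  8),
    alpha     = band_spec("alpha",      8, 12),
    low_beta  = band_spec("low_beta",  12, 16),
    high_beta = band_spec("high_beta", 16, 25),
    gamma     = band_spec("gamma",     25, 45)
  )
}

#' Map a band onto one-sided FFT bin indices
#'
#' For a window of \code{W} samples at sampling rate \code{Fs}, bin \code{k}
#' of the DFT corresponds to frequency \code{k * Fs / W}. The band claims
#' every one-sided bin (0 .. floor(W/2)) whose frequency lies in
#' \code{[low, high)}. The set may legitimately be empty when the spectral
#' resolution \code{Fs / W} is too coarse for the band.
#'
#' @param W Window length in samples.
#' @param Fs Sampling rate in Hz.
#' @param band A \code{\link{band_spec}}.
#' @return Integer vector of zero-based bin indices (possibly empty).
#' @examples
#' band_bins(256, 128, band_spec("theta", 4, 8))  # bins 8..15
#' @export
band_bins <- function(W, Fs, band) {
  stopifnot(inherits(band, "band_spec"))
  if (!is.numeric(W) || length(W) != 1L || W < 1) {
    stop("W must be a positive window length", call. = FALSE)
  }
  k <- 0:(W %/% 2)
  f <- k * Fs / W
  k[f >= band$low & f < band$high]
}
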