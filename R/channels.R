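#' Electrode layout of DEAP-style preprocessed recordings
#'
#' The preprocessed DEAP files order their 32 EEG channels in the "Geneva"
#' convention, left hemisphere front-to-back first, then the right.
#' Internally the package stores zero-based indices (row/array offsets);
#' all user-facing interfaces use electrode names.
#'
#' @return Character vector of the 32 EEG electrode names in Geneva order.
#' @export
geneva_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' The 14 study electrodes
#'
#' The electrode subset of the Emotiv EPOC+-style montage used for feature
#' extraction: Fp1, AF3, F3, F7, FC1, P3, PO3, Fp2, Fz, F4, F8, C4, P4, PO4.
#'
#' @return Character vector of 14 electrode names.
#' @export
default_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC1", "P3", "PO3",
    "Fp2", "Fz", "F4", "F8", "C4", "P4", "PO4")
}

#' Resolve electrode names to channel indices
#'
#' Order-preserving lookup of electrode names in a channel map. The lookup
#' is injective on distinct names: duplicated input names map to the same
#' index, distinct names never collide.
#'
#' @param names Character vector of electrode names.
#' @param map Character vector of the full channel ordering
#'   (default \code{\link{geneva_channels}()}).
#' @param base Index base of the returned indices, 1 (R convention,
#'   default) or 0 (array-offset convention).
#' @return Integer vector of indices, same length and order as \code{names}.
#' @examples
#' resolve_channels(c("Fp1", "Fz"))        # 1, 19
#' resolve_channels(default_channels())    # the 14 study indices
#' @export
resolve_channels <- function(names, map = geneva_channels(), base = 1L) {
  stopifnot(is.character(names), is.character(map), base %in% c(0L, 1L))
  if (anyDuplicated(map)) {
    stop("channel map must be a bijection: duplicated electrode names", call. = FALSE)
  }
  idx <- match(names, map)
  if (anyNA(idx)) {
    stop(sprintf("unknown electrode name(s): %s; valid names are: %s",
                 paste(names[is.na(idx)], collapse = ", "),
                 paste(map, collapse = ", ")), call. = FALSE)
  }
  as.integer(idx - 1L + base)
}
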