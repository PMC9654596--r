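#' Binarize a self-assessment rating
#'
#' Ratings on the 1--9 scale split into class 0 (\code{[1, 5)}) and
#' class 1 (\code{[5, 9]}); a rating of exactly 5 is class 1.
#'
#' @param r Numeric vector of ratings in [1, 9].
#' @return Integer vector of 0/1 class labels.
#' @examples
#' binarize_rating(c(4.9, 5, 1, 9))  # 0 1 0 1
#' @export
binarize_rating <- function(r) {
  if (anyNA(r) || any(r < 1) || any(r > 9)) {
    stop("validation error: ratings must lie in [1, 9]", call. = FALSE)
  }
  as.integer(r >= 5)
}

#' One-hot encode 0/1 class labels
#'
#' @param y Integer vector of 0/1 labels.
#' @return Matrix [n x 2]; each row sums to 1.
#' @export
one_hot <- function(y) {
  stopifnot(all(y %in% c(0L, 1L)))
  cbind(class0 = as.numeric(y == 0L), class1 = as.numeric(y == 1L))
}

#' Append complementary-rating extension columns
#'
#' Feature extension appends the trial's other self-assessment ratings as
#' extra input columns when predicting a target rating. Modes:
#' \code{"none"} appends nothing, \code{"FE-L"} liking, \code{"FE-L-D"}
#' liking + dominance, \code{"FE-3"} the three ratings other than the
#' target. The target rating itself is structurally excluded, so the
#' label can never leak in directly; the deliberate use of correlated
#' companion ratings is the method itself. Appended columns follow the
#' fixed rating order (valence, arousal, dominance, liking restricted to
#' the appended set) so saved models stay portable.
#'
#' @param M A \code{feature_matrix} carrying per-window ratings.
#' @param mode One of \code{"none"}, \code{"FE-L"}, \code{"FE-L-D"},
#'   \code{"FE-3"}.
#' @param target The prediction target, \code{"valence"} or
#'   \code{"arousal"}.
#' @return A \code{feature_matrix} with 70/71/72/73 columns for the
#'   default bank under none/FE-L/FE-L-D/FE-3.
#' @export
extend_features <- function(M, mode = c("none", "FE-L", "FE-L-D", "FE-3"),
                            target = c("valence", "arousal")) {
  stopifnot(inherits(M, "feature_matrix"))
  mode <- match.arg(mode)
  target <- match.arg(target)
  if (!target %in% colnames(M$ratings)) {
    stop("validation error: target rating missing from feature matrix", call. = FALSE)
  }
  appended <- switch(mode,
    "none"   = character(0),
    "FE-L"   = "liking",
    "FE-L-D" = c("dominance", "liking"),
    "FE-3"   = setdiff(c("valence", "arousal", "dominance", "liking"), target))
  appended <- intersect(c("valence", "arousal", "dominance", "liking"), appended)
  if (target %in% appended) stop("internal error: target in extension", call. = FALSE)
  if (length(appended)) {
    M$values <- cbind(M$values, M$ratings[, appended, drop = FALSE])
    M$feature_names <- c(M$feature_names, appended)
    colnames(M$values) <- M$feature_names
  }
  M$extension <- mode
  M
}

#' Split indices into train and test sets
#'
#' Seeded shuffle then partition. The train size is
#' \code{round(fraction * n)} exactly, train and test are disjoint and
#' exhaustive. With \code{unit = "window-row"} individual rows are
#' shuffled, which reproduces the published split sizes but places
#' windows of the same trial on both sides (an optimistic-evaluation
#' caveat); \code{unit = "trial"} keeps all windows of one trial on one
#' side of the split.
#'
#' @param n_total Number of rows.
#' @param fraction Train fraction in (0, 1).
#' @param seed Shuffle seed.
#' @param unit \code{"window-row"} (default) or \code{"trial"}.
#' @param trials With \code{unit = "trial"}: integer vector of length
#'   \code{n_total} giving each row's trial id.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @examples
#' s <- split_indices(624640, 0.75, seed = 1)
#' length(s$train)  # 468480
#' @export
split_indices <- function(n_total, fraction, seed = 1L,
                          unit = c("window-row", "trial"), trials = NULL) {
  unit <- match.arg(unit)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("configuration error: fraction must lie in (0, 1)", call. = FALSE)
  }
  if (n_total < 2) stop("need at least 2 rows to split", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (unit == "window-row") {
    perm <- sample.int(n_total)
    n_train <- round(fraction * n_total)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]))
  } else {
    if (is.null(trials) || length(trials) != n_total) {
      stop("unit = 'trial' needs a per-row `trials` vector", call. = FALSE)
    }
    ids <- unique(trials)
    perm <- sample(ids)
    n_train_trials <- round(fraction * length(ids))
    tr_ids <- perm[seq_len(n_train_trials)]
    list(train = which(trials %in% tr_ids),
         test = which(!trials %in% tr_ids))
  }
}

#' Convert a feature matrix to model-ready tensors
#'
#' Binarizes the target rating, one-hot encodes it, and adds the trailing
#' singleton axis the 1-d convolutional input expects.
#'
#' @param M A \code{feature_matrix} (standardized, unless
#'   \code{allow_raw = TRUE}).
#' @param target \code{"valence"} or \code{"arousal"}.
#' @param allow_raw Permit an unstandardized matrix (default FALSE).
#' @return List with \code{x} array [n x width x 1], \code{y} one-hot
#'   matrix [n x 2], and \code{labels} the integer 0/1 vector.
#' @export
to_model_tensors <- function(M, target = c("valence", "arousal"),
                             allow_raw = FALSE) {
  stopifnot(inherits(M, "feature_matrix"))
  target <- match.arg(target)
  if (!isTRUE(M$standardized) && !allow_raw) {
    stop("feature matrix is not standardized; pass allow_raw = TRUE to override",
         call. = FALSE)
  }
  if (anyNA(M$values)) stop("validation error: NaN/NA in inputs", call. = FALSE)
  y <- binarize_rating(M$ratings[, target])
  x <- array(M$values, dim = c(nrow(M$values), ncol(M$values), 1L))
  list(x = x, y = one_hot(y), labels = y)
}
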