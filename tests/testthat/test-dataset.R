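test_that("rating binarization follows the 5-boundary with class 1 at 5", {
  expect_identical(binarize_rating(c(4.9, 5, 1, 9)), c(0L, 1L, 0L, 1L))
  expect_error(binarize_rating(0.5), "\\[1, 9\\]")
  expect_error(binarize_rating(9.5), "\\[1, 9\\]")
})

test_that("one-hot rows sum to one and re-encoding is idempotent", {
  y <- c(0L, 1L, 1L, 0L)
  oh <- one_hot(y)
  expect_identical(unname(rowSums(oh)), rep(1, 4))
  expect_identical(max.col(oh) - 1L, y)
  expect_identical(one_hot(max.col(oh) - 1L), oh)
})

test_that("feature extension appends the documented columns and never the target", {
  rec <- tiny_recording(n_trials = 2, n_channels = 3, n_samples = 128)
  fm <- extract_features(rec, channels = "Fp1",
                         channel_map = geneva_channels()[1:3], W = 64, S = 16)
  w0 <- ncol(fm$values)
  expect_identical(ncol(extend_features(fm, "none", "valence")$values), w0)
  expect_identical(ncol(extend_features(fm, "FE-L", "valence")$values), w0 + 1L)
  expect_identical(ncol(extend_features(fm, "FE-L-D", "valence")$values), w0 + 2L)
  fe3 <- extend_features(fm, "FE-3", "valence")
  expect_identical(ncol(fe3$values), w0 + 3L)
  expect_identical(utils::tail(fe3$feature_names, 3),
                   c("arousal", "dominance", "liking"))
  fe3a <- extend_features(fm, "FE-3", "arousal")
  expect_identical(utils::tail(fe3a$feature_names, 3),
                   c("valence", "dominance", "liking"))
  # the appended values are the per-window ratings themselves
  expect_identical(unname(fe3$values[, "liking"]), unname(fm$ratings[, "liking"]))
  for (mode in c("FE-L", "FE-L-D", "FE-3")) {
    ext <- extend_features(fm, mode, "valence")
    expect_false("valence" %in% ext$feature_names)
  }
})

test_that("row-level splits reproduce the published sizes exactly", {
  s <- split_indices(624640, 0.75, seed = 1)
  expect_length(s$train, 468480L)
  expect_length(s$test, 156160L)
  expect_length(split_indices(624640, 0.80, seed = 1)$train, 499712L)
  s5 <- split_indices(100, 0.5, seed = 2)
  expect_length(s5$train, 50L)
  expect_length(intersect(s5$train, s5$test), 0L)
  expect_identical(sort(c(s5$train, s5$test)), 1:100)
  expect_error(split_indices(100, 1.5, 1), "configuration error")
})

test_that("splits are seed-deterministic with identical sizes across seeds", {
  a <- split_indices(1000, 0.7, seed = 11)
  b <- split_indices(1000, 0.7, seed = 11)
  c_ <- split_indices(1000, 0.7, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$train, c_$train))
  expect_identical(length(a$train), length(c_$train))
})

test_that("trial-unit splitting keeps all windows of a trial on one side", {
  trials <- rep(1:10, each = 20)
  s <- split_indices(200, 0.7, seed = 3, unit = "trial", trials = trials)
  expect_length(intersect(unique(trials[s$train]), unique(trials[s$test])), 0L)
  expect_identical(sort(c(s$train, s$test)), 1:200)
  expect_length(unique(trials[s$train]), 7L)
})

test_that("tensor conversion adds the singleton axis and one-hot labels", {
  rec <- tiny_recording(n_trials = 2, n_channels = 3, n_samples = 128)
  fm <- extract_features(rec, channels = "Fp1",
                         channel_map = geneva_channels()[1:3], W = 64, S = 16)
  fm <- extend_features(fm, "FE-3", "valence")
  std <- standardize_features(fm)
  tens <- to_model_tensors(std$M, "valence")
  expect_identical(dim(tens$x), c(nrow(fm$values), 8L, 1L))
  expect_identical(dim(tens$y), c(nrow(fm$values), 2L))
  expect_identical(unname(rowSums(tens$y)), rep(1, nrow(fm$values)))
  # squeezing the singleton axis recovers the matrix exactly
  expect_identical(matrix(tens$x, nrow = dim(tens$x)[1]),
                   unname(std$M$values))
  # unstandardized input is refused unless explicitly allowed
  expect_error(to_model_tensors(fm, "valence"), "not standardized")
  expect_silent(to_model_tensors(fm, "valence", allow_raw = TRUE))
})

test_that("constant ratings produce a single one-hot column", {
  rec <- tiny_recording(n_trials = 2, n_channels = 3, n_samples = 128)
  rec$ratings[, "valence"] <- 9
  fm <- extract_features(rec, channels = "Fp1",
                         channel_map = geneva_channels()[1:3], W = 64, S = 16)
  tens <- to_model_tensors(fm, "valence", allow_raw = TRUE)
  expect_identical(unname(colSums(tens$y)), c(0, nrow(fm$values)))
})

test_that("NaN inputs are rejected at tensor conversion", {
  rec <- tiny_recording(n_trials = 2, n_channels = 3, n_samples = 128)
  fm <- extract_features(rec, channels = "Fp1",
                         channel_map = geneva_channels()[1:3], W = 64, S = 16)
  fm$values[1, 1] <- NaN
  expect_error(to_model_tensors(fm, "valence", allow_raw = TRUE), "NaN")
})
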