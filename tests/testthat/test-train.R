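test_that("metric identities hold exactly for random confusion counts", {
  set.seed(17)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tn <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp + tn + fn == 0) next
    m <- metrics_from_counts(tp, fp, tn, fn)
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (fn + tp > 0) expect_equal(m$recall, tp / (fn + tp))
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
      # harmonic <= geometric <= arithmetic mean of (precision, recall)
      expect_lte(m$f1, sqrt(m$precision * m$recall) + 1e-12)
      expect_lte(sqrt(m$precision * m$recall),
                 (m$precision + m$recall) / 2 + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("the hand-worked (1,1,1,1) case gives one half across the board", {
  m <- metrics_from_counts(1, 1, 1, 1)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  expect_false(m$undefined)
})

test_that("degenerate denominators report zero with an explicit flag", {
  m <- metrics_from_counts(0, 0, 5, 3)
  expect_equal(m$precision, 0)
  expect_true(m$undefined)
})

test_that("a perfect predictor scores 1 on every metric", {
  net <- threshold_net()
  x <- array(c(-1, -1, 1, 1), c(4, 1, 1))
  y <- one_hot(c(0L, 0L, 1L, 1L))
  rep <- evaluate(net, list(x = x, y = y))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$per_class$precision, c(1, 1))
  expect_equal(rep$per_class$recall, c(1, 1))
  expect_equal(rep$per_class$f1, c(1, 1))
  expect_identical(rep$per_class$support, c(2L, 2L))
})

test_that("report accuracy equals an independent misclassification count", {
  net <- threshold_net()
  set.seed(6)
  x <- array(rnorm(40), c(40, 1, 1))
  y <- one_hot(sample(0:1, 40, replace = TRUE))
  rep <- evaluate(net, list(x = x, y = y))
  expect_equal(rep$accuracy,
               1 - sum(rep$predicted != (max.col(y) - 1L)) / 40)
  expect_identical(sum(rep$per_class$support), 40L)
  expect_error(evaluate(net, list(x = array(0, c(0, 1, 1)),
                                  y = matrix(0, 0, 2))), "empty")
})

test_that("zero-epoch training is a no-op with an empty trace", {
  net <- build_model("C1D2", 8, seed = 3)
  x <- array(rnorm(20 * 8), c(20, 8, 1))
  y <- one_hot(sample(0:1, 20, replace = TRUE))
  fit <- train_model(net, list(x = x, y = y), train_config(epochs = 0))
  expect_identical(fit$net$layers, net$layers)
  expect_identical(nrow(fit$history), 0L)
})

test_that("training is reproducible under a fixed seed and reduces the loss", {
  set.seed(30)
  n <- 120
  x <- array(c(rnorm(n / 2, -2), rnorm(n / 2, 2)), c(n, 1, 1))
  x <- array(x[, rep(1, 6), , drop = FALSE], c(n, 6, 1))
  y <- one_hot(rep(0:1, each = n / 2))
  net <- cnn_build(list(layer_conv1d(4, 3, "same"), layer_flatten(),
                        layer_dense(2, "softmax")), input_width = 6, seed = 2)
  cfg <- train_config(epochs = 5, batch_size = 20, seed = 10)
  f1 <- train_model(net, list(x = x, y = y), cfg)
  f2 <- train_model(net, list(x = x, y = y), cfg)
  expect_identical(f1$history, f2$history)
  expect_lt(utils::tail(f1$history$loss, 1), f1$history$loss[1])
  expect_gt(utils::tail(f1$history$train_acc, 1), 0.9)
})

test_that("the fitted-model object carries methods end to end", {
  cfg <- synth_config(n_trials = 6, n_channels = 32, n_samples = 512,
                      rating_law = "two_cluster", seed = 8)
  rec <- generate_participant(cfg)
  fm <- extend_features(extract_features(rec, W = 128, S = 64), "FE-3", "valence")
  fit <- eeg_cnn(fm, "valence", variant = "C1D2",
                 config = train_config(epochs = 2, batch_size = 32, seed = 4))
  expect_s3_class(fit, "eeg_cnn")
  expect_identical(nrow(fit$history), 2L)
  out <- utils::capture.output(print(fit))
  expect_true(any(grepl("held-out accuracy", out)))
  p <- predict(fit, fm)
  expect_identical(dim(p), c(nrow(fm$values), 2L))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  cls <- predict(fit, fm, type = "class")
  expect_true(all(cls %in% 0:1))
  cf <- coef(fit)
  expect_true(any(!vapply(cf, is.null, logical(1))))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("split sweep partitions every fraction exhaustively", {
  cfg <- synth_config(n_trials = 4, n_channels = 32, n_samples = 512,
                      rating_law = "two_cluster", seed = 9)
  rec <- generate_participant(cfg)
  fm <- extend_features(extract_features(rec, W = 128, S = 128), "FE-3", "valence")
  tab <- run_split_sweep(fm, fractions = c(0.75, 0.5),
                         config = train_config(epochs = 1, batch_size = 16, seed = 2))
  n <- nrow(fm$values)
  expect_identical(tab$train_size + tab$test_size, rep(n, 2L))
  expect_identical(tab$train_class0 + tab$train_class1, tab$train_size)
  expect_identical(tab$test_class0 + tab$test_class1, tab$test_size)
  expect_identical(tab$seed, rep(2L, 2L))
})
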