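test_that("window planning matches the published per-trial counts", {
  expect_length(plan_windows(8064, 256, 16)$starts, 488L)
  expect_length(plan_windows(8064, 1024, 16)$starts, 440L)
  expect_length(plan_windows(256, 256, 16)$starts, 0L)
  expect_error(plan_windows(100, 0, 16), "configuration error")
  expect_error(plan_windows(100, 16, 0), "configuration error")
})

test_that("window planning equals brute-force enumeration of the strict rule", {
  for (L in c(1, 2, 63, 64, 65, 255, 256, 257, 1000, 8064, 9999)) {
    for (W in c(4, 16, 255, 256, 1024)) {
      for (S in c(1, 7, 16, 64)) {
        p <- plan_windows(L, W, S)
        expect_identical(p$starts, as.integer(enumerate_starts(L, W, S)),
                         info = sprintf("L=%d W=%d S=%d", L, W, S))
        expect_true(all(p$starts + W < L))
        expect_true(!is.unsorted(p$starts))
      }
    }
  }
})

test_that("full-cohort window algebra reproduces every published row count", {
  tab <- window_count_table()
  expect_identical(tab$total,
                   c(645120L, 645120L, 643840L, 642560L, 640000L,
                     634880L, 624640L, 604160L, 563200L))
  expect_identical(tab$train_size + tab$test_size, tab$total)
  expect_equal(tab$time_slice_s[1], 0.03125)
})

test_that("band bins follow the half-open [low, high) rule at each resolution", {
  bands <- default_bands()
  expect_identical(band_bins(256, 128, bands$theta), 8:15)
  expect_identical(band_bins(4, 128, bands$theta), integer(0))
  expect_identical(band_bins(128, 128, bands$gamma), 25:44)
  # adjacent bands never share a bin, and DC is never claimed
  for (W in c(16, 64, 256, 1024)) {
    all_bins <- unlist(lapply(bands, function(b) band_bins(W, 128, b)))
    expect_identical(anyDuplicated(all_bins), 0L)
    expect_false(0L %in% all_bins)
  }
})

test_that("band power equals the direct-DFT oracle on seeded random windows", {
  bands <- default_bands()
  set.seed(2024)
  worst <- 0
  for (i in 1:60) {
    W <- sample(c(32, 64, 128, 256), 1)
    x <- rnorm(W)
    got <- band_power(x, 128, bands)
    want <- direct_band_power(x, 128, bands)
    worst <- max(worst, abs(got - want) / pmax(abs(want), 1e-300))
  }
  expect_lt(worst, 1e-9)
})

test_that("an on-bin 10 Hz sinusoid concentrates its power in alpha", {
  x <- sin(2 * pi * 10 * (0:255) / 128)
  p <- band_power(x, 128, default_bands())
  expect_gt(p[["alpha"]], 100 * max(p[setdiff(names(p), "alpha")]))
  expect_equal(unname(band_power(numeric(256), 128, default_bands())),
               rep(0, 5))
})

test_that("feature extraction yields the documented shapes and provenance", {
  rec <- tiny_recording(n_trials = 2, n_channels = 5, n_samples = 300)
  fm <- extract_features(rec, channels = c("Fp1", "AF3"),
                         channel_map = geneva_channels()[1:5],
                         W = 64, S = 32)
  npt <- n_windows(300, 64, 32)
  expect_identical(dim(fm), c(2L * npt, 2L * 5L))
  expect_identical(fm$feature_names[1:5],
                   paste0("Fp1_", names(default_bands())))
  expect_identical(fm$provenance$trial, rep(1:2, each = npt))
  # every row carries its trial's ratings
  expect_identical(unname(fm$ratings[npt + 1, ]), unname(rec$ratings[2, ]))

  # single-trial recording at the full DEAP geometry: 488 x 70
  rec1 <- tiny_recording(n_trials = 1, n_channels = 32, n_samples = 8064)
  fm1 <- extract_features(rec1)
  expect_identical(dim(fm1), c(488L, 70L))
})

test_that("extraction equals per-window band_power applied by hand", {
  rec <- tiny_recording(n_trials = 1, n_channels = 3, n_samples = 200)
  fm <- extract_features(rec, channels = "F3",
                         channel_map = geneva_channels()[1:3], W = 64, S = 16)
  starts <- plan_windows(200, 64, 16)$starts
  for (w in seq_along(starts)) {
    seg <- rec$data[1, 3, starts[w] + 1:64]
    expect_equal(unname(fm$values[w, ]),
                 unname(band_power(seg, 128, default_bands())),
                 tolerance = 1e-12)
  }
})

test_that("permuting the band order permutes feature columns identically", {
  rec <- tiny_recording(n_trials = 1, n_channels = 3, n_samples = 256)
  fwd <- extract_features(rec, channels = c("Fp1", "F3"),
                          channel_map = geneva_channels()[1:3], W = 64, S = 64)
  rev_bands <- rev(default_bands())
  bwd <- extract_features(rec, channels = c("Fp1", "F3"),
                          channel_map = geneva_channels()[1:3], W = 64, S = 64,
                          bands = rev_bands)
  expect_identical(bwd$values[, bwd$feature_names],
                   fwd$values[, bwd$feature_names])
})

test_that("standardization hits exact zero mean / unit scale and inverts", {
  set.seed(5)
  m <- matrix(rnorm(200, mean = 3, sd = 4), 40, 5)
  std <- standardize_features(m)
  expect_lt(max(abs(colMeans(std$M))), 1e-9)
  pop_sd <- sqrt(colMeans(sweep(std$M, 2, colMeans(std$M))^2))
  expect_lt(max(abs(pop_sd - 1)), 1e-9)
  # stored statistics applied to new data then inverted recover the input
  new <- matrix(rnorm(50), 10, 5)
  z <- standardize_features(new, stats = std$stats)$M
  expect_equal(unstandardize_features(z, std$stats), new, tolerance = 1e-9)
})

test_that("zero-variance columns get scale 1 and a warning", {
  m <- cbind(const = rep(2, 10), x = rnorm(10))
  expect_warning(std <- standardize_features(m), "zero-variance")
  expect_equal(unname(std$M[, 1]), rep(0, 10))
  expect_equal(std$stats$scale[["const"]], 1)
})
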