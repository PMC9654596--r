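---
title: "Band-power features and residual 1D CNNs for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power features and residual 1D CNNs for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Affective computing from EEG asks whether a participant's self-reported
emotional state can be decoded from scalp potentials. The de-facto benchmark
layout is the DEAP one: 32 participants each watch 40 one-minute music
videos while 32-channel EEG is recorded, preprocessed to 128 Hz and
band-passed to 4--45 Hz, giving a 40 trials x 40 channels x 8064 samples
array per participant plus four self-assessment ratings per trial (valence,
arousal, dominance, liking, each on a continuous 1--9 scale). The decoding
task treated here is binary: ratings in [1, 5) form class 0 and [5, 9]
class 1, for valence or arousal.

`eegcnn` implements the full pipeline: sliding-window FFT band-power
features over 14 electrodes, optional "feature extension" with the
complementary ratings, and a ladder of five residual one-dimensional
convolutional classifiers, together with a seeded synthetic-EEG generator
so that every stage is testable without the access-gated original data.

## Feature extraction

Each trial's signal on each selected channel is cut into windows of `W`
samples advanced by a step of `S = 16`. A window starting at offset `s`
(zero-based) is included iff `s + W < L` strictly, with `L = 8064`; this is
the inclusion rule that reproduces the published per-trial window counts for
every window size from 4 to 1024 samples (488 windows per trial at
`W = 256`, hence 19,520 rows per participant and 624,640 for the cohort).
The full 63-second trial, including the 3-second pre-trial segment, enters
the plan: the printed counts are only consistent with `L = 8064`.

Each window is Fourier-transformed (no taper, no detrending -- the 4--45 Hz
band-pass of the source data makes detrending moot, and the aggregation
below is insensitive to spectral leakage at these bandwidths). Five bands
are aggregated: theta [4, 8), alpha [8, 12), low beta [12, 16), high beta
[16, 25) and gamma [25, 45) Hz. Band edges are half-open so adjacent bands
never double-count a bin, and every band floor is at or above 4 Hz, so the
DC bin is excluded by construction. Bin `k` of a `W`-point window maps to
`k * 128 / W` Hz; at small `W` the resolution is too coarse for the lower
bands, whose bin sets are then legitimately empty (power 0). That is the
mechanistic reason accuracy grows with window size in the window sweep: a
4-sample window resolves only a single 32 Hz bin.

The per-band statistic is the **sum of one-sided FFT magnitudes** over the
band's bins. Whether the original pipeline summed magnitudes, means or
squared magnitudes is not derivable from its description; the sum is used
here, pinned by an exact direct-DFT oracle in the tests. The choice only
rescales columns and is neutralized by the z-scoring that follows.

With the default 14 electrodes (Fp1, AF3, F3, F7, FC1, P3, PO3, Fp2, Fz,
F4, F8, C4, P4, PO4 -- the Emotiv EPOC+-style montage, resolved by name
against the Geneva channel order) and 5 bands, a window becomes a 70-value
row. Feature extension appends the complementary ratings -- none, liking
(FE-L), liking + dominance (FE-L-D), or all three non-target ratings
(FE-3, width 73). The target rating itself is structurally excluded from
the extension; feeding the *correlated* companion ratings to the classifier
is the method's deliberate design, not an accident, and is inherited here
as specified.

## Data preparation and its caveats

Columns are z-scored (population variance convention). Two protocol
details deserve explicit flags, both implemented as documented options:

* **Scaler leakage.** Statistics are fitted on the full matrix *before*
  splitting (`standardize_on = "all"`, the study protocol), which leaks
  test-set moments into training. `standardize_on = "train"` fits on the
  training rows only.
* **Split leakage.** The train/test split shuffles *window rows*
  (`split_unit = "window-row"`), so overlapping windows from the same trial
  land on both sides -- the only protocol that reproduces the published
  split sizes exactly (468,480 / 156,160 at `W = 256`, 75/25), but an
  optimistic one. `split_unit = "trial"` keeps whole trials on one side.
  The train size is `round(fraction * n)` exactly.

The validation set monitored during training *is* the held-out test set,
mirroring the source protocol (whose validation accuracy under drop-out
exceeds train accuracy); pass a separate `validation` list to
`train_model()` for a three-way protocol. Whether the original split
shuffled rows is unstated; a seeded shuffle is assumed, and every sweep
row records its seed.

## The architecture ladder

Five 1D-CNN variants form a parameter-reduction ladder; all but the
lightest carry a residual connection (a skip path adding an earlier
activation into a later convolution's output, through a width-matching
1x1 projection when the channel counts differ). Hidden activations are
rectified-linear, the output is a 2-way soft-max, and drop-out (which adds
no parameters) regularizes the dense stage.

The published architecture description fixes only the layer structure
(counts of convolution and dense layers, presence of the residual path)
and the exact trainable-parameter totals. The remaining hyper-parameters
-- filter counts, kernel widths, pooling and dense widths -- were chosen
within that structure by exhaustive search so that the parameter totals
match **exactly** at the FE-3 input width of 73; the totals are the one
bit-exact architectural fingerprint available, and the test suite enforces
all five. Dense-layer counts include the soft-max output layer.

| id | structure (input 73 x 1) | parameters |
|----|--------------------------|-----------:|
| M1 | Conv16k3v - Conv64k5 - pool - Conv256k5v - pool - Conv256k5 (+identity skip) - Dense1024 - Dense32 - Dense2 | 4,381,410 |
| C3D2 | Conv32k5 - pool - Conv128k5v - pool - Conv64k3 (+proj skip) - Dense16 - Dense2 | 70,130 |
| C2D2 | Conv96k7v - pool - Conv32k7 (+proj skip) - Dense32 - Dense2 | 59,298 |
| M2 | Conv24k3 - pool - Conv128k7 (+proj skip) - pool - Dense2 | 29,538 |
| C1D2 | Conv32k6 - pool - Dense16 - Dense2 | 18,706 |

(`v` marks valid padding; all other convolutions are zero-padded to
preserve length; `pool` is non-overlapping max pooling of width 2.)

The network engine itself -- im2col convolution, max pooling, dropout,
residual adds, soft-max cross-entropy, Adam -- is implemented in base R
with BLAS matrix products. Its correctness is established by
finite-difference gradient checks on a residual network and a naive
convolution oracle, not by convention. Training defaults are the study
settings (100 epochs, batch 100, Adam at 1e-3, categorical cross-entropy).
The `param_data_ratio()` denominator defaults to 384,000 -- the constant
the published ratio column back-computes to -- and is exposed as an
argument because it matches no array size in the pipeline.

## The synthetic generator

`synth_config()` describes a DEAP-shaped participant whose per-band power
carries a planted dependence on the ratings. Each (trial, channel) signal
is white noise spectrally shaped per band -- band-limited noise rather than
pure tones, so FFT features have realistic within-band spread and the
classification problem is not degenerate -- plus a broadband noise floor
(default 0.2 relative amplitude). Default couplings are linear in the
rating, centred at the scale midpoint: alpha is driven hardest by valence
(slope 0.8), theta and low beta by arousal (0.6, 0.5), high beta and gamma
weakly by valence (0.4, 0.3). Giving *every* band some slope means even
4-sample windows (which resolve only the 32 Hz bin) retain part of the
signal, so the window sweep degrades gracefully rather than cliff-dropping.
Ratings are drawn once per trial (as per-video labels are); the
`two_cluster` law pins the target rating to {2, 8} for a cleanly separable
two-class design. A single master seed derives per-participant, per-trial
and per-channel substreams, so any slice regenerates stably and the
caller's RNG state is never disturbed.

What the generator does *not* emulate: 1/f spectral slope, artifacts,
inter-channel covariance structure, non-stationarity, or any genuine
physiology. Passing tests on synthetic data therefore demonstrate that the
pipeline's mechanics are correct and that planted band-power/rating
dependence of realistic strength is recoverable end to end -- they say
nothing about accuracy attainable on real recordings, and the published
headline accuracies on the original dataset are deliberately not claimed
or reproduced here.

## Problem sizes used in the checks

The test suite exercises the published *geometry* at full scale (window
algebra for 32 x 40 trials, 19,520 x 70 per-participant matrices) but
trains networks at reduced scale, chosen as the smallest sizes at which the
properties under test are stable: the end-to-end separability check trains
M2 on four synthetic participants (78,080 windows) for 2 epochs; the
label-shuffle null and the nine-point window sweep use one participant and
1 epoch. On strongly separable two-cluster data the M2 training accuracy
exceeds 99% within the first epoch, so longer schedules add nothing to
these checks.

## Numerical and degenerate-input choices

* Zero-variance feature columns get a substitute scale of 1 and a warning
  (they become all-zero columns, not NaN).
* Precision/recall with an empty denominator are reported as 0 with an
  explicit `undefined` flag, never dropped.
* Max pooling ties resolve to the earliest position; a trailing remainder
  shorter than the pool width is dropped (floor semantics).
* `W = L` trials yield zero windows (the strict rule), an empty but legal
  plan.
* Non-finite training loss aborts with a diagnostic rather than continuing.
* Reported test accuracy is the final-epoch value; the full per-epoch trace
  (train and validation) is returned for plotting either.

## A worked example

```{r, eval = FALSE}
library(eegcnn)

cfg  <- synth_config(rating_law = "two_cluster", seed = 1)
recs <- lapply(1:4, function(p) generate_participant(cfg, p))

fm  <- rbind_features(lapply(recs, extract_features, W = 256, S = 16))
fe3 <- extend_features(fm, "FE-3", target = "valence")

fit <- eeg_cnn(fe3, target = "valence", variant = "M2",
               config = train_config(epochs = 2, seed = 7))
print(fit)
summary(fit)   # layer table + per-class precision/recall/F1/support
plot(fit)      # train vs validation accuracy per epoch
```
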