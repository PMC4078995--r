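cfg <- preproc_config()

test_that("band-pass filter rejects DC and out-of-band components, keeps the passband", {
  tt <- seq(0, 300, by = 0.1)
  mid <- 800:2200  # away from edges

  # constant input is pure DC
  expect_lt(max(abs(bandpass_filter(rep(5, 3001), 0.1, cfg))), 0.05)

  # 0.1 Hz is deep in the passband: amplitude preserved within 5%
  y <- bandpass_filter(sin(2 * pi * 0.1 * tt), 0.1, cfg)
  expect_gt(max(abs(y[mid])), 0.95)
  expect_lt(max(abs(y[mid])), 1.05)

  # 2.5 Hz sits in the stopband: attenuated below 10%
  y <- bandpass_filter(sin(2 * pi * 2.5 * tt), 0.1, cfg)
  expect_lt(max(abs(y[mid])), 0.10)

  # >= 20 dB attenuation (ratio <= 0.1) at 0.001 Hz and at 3 Hz
  y <- bandpass_filter(sin(2 * pi * 0.001 * tt), 0.1, cfg)
  expect_lt(max(abs(y[mid])), 0.1)
  y <- bandpass_filter(sin(2 * pi * 3 * tt), 0.1, cfg)
  expect_lt(max(abs(y[mid])), 0.1)
})

test_that("filter is near-idempotent in the passband and errors on short input", {
  tt <- seq(0, 300, by = 0.1)
  mid <- 800:2200
  y1 <- bandpass_filter(sin(2 * pi * 0.1 * tt), 0.1, cfg)
  y2 <- bandpass_filter(y1, 0.1, cfg)
  expect_lt(max(abs(y2[mid] - y1[mid])) / max(abs(y1[mid])), 0.10)

  expect_error(bandpass_filter(rnorm(10), 0.1, cfg), "too short")
  expect_error(bandpass_filter(rnorm(100), 0.1,
                               preproc_config(band_high = 6)), "Nyquist")
})

test_that("Z-scoring matches the hand-computed baseline convention", {
  # baseline {1,1,3,3}: mean 2, population SD 1; test sample 4 -> d = 2
  vals <- c(1, 1, 3, 3, rep(4, 11))
  trial <- make_trial_df(list(vals), dt = 1, t_start = -4)
  cfg4 <- preproc_config(zscore_baseline = 4, expected_channels = 1)
  z <- zscore_trial(trial, cfg4, filter = FALSE)
  expect_equal(z$z[z$time_s >= 0], rep(2, 11))

  # sample-SD convention: SD = 2/sqrt(3)
  cfg4s <- preproc_config(zscore_baseline = 4, expected_channels = 1,
                          sd_type = "sample")
  zs <- zscore_trial(trial, cfg4s, filter = FALSE)
  expect_equal(zs$z[zs$time_s >= 0], rep(2 / (2 / sqrt(3)), 11))

  # test samples identical to the baseline mean give d = 0
  trial0 <- make_trial_df(list(c(1, 3, 1, 3, rep(2, 11))), dt = 1,
                          t_start = -4)
  z0 <- zscore_trial(trial0, cfg4, filter = FALSE)
  expect_equal(z0$z[z0$time_s >= 0], rep(0, 11))

  # zero baseline SD is an error naming the channel
  trialc <- make_trial_df(list(c(rep(2, 4), rep(4, 11))), dt = 1,
                          t_start = -4)
  expect_error(zscore_trial(trialc, cfg4, filter = FALSE), "zero baseline SD")
})

test_that("Z-scores are invariant under positive affine transforms of the input", {
  set.seed(42)
  x <- cumsum(rnorm(301)) / 5 + sin(seq(0, 30, by = 0.1))
  t1 <- make_trial_df(list(x), dt = 0.1, t_start = -20)
  t2 <- make_trial_df(list(3.7 * x + 11), dt = 0.1, t_start = -20)
  cfg1 <- preproc_config(expected_channels = 1)
  # exact without filtering (the Z-score is affine-invariant analytically)
  expect_equal(zscore_trial(t1, cfg1, filter = FALSE)$z,
               zscore_trial(t2, cfg1, filter = FALSE)$z)
  # with filtering: the offset leaves a small DC transient, so equality is
  # to numerical tolerance only
  z1 <- zscore_trial(t1, cfg1)
  z2 <- zscore_trial(t2, cfg1)
  expect_equal(z1$z, z2$z, tolerance = 1e-2)
})

test_that("feature extraction averages the closed [3, 10] s window", {
  # linear ramp 0 -> 7 over 0..10 s: brute-force mean of included samples
  time_s <- seq(-3, 10, by = 0.1)
  z <- tibble::tibble(channel = 1L, time_s = time_s, z = 0.7 * pmax(time_s, 0))
  f <- extract_features(z, preproc_config(expected_channels = 1))
  inc <- time_s >= 3 & time_s <= 10
  expect_equal(f$feature, mean(0.7 * time_s[inc]))
  # boundary samples at exactly 3.0 and 10.0 s are included
  expect_equal(sum(inc), 71)

  # constant Z over the window
  zc <- tibble::tibble(channel = 1L, time_s = time_s, z = 1.5)
  expect_equal(extract_features(zc, preproc_config(expected_channels = 1))$feature, 1.5)

  # one sample in window
  z1 <- tibble::tibble(channel = 1L, time_s = c(0, 5), z = c(9, -2))
  expect_equal(extract_features(z1, preproc_config(expected_channels = 1))$feature, -2)

  # empty window errors
  z0 <- tibble::tibble(channel = 1L, time_s = c(-1, 0), z = c(0, 0))
  expect_error(extract_features(z0, preproc_config(expected_channels = 1)),
               "feature window")
})

test_that("QC retains only complete trials and accounts for every trial", {
  spec <- fnirs_sim_spec(n_trials_per_group = 3, n_channels = 4,
                         dropout_rate = 0)
  sim <- simulate_fnirs_trials(spec, seed = 5)
  cfg4 <- preproc_config(expected_channels = 4)

  qc <- qc_trials(sim$trials, cfg4)
  expect_true(all(qc$retained))

  # drop one channel from trial 2 entirely -> incomplete channel set
  broken <- dplyr::filter(sim$trials, !(trial == 2 & channel == 3))
  qc2 <- qc_trials(broken, cfg4)
  expect_false(qc2$retained[qc2$trial == 2])
  expect_match(qc2$reason[qc2$trial == 2], "incomplete")

  # gap markers (NA) in one channel of two trials -> those two rejected
  gappy <- sim$trials
  gappy$oxyhb[gappy$trial %in% c(1, 4) & gappy$channel == 2 &
                gappy$time_s > 5] <- NA
  qc3 <- qc_trials(gappy, cfg4)
  expect_equal(sum(!qc3$retained), 2)
  expect_equal(sum(qc3$retained) + sum(!qc3$retained), 6)
  expect_equal(sort(qc3$trial[!qc3$retained]), c(1, 4))
})

test_that("feature table has one row per retained trial and supports restriction", {
  feats <- paperlike_features50(seed = 1)
  expect_equal(dim(feats), c(50, 3 + 24))
  expect_equal(sum(feats$label == 1), 25)
  expect_equal(sum(feats$label == -1), 25)

  fm <- features_matrix(feats)
  expect_equal(dim(fm$X), c(50, 24))
  expect_equal(fm$channel_ids, 1:24)

  # hemispheric restriction: right = channels 13..24
  sim <- simulate_fnirs_trials(fnirs_sim_spec(n_trials_per_group = 2,
                                              n_channels = 4), seed = 2)
  cfg4 <- preproc_config(expected_channels = 4)
  right <- fnirs_features(sim$trials, cfg4, channels = "right")
  expect_equal(grep("^ch", names(right), value = TRUE), c("ch03", "ch04"))

  # a single trial still yields a 1 x D matrix
  one <- dplyr::filter(sim$trials, trial == 1)
  f1 <- fnirs_features(one, cfg4)
  expect_equal(nrow(f1), 1)
  expect_equal(ncol(features_matrix(f1)$X), 4)
})

test_that("preprocessing commutes with input row order and channel relabeling", {
  spec <- fnirs_sim_spec(n_trials_per_group = 2, n_channels = 4)
  sim <- simulate_fnirs_trials(spec, seed = 3)
  cfg4 <- preproc_config(expected_channels = 4)
  f_ref <- fnirs_features(sim$trials, cfg4)

  shuffled <- sim$trials[sample.int(nrow(sim$trials)), ]
  f_shuf <- fnirs_features(shuffled, cfg4)
  expect_equal(f_shuf, f_ref, ignore_attr = TRUE)

  # swapping channel ids 1 <-> 4 swaps the feature columns identically
  swapped <- sim$trials
  swapped$channel <- c(4L, 2L, 3L, 1L)[swapped$channel]
  f_swap <- fnirs_features(swapped, cfg4)
  expect_equal(f_swap$ch01, f_ref$ch04)
  expect_equal(f_swap$ch04, f_ref$ch01)
  expect_equal(f_swap$ch02, f_ref$ch02)
})

test_that("long-form TSV round-trips through the reader", {
  sim <- simulate_fnirs_trials(fnirs_sim_spec(n_trials_per_group = 1,
                                              n_channels = 2), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$trials, path)
  back <- read_fnirs_long(path)
  expect_equal(back$oxyhb, sim$trials$oxyhb, tolerance = 1e-9)
  f1 <- fnirs_features(back, preproc_config(expected_channels = 2))
  f2 <- fnirs_features(sim$trials, preproc_config(expected_channels = 2))
  expect_equal(f1, f2, ignore_attr = TRUE, tolerance = 1e-9)
})
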