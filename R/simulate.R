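#' Synthetic study specification
#'
#' Describes a synthetic two-group multichannel fNIRS study with known ground
#' truth: balanced groups of trials, a baseline of at least 20 s, a 10 s test
#' period, and a chosen set of informative channels carrying group-dependent
#' signed hemodynamic effects. Effect sizes are expressed in units of the
#' baseline SD of the mean-Z feature, so an effect of +1.5 on channel 15
#' means the +1 group's feature at channel 15 sits about 1.5 SD above the
#' -1 group's.
#'
#' Defaults emulate the structure of a 50-trial, 24-channel study: 10 Hz
#' sampling, slow drift, ~1 Hz heartbeat pulsation, white measurement noise
#' with moderate equicorrelation across channels, and a gamma-shaped
#' hemodynamic response peaking ~5.5 s after stimulus onset.
#'
#' @param n_trials_per_group trials per group (default 25).
#' @param n_channels number of channels D (default 24).
#' @param informative named numeric vector: names are channel ids, values are
#'   signed effect sizes in feature-SD units.
#' @param sampling_interval seconds (default 0.1).
#' @param baseline_s baseline duration in seconds (>= 20).
#' @param test_s test-period duration (default 10).
#' @param hrf_peak_s hemodynamic response peak latency (default 5.5 s).
#' @param hrf_shape gamma shape of the response curve.
#' @param noise_sd white-noise SD (arbitrary concentration units).
#' @param heartbeat_amp,heartbeat_freq cardiac pulsation amplitude and
#'   frequency (Hz).
#' @param drift_amp,drift_freq slow drift amplitude and frequency (Hz).
#' @param rho equicorrelation of noise across channels (0 <= rho < 1).
#' @param dropout_rate fraction of trials given one unrecorded channel (to
#'   exercise quality control).
#' @return object of class `fnirs_sim_spec`.
#' @export
fnirs_sim_spec <- function(n_trials_per_group = 25, n_channels = 24,
                           informative = numeric(0),
                           sampling_interval = 0.1, baseline_s = 20,
                           test_s = 10, hrf_peak_s = 5.5, hrf_shape = 5,
                           noise_sd = 1.0, heartbeat_amp = 0.3,
                           heartbeat_freq = 1.1, drift_amp = 0.5,
                           drift_freq = 0.008, rho = 0.3,
                           dropout_rate = 0) {
  stopifnot(n_trials_per_group >= 1, n_channels >= 1, baseline_s >= 20,
            test_s > 0, sampling_interval > 0, noise_sd > 0,
            heartbeat_amp >= 0, drift_amp >= 0, rho >= 0, rho < 1,
            dropout_rate >= 0, dropout_rate <= 1)
  if (hrf_peak_s <= 0) stop("hrf_peak_s must be positive", call. = FALSE)
  ids <- as.integer(names(informative))
  if (length(informative) && (anyNA(ids) || any(ids < 1 | ids > n_channels))) {
    stop("informative channel ids must name channels in 1..", n_channels,
         call. = FALSE)
  }
  structure(list(n_trials_per_group = n_trials_per_group,
                 n_channels = n_channels,
                 informative = informative,
                 sampling_interval = sampling_interval,
                 baseline_s = baseline_s, test_s = test_s,
                 hrf_peak_s = hrf_peak_s, hrf_shape = hrf_shape,
                 noise_sd = noise_sd,
                 heartbeat_amp = heartbeat_amp,
                 heartbeat_freq = heartbeat_freq,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 rho = rho, dropout_rate = dropout_rate),
            class = "fnirs_sim_spec")
}

#' The default "paper-like" scenario: 25 + 25 trials, 24 channels
#'
#' Seven informative channels with effects of +-1.5 feature-SD: positive at
#' 3, 5, 14, 15, 16 and negative at 6 and 18 (right-hemisphere channels are
#' 13--24, left are 1--12).
#'
#' @param ... overrides passed on to [fnirs_sim_spec()].
#' @return an `fnirs_sim_spec`.
#' @export
preset_paperlike <- function(...) {
  args <- list(...)
  defaults <- list(
    n_trials_per_group = 25, n_channels = 24,
    informative = c(`3` = 1.5, `5` = 1.5, `6` = -1.5, `14` = 1.5,
                    `15` = 1.5, `16` = 1.5, `18` = -1.5)
  )
  do.call(fnirs_sim_spec, utils::modifyList(defaults, args))
}

#' Canonical hemodynamic response curve
#'
#' Normalized unimodal gamma-family curve: zero at stimulus onset, maximum
#' `amplitude` exactly at `peak_s`, decaying back toward zero —
#' `h(t) = amplitude * (t/p)^a * exp(a * (1 - t/p))`.
#'
#' @param time_s time since stimulus onset, seconds (>= 0; negative times
#'   return 0).
#' @param peak_s peak latency (> 0).
#' @param amplitude peak value.
#' @param shape gamma shape parameter `a` (controls width).
#' @return numeric vector of response values.
#' @examples
#' hemodynamic_response(c(0, 5.5, 20), peak_s = 5.5)
#' @export
hemodynamic_response <- function(time_s, peak_s = 5.5, amplitude = 1,
                                 shape = 5) {
  if (peak_s <= 0) stop("peak_s must be positive", call. = FALSE)
  out <- numeric(length(time_s))
  pos <- time_s > 0
  r <- time_s[pos] / peak_s
  out[pos] <- amplitude * r^shape * exp(shape * (1 - r))
  out
}

#' Simulate raw multichannel trial time series
#'
#' Generates per-trial, per-channel oxy-Hb-like series: slow sinusoidal
#' drift + cardiac pulsation + equicorrelated white noise, plus, on
#' informative channels, a signed hemodynamic response during the test
#' period. The response amplitude is calibrated empirically (per seed) so
#' that the group difference of the resulting mean-Z feature approximately
#' equals the specified effect size. Optionally a fraction of trials lose one
#' channel (recorded as `NA`) to exercise quality control.
#'
#' @param spec an [fnirs_sim_spec()].
#' @param seed integer seed; identical `(spec, seed)` give bitwise-identical
#'   output.
#' @return list with `trials` (long tibble: `participant`, `group`, `trial`,
#'   `channel`, `time_s`, `oxyhb`) and `truth` (informative effects, group
#'   per trial, dropout trials, calibrated amplitudes).
#' @export
simulate_fnirs_trials <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "fnirs_sim_spec"))
  withr::with_seed(seed, simulate_trials_impl(spec))
}

simulate_trials_impl <- function(spec) {
  dt <- spec$sampling_interval
  time_s <- seq(-spec$baseline_s, spec$test_s, by = dt)
  nt <- length(time_s)
  n_tr <- 2 * spec$n_trials_per_group
  D <- spec$n_channels
  groups <- rep(c(1L, -1L), each = spec$n_trials_per_group)

  cfg <- preproc_config(expected_channels = D, test_duration = spec$test_s)
  hrf <- hemodynamic_response(time_s, spec$hrf_peak_s, 1, spec$hrf_shape)
  hrf_f <- bandpass_filter(hrf, dt, cfg)
  in_base <- time_s >= -cfg$zscore_baseline & time_s < 0
  in_win <- time_s >= cfg$feature_window[1] & time_s <= cfg$feature_window[2]
  hrf_gain_shape <- mean(hrf_f[in_win]) - mean(hrf_f[in_base])

  # noise background for every trial x channel
  noise <- array(0, dim = c(nt, D, n_tr))
  for (tr in seq_len(n_tr)) {
    common <- rnorm(nt)
    phase_h <- runif(1, 0, 2 * pi)
    phase_d <- runif(1, 0, 2 * pi)
    for (ch in seq_len(D)) {
      eps <- sqrt(spec$rho) * common + sqrt(1 - spec$rho) * rnorm(nt)
      noise[, ch, tr] <- spec$noise_sd * eps +
        spec$heartbeat_amp * sin(2 * pi * spec$heartbeat_freq * time_s +
                                   phase_h + 0.2 * ch) +
        spec$drift_amp * sin(2 * pi * spec$drift_freq * time_s +
                               phase_d + 0.4 * ch)
    }
  }

  # empirical calibration: feature shift per unit response amplitude is
  # hrf_gain_shape / baseline SD of the filtered background
  inv_s <- matrix(0, n_tr, D)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(D)) {
      xf <- bandpass_filter(noise[, ch, tr], dt, cfg)
      inv_s[tr, ch] <- 1 / baseline_sd(xf[in_base], cfg$sd_type)
    }
  }
  unit_gain <- hrf_gain_shape * colMeans(inv_s)

  info_ids <- as.integer(names(spec$informative))
  amp <- setNames(numeric(length(info_ids)), info_ids)
  for (i in seq_along(info_ids)) {
    amp[i] <- (spec$informative[i] / 2) / unit_gain[info_ids[i]]
  }
  if (length(amp) && any(!is.finite(amp))) {
    warning("infeasible effect/noise combination; some amplitudes non-finite")
  }

  dropout <- rbinom(n_tr, 1, spec$dropout_rate) == 1
  dropout_channel <- ifelse(dropout, sample.int(D, n_tr, replace = TRUE), NA)

  rows <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    sig <- noise[, , tr]
    for (i in seq_along(info_ids)) {
      ch <- info_ids[i]
      sig[, ch] <- sig[, ch] + groups[tr] * amp[i] * hrf
    }
    if (dropout[tr]) sig[, dropout_channel[tr]] <- NA_real_
    rows[[tr]] <- tibble::tibble(
      participant = sprintf("%s%02d", ifelse(groups[tr] == 1, "A", "B"),
                            ceiling(((tr - 1) %% spec$n_trials_per_group + 1) / 5)),
      group = groups[tr],
      trial = tr,
      channel = rep(seq_len(D), each = nt),
      time_s = rep(time_s, times = D),
      oxyhb = as.vector(sig)
    )
  }
  trials <- dplyr::bind_rows(rows)

  truth <- list(informative = spec$informative,
                informative_channels = info_ids,
                signs = sign(spec$informative),
                expected_optimal = sort(info_ids),
                group_of_trial = groups,
                dropout_trials = which(dropout),
                dropout_channel = dropout_channel[dropout],
                amplitudes = amp)
  list(trials = trials, truth = truth)
}

#' Simulate a feature matrix directly
#'
#' Draws mean-Z features straight from a per-group multivariate normal (unit
#' variances, equicorrelation `rho`, mean shifts of +-effect/2 on informative
#' channels), bypassing the time-series stage. Fast path for statistical
#' experiments over many seeds.
#'
#' @param spec an [fnirs_sim_spec()].
#' @param seed integer seed.
#' @return list with `features` (tibble shaped like [fnirs_features()]
#'   output) and `truth`.
#' @export
simulate_fnirs_features <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "fnirs_sim_spec"))
  withr::with_seed(seed, {
    n_tr <- 2 * spec$n_trials_per_group
    D <- spec$n_channels
    groups <- rep(c(1L, -1L), each = spec$n_trials_per_group)
    if (spec$rho < 0 || spec$rho >= 1) {
      stop("equicorrelation must give a positive-definite covariance",
           call. = FALSE)
    }
    common <- rnorm(n_tr)
    Z <- sqrt(spec$rho) * matrix(common, n_tr, D) +
      sqrt(1 - spec$rho) * matrix(rnorm(n_tr * D), n_tr, D)
    mu <- matrix(0, n_tr, D)
    info_ids <- as.integer(names(spec$informative))
    for (i in seq_along(info_ids)) {
      mu[, info_ids[i]] <- groups * spec$informative[i] / 2
    }
    X <- mu + Z
    colnames(X) <- sprintf("ch%02d", seq_len(D))
    features <- dplyr::bind_cols(
      tibble::tibble(
        participant = sprintf("%s%02d", ifelse(groups == 1, "A", "B"),
                              ceiling(((seq_len(n_tr) - 1) %%
                                         spec$n_trials_per_group + 1) / 5)),
        trial = seq_len(n_tr),
        label = groups),
      tibble::as_tibble(X))
    truth <- list(informative = spec$informative,
                  informative_channels = info_ids,
                  signs = sign(spec$informative),
                  expected_optimal = sort(info_ids),
                  group_of_trial = groups)
    list(features = features, truth = truth)
  })
}
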