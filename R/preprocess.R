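#' Preprocessing configuration
#'
#' Bundles every tunable of the raw-signal pipeline: band-pass edges, the
#' pre-onset baseline used for Z-scoring, the feature window over which mean
#' Z-scores are taken, and the expected channel count used by quality control.
#'
#' @param band_low,band_high band-pass edges in Hz. The defaults (0.02, 1.0)
#'   suppress slow drift and heartbeat pulsation.
#' @param zscore_baseline length in seconds of the baseline immediately before
#'   test onset whose mean and SD standardize the test-period signal.
#' @param feature_window two-element numeric, seconds after test onset; the
#'   per-channel feature is the mean Z-score over this closed interval. The
#'   default `c(3, 10)` reflects the few-second lag of the hemodynamic
#'   response peak behind stimulus onset.
#' @param expected_channels number of channels a complete trial must carry.
#' @param test_duration test-period length in seconds.
#' @param filter_order Butterworth prototype order (band-pass has twice as
#'   many poles).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1) for the baseline SD in the Z-score.
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(band_low = 0.02, band_high = 1.0,
                           zscore_baseline = 3, feature_window = c(3, 10),
                           expected_channels = 24, test_duration = 10,
                           filter_order = 3,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(band_low > 0, band_high > band_low, zscore_baseline > 0,
            length(feature_window) == 2, feature_window[1] < feature_window[2],
            feature_window[1] >= 0, feature_window[2] <= test_duration,
            expected_channels >= 1, filter_order >= 1)
  structure(list(band_low = band_low, band_high = band_high,
                 zscore_baseline = zscore_baseline,
                 feature_window = feature_window,
                 expected_channels = expected_channels,
                 test_duration = test_duration,
                 filter_order = filter_order, sd_type = sd_type),
            class = "preproc_config")
}

#' @export
print.preproc_config <- function(x, ...) {
  cat("fNIRS preprocessing config\n",
      sprintf("  band-pass:       %.3g-%.3g Hz (Butterworth order %d, zero phase)\n",
              x$band_low, x$band_high, x$filter_order),
      sprintf("  Z baseline:      %g s before onset (%s SD)\n",
              x$zscore_baseline, x$sd_type),
      sprintf("  feature window:  [%g, %g] s after onset\n",
              x$feature_window[1], x$feature_window[2]),
      sprintf("  channels:        %d expected\n", x$expected_channels),
      sep = "")
  invisible(x)
}

baseline_sd <- function(x, sd_type) {
  m <- mean(x)
  if (sd_type == "population") sqrt(mean((x - m)^2)) else stats::sd(x)
}

# half-sample tolerance for closed-interval window membership under
# floating-point time stamps
.time_eps <- 1e-6

#' Baseline Z-scores for one trial
#'
#' Standardizes each channel of a single trial against its own pre-onset
#' baseline: `z = (x - m_baseline) / s`, where `m_baseline` and `s` are the
#' mean and SD of the (band-pass filtered) signal over the
#' `zscore_baseline` seconds immediately before test onset. Time is expressed
#' relative to test onset (`time_s = 0` at onset, negative during baseline).
#'
#' @param trial_df long tibble for one trial with columns `channel`, `time_s`
#'   and `oxyhb`, covering at least the Z baseline before onset and the test
#'   period after it.
#' @param config a [preproc_config()].
#' @param filter if `TRUE` (default) the series is band-pass filtered before
#'   the baseline statistics and Z-scores are computed.
#' @return tibble with `channel`, `time_s`, `z`, restricted to the interval
#'   from `-zscore_baseline` s through the end of the test period.
#' @export
zscore_trial <- function(trial_df, config = preproc_config(), filter = TRUE) {
  need <- c("channel", "time_s", "oxyhb")
  if (!all(need %in% names(trial_df))) {
    stop("trial_df must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt <- infer_sampling_interval(trial_df$time_s)
  trial_df |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_s)
      x <- if (filter) bandpass_filter(df$oxyhb, dt, config) else df$oxyhb
      in_base <- df$time_s >= -config$zscore_baseline - .time_eps &
        df$time_s < -.time_eps
      if (sum(in_base) < 2) {
        stop("channel ", key$channel, ": baseline shorter than ",
             config$zscore_baseline, " s before onset", call. = FALSE)
      }
      s <- baseline_sd(x[in_base], config$sd_type)
      if (s <= 0) {
        stop("channel ", key$channel, ": zero baseline SD, cannot Z-score",
             call. = FALSE)
      }
      keep <- df$time_s >= -config$zscore_baseline - .time_eps &
        df$time_s <= config$test_duration + .time_eps
      tibble::tibble(time_s = df$time_s[keep],
                     z = (x[keep] - mean(x[in_base])) / s)
    }) |>
    dplyr::ungroup()
}

#' Mean Z-score features for one trial
#'
#' Averages each channel's Z-score series over the feature window (closed
#' interval in onset-relative seconds, default 3--10 s).
#'
#' @param z_df tibble from [zscore_trial()] with `channel`, `time_s`, `z`.
#' @param config a [preproc_config()].
#' @return tibble with one row per channel: `channel`, `feature`.
#' @export
extract_features <- function(z_df, config = preproc_config()) {
  w <- config$feature_window
  in_win <- z_df$time_s >= w[1] - .time_eps & z_df$time_s <= w[2] + .time_eps
  if (!any(in_win)) {
    stop("no samples fall in the feature window [", w[1], ", ", w[2], "] s",
         call. = FALSE)
  }
  z_df[in_win, ] |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(feature = mean(.data$z), .groups = "drop")
}

#' Trial-level quality control
#'
#' A trial is retained only if every expected channel is present, all channel
#' series have equal length, and no sample is missing (`NA`); any gap in any
#' channel rejects the whole trial (strict all-channels-recorded rule).
#'
#' @param long_df long tibble with columns `participant`, `trial`, `channel`,
#'   `time_s`, `oxyhb` (and typically `group`).
#' @param config a [preproc_config()].
#' @return tibble with one row per trial: `participant`, `trial`, `retained`,
#'   `reason` (`NA` when retained).
#' @export
qc_trials <- function(long_df, config = preproc_config()) {
  D <- config$expected_channels
  long_df |>
    dplyr::group_by(.data$participant, .data$trial) |>
    dplyr::summarise(
      n_channels = dplyr::n_distinct(.data$channel),
      equal_len = length(unique(table(.data$channel))) == 1,
      any_na = anyNA(.data$oxyhb),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      retained = .data$n_channels == D & .data$equal_len & !.data$any_na,
      reason = dplyr::case_when(
        .data$n_channels != D ~
          paste0("incomplete channel set (", .data$n_channels, "/", D, ")"),
        !.data$equal_len ~ "unequal channel series lengths",
        .data$any_na ~ "missing samples in at least one channel",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("participant", "trial", "retained", "reason")
}

infer_sampling_interval <- function(time_s) {
  dt <- diff(sort(unique(round(time_s, 9))))
  dt <- dt[dt > 0]
  if (!length(dt)) stop("cannot infer sampling interval", call. = FALSE)
  d0 <- stats::median(dt)
  if (any(abs(dt - d0) > 1e-6 * max(1, d0))) {
    stop("mixed or irregular sampling intervals in input", call. = FALSE)
  }
  d0
}

#' Build the trial-by-channel feature table
#'
#' Runs the full preprocessing chain on a long-form recording — quality
#' control, zero-phase band-pass filtering, baseline Z-scoring, feature-window
#' averaging — and returns one row per retained trial with one mean-Z column
#' per channel. Trials (not participants) are the classification unit.
#'
#' @param long_df long tibble with columns `participant`, `group`, `trial`,
#'   `channel`, `time_s`, `oxyhb`; `time_s` is relative to test onset.
#' @param config a [preproc_config()].
#' @param channels `"bilateral"` (all), `"left"` (ids `1:(D/2)`), `"right"`
#'   (ids `(D/2+1):D`), or an integer vector of channel ids.
#' @param positive_label value of `group` mapped to label +1 when `group` is
#'   not already numeric +-1.
#' @return tibble with columns `participant`, `trial`, `label`, then one
#'   `chNN` column per selected channel; the QC table is attached as
#'   attribute `"qc"`.
#' @examples
#' sim <- simulate_fnirs_trials(fnirs_sim_spec(n_channels = 4,
#'                                             informative = c(`2` = 1.5)),
#'                              seed = 1)
#' feats <- fnirs_features(sim$trials, preproc_config(expected_channels = 4))
#' @export
fnirs_features <- function(long_df, config = preproc_config(),
                           channels = "bilateral", positive_label = NULL) {
  need <- c("participant", "group", "trial", "channel", "time_s", "oxyhb")
  if (!all(need %in% names(long_df))) {
    stop("input must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  qc <- qc_trials(long_df, config)
  kept <- qc[qc$retained, c("participant", "trial")]
  if (!nrow(kept)) stop("no trials survive quality control", call. = FALSE)
  data <- dplyr::semi_join(long_df, kept, by = c("participant", "trial"))

  ids <- resolve_channels(channels, config$expected_channels)
  data <- data[data$channel %in% ids, ]

  feats <- data |>
    dplyr::group_by(.data$participant, .data$group, .data$trial) |>
    dplyr::group_modify(function(df, key) {
      z <- zscore_trial(df, config)
      extract_features(z, config)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(channel = sprintf("ch%02d", .data$channel)) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "feature",
                       names_sort = TRUE)

  feats$label <- encode_labels(feats$group, positive_label)
  out <- dplyr::select(feats, "participant", "trial", "label",
                       dplyr::matches("^ch\\d+$"))
  attr(out, "qc") <- qc
  attr(out, "channel_ids") <- ids
  out
}

resolve_channels <- function(channels, D) {
  if (is.character(channels) && length(channels) == 1) {
    half <- D %/% 2
    switch(channels,
           bilateral = seq_len(D),
           all = seq_len(D),
           left = seq_len(half),
           right = (half + 1):D,
           stop("unknown channel set '", channels, "'", call. = FALSE))
  } else {
    ids <- sort(unique(as.integer(channels)))
    if (any(ids < 1 | ids > D)) {
      stop("channel ids must lie in 1..", D, call. = FALSE)
    }
    ids
  }
}

encode_labels <- function(group, positive_label = NULL) {
  if (is.numeric(group)) {
    if (!all(group %in% c(-1, 1))) {
      stop("numeric group labels must be +1/-1", call. = FALSE)
    }
    return(as.integer(group))
  }
  vals <- sort(unique(as.character(group)))
  if (length(vals) > 2) stop("more than two group labels", call. = FALSE)
  if (is.null(positive_label)) {
    stop("group is non-numeric; give positive_label (one of ",
         paste(vals, collapse = ", "), ")", call. = FALSE)
  }
  ifelse(as.character(group) == positive_label, 1L, -1L)
}

#' Extract the numeric design from a feature table
#'
#' @param features_df tibble from [fnirs_features()] (or the same shape):
#'   `label` plus `chNN` columns.
#' @return list with `X` (N x D matrix, columns named by channel), `t`
#'   (+-1 integer labels), `channel_ids` (integer), and `provenance`
#'   (participant/trial tibble when available).
#' @export
features_matrix <- function(features_df) {
  ch_cols <- grep("^ch\\d+$", names(features_df), value = TRUE)
  if (!length(ch_cols)) stop("no chNN feature columns found", call. = FALSE)
  if (!"label" %in% names(features_df)) {
    stop("features_df must have a 'label' column", call. = FALSE)
  }
  X <- as.matrix(features_df[ch_cols])
  if (anyNA(X) || any(!is.finite(X))) {
    stop("feature matrix contains missing or non-finite entries",
         call. = FALSE)
  }
  t <- as.integer(features_df$label)
  if (!all(t %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  prov <- if (all(c("participant", "trial") %in% names(features_df))) {
    features_df[c("participant", "trial")]
  } else NULL
  list(X = X, t = t,
       channel_ids = as.integer(sub("^ch", "", ch_cols)),
       provenance = prov)
}

#' Read a long-form fNIRS recording
#'
#' Expects delimited text with header `participant, group, trial, channel,
#' time_s, oxyhb`; `time_s` is onset-relative seconds. Empty fields or a
#' configurable sentinel become `NA` and later reject the trial during QC.
#'
#' @param path file path.
#' @param delim field delimiter (tab by default).
#' @param na strings to read as missing.
#' @return a long tibble.
#' @export
read_fnirs_long <- function(path, delim = "\t", na = c("", "NA", "NaN")) {
  readr::read_delim(path, delim = delim, na = na, show_col_types = FALSE,
                    col_types = readr::cols(
                      participant = readr::col_character(),
                      group = readr::col_guess(),
                      trial = readr::col_integer(),
                      channel = readr::col_integer(),
                      time_s = readr::col_double(),
                      oxyhb = readr::col_double()
                    ))
}

#' Write a feature table as TSV
#' @param features_df tibble from [fnirs_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features_df, path) {
  readr::write_tsv(features_df, path)
  invisible(path)
}
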