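# shared fixtures, built in code

# rescale a vector to an exact sample mean and SD
scale_to <- function(x, m, s) {
  (x - mean(x)) / stats::sd(x) * s + m
}

# one-trial long tibble with onset-relative time and given per-channel series
make_trial_df <- function(values_by_channel, dt = 0.1, t_start = -20,
                          participant = "P1", group = 1L, trial = 1L) {
  n <- length(values_by_channel[[1]])
  time_s <- seq(t_start, by = dt, length.out = n)
  dplyr::bind_rows(lapply(seq_along(values_by_channel), function(ch) {
    tibble::tibble(participant = participant, group = group, trial = trial,
                   channel = ch, time_s = time_s,
                   oxyhb = values_by_channel[[ch]])
  }))
}

# small linearly separable 2-D set used by margin-oracle tests
sep_toy <- function() {
  list(X = rbind(c(0, 1), c(1, 2), c(-1, 1.5), c(2, -1), c(3, 0), c(2.5, -2)),
       y = c(1, 1, 1, -1, -1, -1))
}

# brute-force hard-margin oracle: sweep hyperplane directions, pick the best
# midpoint intercept for each; returns the maximal geometric margin
grid_margin_oracle <- function(X, y, n_theta = 20000) {
  best <- -Inf
  for (theta in seq(0, pi, length.out = n_theta)) {
    u <- c(cos(theta), sin(theta))
    proj <- as.numeric(X %*% u)
    for (s in c(1, -1)) {
      lo <- min(s * proj[y == 1])
      hi <- max(s * proj[y == -1])
      best <- max(best, (lo - hi) / 2)
    }
  }
  best
}

# hand step-up BH oracle (independent of stats::p.adjust)
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# memoized paper-scale featurization of the time-series generator (expensive)
.fix_env <- new.env(parent = emptyenv())
paperlike_features50 <- function(seed = 1) {
  key <- paste0("f50_", seed)
  if (is.null(.fix_env[[key]])) {
    sim <- simulate_fnirs_trials(preset_paperlike(), seed = seed)
    .fix_env[[key]] <- fnirs_features(sim$trials)
  }
  .fix_env[[key]]
}
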