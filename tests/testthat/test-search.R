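test_that("subset enumeration is complete and exactly counted", {
  expect_equal(enumerate_subsets(2), c(1, 2, 3))
  expect_equal(length(enumerate_subsets(12)), 4095)
  expect_equal(length(enumerate_subsets(16)), 65535)
  seen <- tabulate(enumerate_subsets(16), 65535)
  expect_true(all(seen == 1L))
  expect_error(enumerate_subsets(0), "1..30")
  expect_error(enumerate_subsets(31), "1..30")

  expect_equal(subset_channels(5, c(10, 20, 30)), c(10, 30))
  expect_equal(fnirselect:::mask_popcount(c(1, 3, 4095), 12), c(1, 2, 12))
})

test_that("batched exhaustive evaluation equals an independent per-subset loop", {
  spec <- fnirs_sim_spec(n_trials_per_group = 12, n_channels = 5,
                         informative = c(`2` = 1.5, `4` = -1.5))
  sim <- simulate_fnirs_features(spec, seed = 9)
  folds <- kfold_assign(features_matrix(sim$features)$t, k = 5, seed = 3)

  sr <- channel_search(sim$features, folds = folds, top = 10)
  expect_equal(nrow(sr$results), 31)

  # independent route: one svm_cv call per decoded subset
  oracle_cve <- vapply(sr$results$mask, function(m) {
    svm_cv(sim$features, channels = subset_channels(m, 1:5),
           folds = folds)$cve
  }, numeric(1))
  expect_equal(sr$results$cve, oracle_cve)

  # identity on every evaluation
  expect_equal(sr$results$accuracy, (1 - sr$results$cve) * 100)

  # determinism: re-run is identical
  sr2 <- channel_search(sim$features, folds = folds, top = 10)
  expect_identical(sr2$results, sr$results)
  expect_identical(sr2$top_weights, sr$top_weights)
})

test_that("checkpointed runs resume to the same report", {
  spec <- fnirs_sim_spec(n_trials_per_group = 10, n_channels = 6,
                         informative = c(`1` = 1.5))
  sim <- simulate_fnirs_features(spec, seed = 2)
  folds <- kfold_assign(features_matrix(sim$features)$t, k = 5, seed = 1)
  ref <- channel_search(sim$features, folds = folds, top = 5)

  # simulate an interruption: ledger holds only the first 20 evaluations
  ckpt <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(mask = ref$results$mask[1:20], errors = ref$results$errors[1:20]),
    ckpt, sep = "\t", row.names = FALSE, quote = FALSE)
  resumed <- channel_search(sim$features, folds = folds, top = 5,
                            checkpoint = ckpt, chunk_size = 16L)
  expect_identical(resumed$results, ref$results)
})

test_that("ranking is by CVE, then parsimony, then mask", {
  res <- tibble::tibble(mask = c(7, 3, 12, 5),
                        size = c(3, 2, 2, 2),
                        cve = c(0.1, 0.1, 0.1, 0.3),
                        accuracy = (1 - cve) * 100)
  ranked <- rank_subsets(res)
  expect_equal(ranked$mask, c(3, 12, 7, 5))
  expect_equal(ranked$rank, 1:4)
})

test_that("optimal subset never scores below the all-channel subset", {
  spec <- fnirs_sim_spec(n_trials_per_group = 15, n_channels = 6,
                         informative = c(`2` = 1.5, `3` = -1.5))
  sim <- simulate_fnirs_features(spec, seed = 7)
  sr <- channel_search(sim$features, top = 10)
  g <- glance(sr)
  expect_gte(g$best_accuracy, g$all_channel_accuracy)
  opt <- optimal_subsets(sr)
  expect_true(all(opt$cve == min(sr$results$cve)))
  expect_equal(opt$rank, seq_len(nrow(opt)))
})

test_that("occurrence and sign summaries describe the top-K structure", {
  spec <- fnirs_sim_spec(n_trials_per_group = 20, n_channels = 6,
                         informative = c(`2` = 2.5, `5` = -2.5))
  sim <- simulate_fnirs_features(spec, seed = 13)
  sr <- channel_search(sim$features, top = 10)

  occ <- channel_occurrence(sr)
  expect_equal(occ$channel, 1:6)
  expect_true(all(occ$count <= 10))
  sgn <- sign_consistency(sr)
  expect_equal(sgn$n_positive + sgn$n_negative + sgn$n_absent, rep(10L, 6))

  # planted channels dominate the top subsets with the planted signs
  expect_gte(occ$count[occ$channel == 2], 8)
  expect_gte(occ$count[occ$channel == 5], 8)
  expect_equal(sgn$sign[sgn$channel == 2], "+")
  expect_equal(sgn$sign[sgn$channel == 5], "-")
  # fully sign-consistent planted channel: positive count equals occurrence
  expect_equal(sgn$n_positive[sgn$channel == 2], occ$count[occ$channel == 2])

  # K = 1: occurrence is the membership indicator of the best subset
  sr1 <- channel_search(sim$features, top = 1)
  occ1 <- channel_occurrence(sr1)
  best <- sr1$top$channels[[1]]
  expect_equal(occ1$count, as.integer(occ1$channel %in% best))
})

test_that("percentile rank counts strictly better subsets", {
  expect_equal(percentile_rank(70, c(50, 60, 70))$rank, 1)
  pr <- percentile_rank(60, c(50, 60, 70))
  expect_equal(pr$rank, 2)
  expect_equal(pr$top_fraction, 2 / 3)
  expect_error(percentile_rank(50, numeric(0)), "empty")

  spec <- fnirs_sim_spec(n_trials_per_group = 10, n_channels = 4)
  sim <- simulate_fnirs_features(spec, seed = 1)
  sr <- channel_search(sim$features, top = 3)
  pr <- percentile_rank(glance(sr)$best_accuracy, sr)
  expect_equal(pr$rank, 1)
})

test_that("evaluate_subsets agrees with channel_search on explicit masks", {
  spec <- fnirs_sim_spec(n_trials_per_group = 10, n_channels = 5,
                         informative = c(`1` = 2))
  sim <- simulate_fnirs_features(spec, seed = 3)
  folds <- kfold_assign(features_matrix(sim$features)$t, 5, seed = 2)
  sr <- channel_search(sim$features, folds = folds, top = 3)
  ev <- evaluate_subsets(sim$features, masks = c(1, 17, 31), folds = folds)
  expect_equal(ev$errors,
               sr$results$errors[match(c(1, 17, 31), sr$results$mask)])
  expect_error(evaluate_subsets(sim$features, masks = 32, folds = folds),
               "out of range")
})
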