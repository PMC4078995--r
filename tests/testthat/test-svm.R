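test_that("symmetric 1-D problem yields the symmetric maximum-margin boundary", {
  x <- matrix(c(-1, 1), ncol = 1)
  fit <- fit_linear_svm(x, c(-1, 1), C = 1e6)
  expect_gt(fit$w, 0)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(decision_value(fit, matrix(0)), 0, tolerance = 1e-6)
  # hard-margin contract on separable data: t * y(x) > 0 for all samples
  expect_true(all(c(-1, 1) * decision_value(fit, x) > 0))
})

test_that("XOR layout is not linearly separable", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  fit <- fit_linear_svm(X, y, C = 1e4)
  expect_gt(sum(predict(fit, X) != y), 0)
})

test_that("margin matches a brute-force grid maximizer on small 2-D sets", {
  toy <- sep_toy()
  fit <- fit_linear_svm(toy$X, toy$y, C = 1e6)
  margin_svm <- 1 / sqrt(sum(fit$w^2))
  margin_grid <- grid_margin_oracle(toy$X, toy$y)
  expect_equal(margin_svm, margin_grid, tolerance = 1e-3)
  expect_true(all(toy$y * decision_value(fit, toy$X) > 0))

  # second layout, includes a tight support pair
  X2 <- rbind(c(0, 0), c(0.4, 0.1), c(1, 0.2), c(1.2, 1.4), c(2, 2), c(0.5, 1.6))
  y2 <- c(-1, -1, -1, 1, 1, 1)
  fit2 <- fit_linear_svm(X2, y2, C = 1e6)
  expect_equal(1 / sqrt(sum(fit2$w^2)), grid_margin_oracle(X2, y2),
               tolerance = 1e-3)
})

test_that("decision values, tie rule and input validation behave as documented", {
  model <- structure(list(w = c(1, -1), b = 0, subset = c("a", "b")),
                     class = "linear_svm")
  expect_equal(decision_value(model, c(2, 1)), 1)
  expect_equal(predict(model, c(2, 1)), 1L)
  # a point exactly on the boundary goes to class -1
  expect_equal(predict(model, c(1, 1)), -1L)
  m0 <- structure(list(w = c(0, 0), b = -3), class = "linear_svm")
  expect_equal(predict(m0, c(100, 100)), -1L)
  expect_error(decision_value(model, c(1, 2, 3)), "columns")

  expect_error(fit_linear_svm(matrix(1:4, 2), c(1, 1)), "both classes")
  expect_error(fit_linear_svm(matrix(c(1, NA, 3, 4), 2), c(1, -1)),
               "non-finite")
  expect_error(fit_linear_svm(matrix(1:4, 2), c(1, 2)), "\\+1/-1")
})

test_that("stratified k-fold partitions are balanced, seeded and validated", {
  y <- rep(c(1, -1), each = 25)
  f <- kfold_assign(y, k = 5, seed = 11)
  expect_equal(unname(tabulate(f, 5)), rep(10, 5))
  for (k in 1:5) expect_equal(sum(y[f == k] == 1), 5)

  expect_identical(kfold_assign(y, 5, seed = 11), f)
  expect_false(identical(kfold_assign(y, 5, seed = 12), f))

  # leave-one-out
  f10 <- kfold_assign(rep(c(1, -1), 5), k = 10, seed = 1)
  expect_equal(sort(f10), 1:10)

  expect_error(kfold_assign(rep(1, 5), k = 6), "exceeds")

  # fold assignment leaves the global RNG untouched
  set.seed(99); before <- .Random.seed
  kfold_assign(y, 5, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("CVE obeys the accuracy identity and detects separable/null structure", {
  # perfectly separated synthetic data: CVE 0, accuracy 100
  spec <- fnirs_sim_spec(n_trials_per_group = 10, n_channels = 3,
                         informative = c(`1` = 8))
  sim <- simulate_fnirs_features(spec, seed = 4)
  cv <- svm_cv(sim$features, channels = 1, seed = 1)
  expect_equal(cv$cve, 0)
  expect_equal(cv$accuracy, 100)

  # identity holds exactly on arbitrary data
  null_sim <- simulate_fnirs_features(fnirs_sim_spec(n_trials_per_group = 50,
                                                     n_channels = 4), seed = 6)
  cv2 <- svm_cv(null_sim$features, seed = 2)
  expect_equal(cv2$cve, sum(cv2$per_fold_errors) / cv2$n)
  expect_equal(cv2$accuracy, (1 - cv2$cve) * 100)
  expect_true(cv2$cve %in% (0:cv2$n / cv2$n))

  # labels carry no signal: accuracy near chance
  expect_gt(cv2$accuracy, 30)
  expect_lt(cv2$accuracy, 70)
})

test_that("margin solution is antisymmetric in labels and covariant to column scaling", {
  toy <- sep_toy()
  fit <- fit_linear_svm(toy$X, toy$y, C = 1e6)
  flip <- fit_linear_svm(toy$X, -toy$y, C = 1e6)
  expect_equal(flip$w, -fit$w, tolerance = 1e-5)
  expect_equal(flip$b, -fit$b, tolerance = 1e-5)

  Xs <- toy$X
  Xs[, 2] <- Xs[, 2] * 7
  fs <- fit_linear_svm(Xs, toy$y, C = 1e6)
  expect_equal(predict(fs, Xs), predict(fit, toy$X))
})

test_that("svm_cv validates folds and reports an error naming a degenerate fold", {
  spec <- fnirs_sim_spec(n_trials_per_group = 4, n_channels = 2)
  sim <- simulate_fnirs_features(spec, seed = 1)
  bad_folds <- c(1, 1, 1, 1, 2, 2, 2, 2)  # fold 1 train split has one class
  expect_error(svm_cv(sim$features, folds = bad_folds), "single class")
})
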