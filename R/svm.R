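#' Fit a linear maximum-margin classifier
#'
#' Soft-margin linear support vector machine, solved exactly in the dual by
#' sequential minimal optimization (maximal-violating-pair working sets).
#' With linearly separable data and large `C` the solution approaches the
#' hard-margin classifier, for which every training sample satisfies
#' `t * y(x) > 0`. A larger `|w_j|` marks channel `j` as contributing more to
#' the decision; the sign of `w_j` gives the direction of the group whose
#' signal is larger at that channel.
#'
#' @param x numeric matrix, N rows (trials) by d columns (channels).
#' @param y labels, +1/-1, both classes present.
#' @param C soft-margin cost (> 0); default 1.
#' @param tol KKT violation tolerance of the dual solver.
#' @return object of class `linear_svm` with elements `w`, `b`, `alpha`,
#'   `subset` (column names), `C`, `iterations`, `converged`.
#' @examples
#' x <- matrix(c(-2, -1, 1, 2), ncol = 1)
#' fit <- fit_linear_svm(x, c(-1, -1, 1, 1), C = 100)
#' predict(fit, matrix(0.5))
#' @export
fit_linear_svm <- function(x, y, C = 1, tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), ncol(x) >= 1, C > 0)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present to fit a classifier", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  fit <- .smo_fit(x, y, C, tol)
  structure(list(w = as.numeric(fit$w), b = as.numeric(fit$b),
                 alpha = as.numeric(fit$alpha),
                 subset = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                 C = C, iterations = fit$iterations,
                 converged = fit$converged),
            class = "linear_svm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decision values and class predictions
#'
#' `decision_value()` evaluates `y(x) = w . x + b`; `predict()` maps it to a
#' class: +1 when `y(x) > 0`, otherwise -1 (points exactly on the boundary
#' are assigned -1 by convention).
#'
#' @param model a `linear_svm`.
#' @param x numeric matrix (rows = samples) or vector with `length(w)`
#'   entries.
#' @return numeric vector of decision values / integer vector of +-1 classes.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$w)) {
    stop("x has ", ncol(x), " columns but the model expects ",
         length(model$w), call. = FALSE)
  }
  as.numeric(x %*% model$w + model$b)
}

#' @param object a `linear_svm`.
#' @param newdata samples to classify.
#' @param ... unused.
#' @rdname decision_value
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(decision_value(object, newdata) > 0, 1L, -1L)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear SVM (C =", x$C, ")\n")
  cat("  w:", format(x$w, digits = 4), "\n  b:", format(x$b, digits = 4), "\n")
  cat("  support vectors:", sum(x$alpha > 1e-8), "of", length(x$alpha), "\n")
  invisible(x)
}

#' @export
tidy.linear_svm <- function(x, ...) {
  tibble::tibble(term = c(x$subset, "(intercept)"),
                 estimate = c(x$w, x$b))
}

#' Stratified K-fold assignment
#'
#' Randomly partitions N rows into K folds, stratified by label so that fold
#' sizes per label differ by at most one. Deterministic given `seed`; the
#' global RNG state is left untouched.
#'
#' @param y +-1 labels (length N).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`, one per row.
#' @export
kfold_assign <- function(y, k = 5, seed = 1) {
  n <- length(y)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")",
                  call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    # deal shuffled rows of each label into folds, continuing the fold
    # cycle across labels so all k folds fill even when k exceeds a label's
    # count (k = n gives leave-one-out)
    start <- 0L
    for (lab in unique(y)) {
      idx <- which(y == lab)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  fold
}

#' Cross-validation error for a channel subset
#'
#' K-fold cross-validation of the linear SVM restricted to a channel subset:
#' for each fold, the model is trained on the remaining folds (columns in the
#' subset only) and the held-out trials are classified. The cross-validation
#' error (CVE) is the fraction of all N trials misclassified, and the
#' classification accuracy is `(1 - CVE) * 100`.
#'
#' @param features_df feature table from [fnirs_features()] (or same shape).
#' @param channels channel ids to use (default: all channels present).
#' @param k number of folds (default 5).
#' @param C soft-margin cost.
#' @param seed seed for the stratified fold assignment (ignored when `folds`
#'   is given).
#' @param folds optional explicit fold-id vector, e.g. to share folds with an
#'   exhaustive search.
#' @return object of class `svm_cv`: `cve`, `accuracy`, `per_fold_errors`,
#'   `predictions`, `folds`, `channels`, `k`, `C`, `seed`, and the refit
#'   full-data `model`.
#' @export
svm_cv <- function(features_df, channels = NULL, k = 5, C = 1, seed = 1,
                   folds = NULL) {
  fm <- features_matrix(features_df)
  ids <- if (is.null(channels)) fm$channel_ids else as.integer(channels)
  cols <- match(ids, fm$channel_ids)
  if (anyNA(cols)) {
    stop("channels not in the feature table: ",
         paste(ids[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  if (is.null(folds)) folds <- kfold_assign(fm$t, k = k, seed = seed)
  k <- max(folds)
  check_folds(folds, fm$t, k)

  X <- fm$X[, cols, drop = FALSE]
  n <- nrow(X)
  preds <- integer(n)
  per_fold <- integer(k)
  for (kk in seq_len(k)) {
    tr <- folds != kk
    fit <- fit_linear_svm(X[tr, , drop = FALSE], fm$t[tr], C = C)
    p <- predict(fit, X[!tr, , drop = FALSE])
    preds[!tr] <- p
    per_fold[kk] <- sum(p != fm$t[!tr])
  }
  cve <- sum(per_fold) / n
  structure(list(cve = cve, accuracy = classification_accuracy(sum(per_fold), n),
                 per_fold_errors = per_fold, predictions = preds,
                 folds = folds, channels = ids, k = k, C = C, seed = seed,
                 n = n, model = fit_linear_svm(X, fm$t, C = C)),
            class = "svm_cv")
}

#' Classification accuracy from a cross-validation error count
#'
#' `accuracy = (1 - CVE) * 100` with `CVE = errors / n`, the fraction of all
#' held-out trials misclassified — e.g. 8 errors out of 50 trials give 84%.
#'
#' @param errors number of misclassified trials across all folds.
#' @param n total number of trials.
#' @return accuracy in percent.
#' @export
classification_accuracy <- function(errors, n) {
  stopifnot(n >= 1, all(errors >= 0), all(errors <= n))
  (1 - errors / n) * 100
}

check_folds <- function(folds, y, k) {
  if (any(tabulate(folds, k) == 0)) stop("empty fold", call. = FALSE)
  for (kk in seq_len(k)) {
    if (length(unique(y[folds != kk])) < 2) {
      stop("training split for fold ", kk, " contains a single class; ",
           "re-seed the fold assignment", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over channels {%s}: CVE = %d/%d, accuracy = %.1f%%\n",
              x$k, paste(x$channels, collapse = ","),
              round(x$cve * x$n), x$n, x$accuracy))
  invisible(x)
}

#' @export
glance.svm_cv <- function(x, ...) {
  tibble::tibble(cve = x$cve, accuracy = x$accuracy, n = x$n, k = x$k,
                 C = x$C, n_channels = length(x$channels))
}

#' @export
tidy.svm_cv <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k), errors = x$per_fold_errors,
                 n = tabulate(x$folds, x$k))
}
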