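#' LASSO linear classifier
#'
#' Classical L1-penalized least squares on +-1 targets, used as a sparse
#' linear classifier: minimize `(1/2N) * sum (t_i - b - w.x_i)^2 +
#' lambda * sum |w_j|`; samples are classified by the sign of `w.x + b`.
#' Exact zeros in `w` perform embedded feature selection. `lambda = 0` is
#' solved exactly by ordinary least squares.
#'
#' @param x numeric N x D matrix (features are already Z-scores; no
#'   re-standardization is applied).
#' @param y +-1 labels.
#' @param lambda penalty (>= 0), on the `glmnet` `(1/2N)` residual scale.
#' @return object of class `linear_svm`-compatible list (`w`, `b`, `subset`)
#'   with class `lasso_classifier`.
#' @export
lasso_classifier <- function(x, y, lambda) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(lambda >= 0, nrow(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite input", call. = FALSE)
  }
  d <- ncol(x)
  if (lambda == 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    w <- cf[-1]; b <- cf[1]
  } else {
    xg <- if (d == 1) cbind(x, 0) else x  # glmnet needs >= 2 columns
    lmax <- lasso_lambda_max(x, y)
    path <- sort(unique(c(exp(seq(log(max(lmax, lambda) * 1.001),
                                  log(max(lambda, lmax * 1e-4)),
                                  length.out = 25)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(xg, y, family = "gaussian", alpha = 1,
                          lambda = path, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-12)
    # suppressWarnings: glmnet interpolates over a lambda grid that can
    # contain near-duplicates
    cf <- suppressWarnings(as.numeric(coef(fit, s = lambda, exact = FALSE)))
    w <- cf[1 + seq_len(d)]; b <- cf[1]
  }
  structure(list(w = as.numeric(w), b = as.numeric(b),
                 subset = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                 lambda = lambda),
            class = "lasso_classifier")
}

# smallest penalty with all-zero weights (intercept-only model)
lasso_lambda_max <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  max(abs(crossprod(xc, y - mean(y)))) / nrow(x)
}

#' @export
predict.lasso_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  ifelse(as.numeric(newdata %*% object$w + object$b) > 0, 1L, -1L)
}

#' @export
tidy.lasso_classifier <- function(x, ...) {
  tibble::tibble(term = c(x$subset, "(intercept)"), estimate = c(x$w, x$b))
}

#' Sparse logistic classifier
#'
#' Sparse-weight logistic regression: L1-penalized logistic likelihood with
#' the penalty chosen by seeded inner cross-validation. This is a functional
#' stand-in for automatic-relevance-determination sparse logistic regression:
#' it preserves the embedded-sparse-selection role (exact zero weights chosen
#' during classifier training) without the variational ARD posterior. A small
#' penalty floor guards against divergence under perfect separation.
#'
#' @param x numeric N x D matrix.
#' @param y +-1 labels, both classes present.
#' @param nfolds inner CV folds for the penalty (default 5).
#' @param seed seed for the inner fold assignment.
#' @param lambda_floor minimum admissible penalty.
#' @return object of class `sparse_logistic` with `w`, `b`, `subset`,
#'   `lambda`.
#' @export
sparse_logistic <- function(x, y, nfolds = 5, seed = 1, lambda_floor = 1e-4) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  d <- ncol(x)
  xg <- if (d == 1) cbind(x, 0) else x  # glmnet needs >= 2 columns
  foldid <- kfold_assign(y, k = nfolds, seed = seed)
  # suppressWarnings: small inner folds trip glmnet's class-count caution
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(xg, factor(y, levels = c(-1, 1)),
                      family = "binomial", alpha = 1,
                      foldid = foldid, standardize = FALSE,
                      type.measure = "class"))
  lam <- max(cvfit$lambda.min, lambda_floor)
  cf <- suppressWarnings(as.numeric(coef(cvfit, s = lam)))
  structure(list(w = cf[1 + seq_len(d)], b = cf[1],
                 subset = colnames(x) %||% paste0("x", seq_len(ncol(x))),
                 lambda = lam),
            class = "sparse_logistic")
}

#' @export
predict.sparse_logistic <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  ifelse(as.numeric(newdata %*% object$w + object$b) > 0, 1L, -1L)
}

#' @export
tidy.sparse_logistic <- function(x, ...) {
  tibble::tibble(term = c(x$subset, "(intercept)"), estimate = c(x$w, x$b))
}

#' Cross-validated accuracy of an embedded sparse baseline
#'
#' Evaluates LASSO or the sparse-logistic stand-in with the same outer folds
#' as the exhaustive search (so the accuracy can be ranked against the
#' exhaustive distribution). In each outer fold the penalty is chosen by
#' seeded inner cross-validation on the training split only; the held-out
#' trials are then classified and accuracy is `(1 - CVE) * 100`. The selected
#' channel set reported is from a final fit on the full dataset.
#'
#' @param features_df feature table from [fnirs_features()].
#' @param method `"lasso"` or `"slr"`.
#' @param k outer folds (ignored when `folds` given).
#' @param seed seed for outer (and derived inner) fold assignments.
#' @param folds optional explicit outer fold ids shared with a search run.
#' @return object of class `comparator_result`: `method`, `accuracy`, `cve`,
#'   `predictions`, `selected_channels`, `weights`, `hyperparameter_trace`
#'   (per-fold chosen penalty), `folds`.
#' @export
comparator_cv <- function(features_df, method = c("lasso", "slr"), k = 5,
                          seed = 1, folds = NULL) {
  method <- match.arg(method)
  fm <- features_matrix(features_df)
  if (is.null(folds)) folds <- kfold_assign(fm$t, k = k, seed = seed)
  k <- max(folds)
  check_folds(folds, fm$t, k)
  n <- nrow(fm$X)
  preds <- integer(n)
  lam_trace <- numeric(k)
  for (kk in seq_len(k)) {
    tr <- folds != kk
    Xtr <- fm$X[tr, , drop = FALSE]
    ytr <- fm$t[tr]
    if (method == "lasso") {
      lam <- inner_cv_lambda_gaussian(Xtr, ytr, seed = seed + kk)
      fit <- lasso_classifier(Xtr, ytr, lambda = lam)
    } else {
      fit <- sparse_logistic(Xtr, ytr, seed = seed + kk)
      lam <- fit$lambda
    }
    lam_trace[kk] <- lam
    preds[!tr] <- predict(fit, fm$X[!tr, , drop = FALSE])
  }
  cve <- mean(preds != fm$t)

  full <- if (method == "lasso") {
    lasso_classifier(fm$X, fm$t,
                     lambda = inner_cv_lambda_gaussian(fm$X, fm$t, seed = seed))
  } else {
    sparse_logistic(fm$X, fm$t, seed = seed)
  }
  nz <- which(abs(full$w) > 0)
  structure(list(method = method, cve = cve, accuracy = (1 - cve) * 100,
                 predictions = preds,
                 selected_channels = fm$channel_ids[nz],
                 weights = setNames(full$w, sprintf("ch%02d", fm$channel_ids)),
                 hyperparameter_trace = lam_trace,
                 folds = folds, n = n, seed = seed),
            class = "comparator_result")
}

inner_cv_lambda_gaussian <- function(x, y, nfolds = 5, seed = 1) {
  foldid <- kfold_assign(y, k = nfolds, seed = seed)
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(x, as.numeric(y), family = "gaussian", alpha = 1,
                      foldid = foldid, standardize = FALSE))
  cvfit$lambda.min
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s comparator: accuracy %.1f%% (CVE %d/%d)\n",
              toupper(x$method), x$accuracy, round(x$cve * x$n), x$n))
  cat("  selected channels:",
      if (length(x$selected_channels)) paste(x$selected_channels, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
glance.comparator_result <- function(x, ...) {
  tibble::tibble(method = x$method, accuracy = x$accuracy, cve = x$cve,
                 n_selected = length(x$selected_channels), n = x$n)
}

#' @export
tidy.comparator_result <- function(x, ...) {
  tibble::tibble(term = names(x$weights), estimate = unname(x$weights),
                 selected = abs(unname(x$weights)) > 0)
}
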