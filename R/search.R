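#' Enumerate all nonempty channel subsets
#'
#' Every nonempty subset of `D` channels, encoded as a bitmask (bit `j` set
#' means the `j`-th channel of the dataset is included), in ascending mask
#' order. There are `2^D - 1` of them.
#'
#' @param D number of channels, 1--30.
#' @return double vector of masks `1, 2, ..., 2^D - 1` (doubles so that
#'   D > 30 cannot silently overflow R integers).
#' @examples
#' enumerate_subsets(2)   # 1, 2, 3
#' @export
enumerate_subsets <- function(D) {
  if (!is.numeric(D) || length(D) != 1 || D < 1 || D > 30 || D != round(D)) {
    stop("D must be an integer in 1..30", call. = FALSE)
  }
  seq_len(2^D - 1)
}

#' Decode a subset mask into channel ids
#' @param mask bitmask (or vector of bitmasks).
#' @param channel_ids channel ids of the dataset, in column order.
#' @return integer vector of channel ids (list of them if `mask` has
#'   length > 1).
#' @export
subset_channels <- function(mask, channel_ids) {
  one <- function(m) channel_ids[bitwAnd(floor(m / 2^(seq_along(channel_ids) - 1)), 1) == 1]
  if (length(mask) == 1) one(mask) else lapply(mask, one)
}

#' Exhaustive channel-subset search
#'
#' Scores every nonempty subset of the available channels with the linear SVM
#' under stratified K-fold cross-validation (one fixed fold assignment for
#' the whole run, so accuracies are comparable across subsets), ranks subsets
#' by cross-validation error, and summarizes the top-`top` subsets: full-data
#' refit weight matrix, per-channel occurrence counts and weight-sign
#' consistency.
#'
#' Ranking is by CVE ascending, ties broken by smaller subset size, then by
#' ascending mask — a reproducible total order that prefers parsimony.
#'
#' @param features_df feature table from [fnirs_features()] (or same shape).
#' @param channels `"all"`/`"bilateral"`, `"left"`, `"right"`, or integer ids;
#'   the search enumerates subsets of these channels only.
#' @param k folds (default 5).
#' @param C soft-margin cost (default 1).
#' @param seed seed for the fold assignment (ignored if `folds` given).
#' @param folds optional explicit fold ids.
#' @param top how many best subsets to keep in the detailed report
#'   (default 50).
#' @param chunk_size masks evaluated per chunk (checkpoint granularity).
#' @param checkpoint optional path to a TSV checkpoint ledger; an interrupted
#'   run restarted with the same arguments resumes after the last completed
#'   chunk. The final report is identical to an uninterrupted run.
#' @return object of class `channel_search`; see [tidy.channel_search()],
#'   [glance.channel_search()], [channel_occurrence()], [sign_consistency()].
#' @examples
#' sim <- simulate_fnirs_features(fnirs_sim_spec(n_channels = 6,
#'                                informative = c(`2` = 1.5, `5` = -1.5)),
#'                                seed = 1)
#' sr <- channel_search(sim$features, top = 10)
#' glance(sr)
#' @export
channel_search <- function(features_df, channels = "all", k = 5, C = 1,
                           seed = 1, folds = NULL, top = 50,
                           chunk_size = 65536L, checkpoint = NULL) {
  fm <- features_matrix(features_df)
  ids <- resolve_search_channels(channels, fm$channel_ids)
  cols <- match(ids, fm$channel_ids)
  X <- fm$X[, cols, drop = FALSE]
  D <- ncol(X)
  n <- nrow(X)
  if (is.null(folds)) folds <- kfold_assign(fm$t, k = k, seed = seed)
  k <- max(folds)
  check_folds(folds, fm$t, k)

  masks <- enumerate_subsets(D)
  errors <- evaluate_masks_chunked(X, fm$t, folds, k, masks, C,
                                   chunk_size = chunk_size,
                                   checkpoint = checkpoint)
  sizes <- mask_popcount(masks, D)
  results <- tibble::tibble(mask = masks, size = sizes, errors = errors,
                            cve = errors / n,
                            accuracy = classification_accuracy(errors, n))

  ord <- order(results$cve, results$size, results$mask)
  top_n <- min(top, nrow(results))
  top_idx <- ord[seq_len(top_n)]
  top_masks <- results$mask[top_idx]
  refit <- .refit_masks(X, as.numeric(fm$t), top_masks, C, 1e-6, 200000L)
  W <- refit$weights
  colnames(W) <- sprintf("ch%02d", ids)

  structure(list(results = results, order = ord,
                 top = tibble::tibble(rank = seq_len(top_n),
                                      mask = top_masks,
                                      size = results$size[top_idx],
                                      cve = results$cve[top_idx],
                                      accuracy = results$accuracy[top_idx],
                                      channels = subset_channels_list(top_masks, ids),
                                      intercept = as.numeric(refit$intercept)),
                 top_weights = W,
                 channel_ids = ids, n = n, k = k, C = C, seed = seed,
                 folds = folds),
            class = "channel_search")
}

subset_channels_list <- function(masks, ids) {
  out <- subset_channels(masks, ids)
  if (!is.list(out)) out <- list(out)
  out
}

resolve_search_channels <- function(channels, available) {
  if (is.character(channels) && length(channels) == 1) {
    D <- max(available)
    half <- D %/% 2
    want <- switch(channels,
                   all = available, bilateral = available,
                   left = available[available <= half],
                   right = available[available > half],
                   stop("unknown channel set '", channels, "'", call. = FALSE))
  } else {
    want <- as.integer(channels)
  }
  if (!all(want %in% available)) {
    stop("channels not present in the feature table: ",
         paste(setdiff(want, available), collapse = ", "), call. = FALSE)
  }
  sort(want)
}

mask_popcount <- function(masks, D) {
  counts <- integer(length(masks))
  for (bit in seq_len(D) - 1) {
    counts <- counts + (bitwAnd(floor(masks / 2^bit), 1) == 1)
  }
  counts
}

evaluate_masks_chunked <- function(X, t, folds, k, masks, C,
                                   chunk_size = 65536L, checkpoint = NULL) {
  nm <- length(masks)
  starts <- seq(1, nm, by = chunk_size)
  done <- 0L
  errors <- integer(0)
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- utils::read.table(checkpoint, header = TRUE, sep = "\t")
    errors <- as.integer(prev$errors)
    done <- length(errors)
  }
  for (s in starts) {
    e <- min(s + chunk_size - 1, nm)
    if (e <= done) next
    s2 <- max(s, done + 1)
    chunk <- .cv_errors_masks(X, as.numeric(t), as.integer(folds), k,
                              masks[s2:e], C, 1e-6, 200000L)
    errors <- c(errors, as.integer(chunk))
    if (!is.null(checkpoint)) {
      utils::write.table(
        data.frame(mask = masks[seq_along(errors)], errors = errors),
        checkpoint, sep = "\t", row.names = FALSE, quote = FALSE)
    }
    done <- length(errors)
  }
  errors
}

#' Evaluate an explicit list of channel-subset masks
#'
#' The streaming core of [channel_search()], exposed directly: cross-validate
#' the linear SVM for each given bitmask over the selected channels and
#' return one evaluation per mask.
#'
#' @inheritParams channel_search
#' @param masks vector of subset bitmasks over the selected channels (bit
#'   `j` = `j`-th selected channel in ascending id order).
#' @return tibble with `mask`, `size`, `errors`, `cve`, `accuracy`.
#' @export
evaluate_subsets <- function(features_df, masks, channels = "all", k = 5,
                             C = 1, seed = 1, folds = NULL) {
  fm <- features_matrix(features_df)
  ids <- resolve_search_channels(channels, fm$channel_ids)
  X <- fm$X[, match(ids, fm$channel_ids), drop = FALSE]
  if (is.null(folds)) folds <- kfold_assign(fm$t, k = k, seed = seed)
  k <- max(folds)
  check_folds(folds, fm$t, k)
  if (any(masks < 1 | masks >= 2^ncol(X))) {
    stop("masks out of range for ", ncol(X), " channels", call. = FALSE)
  }
  errors <- as.integer(.cv_errors_masks(X, as.numeric(fm$t),
                                        as.integer(folds), k,
                                        as.numeric(masks), C, 1e-6, 200000L))
  tibble::tibble(mask = as.numeric(masks),
                 size = mask_popcount(as.numeric(masks), ncol(X)),
                 errors = errors, cve = errors / nrow(X),
                 accuracy = classification_accuracy(errors, nrow(X)))
}

#' Rank subset evaluations
#'
#' Sorts a table of subset evaluations by CVE ascending, breaking ties by
#' smaller subset size, then ascending mask.
#'
#' @param results tibble with columns `mask`, `size`, `cve` (and typically
#'   `accuracy`).
#' @return the same tibble sorted, with a `rank` column prepended.
#' @export
rank_subsets <- function(results) {
  ord <- order(results$cve, results$size, results$mask)
  out <- results[ord, ]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' @export
print.channel_search <- function(x, ...) {
  best <- x$top[1, ]
  n_opt <- sum(x$results$cve == min(x$results$cve))
  cat(sprintf("Exhaustive channel-subset search: %d channels, %d subsets, %d-fold CV (N = %d)\n",
              length(x$channel_ids), nrow(x$results), x$k, x$n))
  cat(sprintf("  best accuracy: %.1f%% (CVE %d/%d), %d co-optimal subset(s)\n",
              best$accuracy, round(best$cve * x$n), x$n, n_opt))
  cat(sprintf("  best subset: {%s}\n",
              paste(best$channels[[1]], collapse = ", ")))
  invisible(x)
}

#' Tidy the ranked subset table
#'
#' @param x a `channel_search`.
#' @param n number of top-ranked subsets to return (default: all evaluated).
#' @param ... unused.
#' @return tibble with `rank`, `mask`, `size`, `cve`, `accuracy`.
#' @export
tidy.channel_search <- function(x, n = NULL, ...) {
  out <- x$results[x$order, ]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  if (!is.null(n)) out <- head(out, n)
  out
}

#' One-line summary of a search
#' @param x a `channel_search`.
#' @param ... unused.
#' @export
glance.channel_search <- function(x, ...) {
  best <- x$top[1, ]
  all_mask <- 2^length(x$channel_ids) - 1
  tibble::tibble(
    n_subsets = nrow(x$results),
    n_channels = length(x$channel_ids),
    best_accuracy = best$accuracy,
    best_cve = best$cve,
    n_optimal = sum(x$results$cve == min(x$results$cve)),
    best_size = best$size,
    all_channel_accuracy =
      x$results$accuracy[match(all_mask, x$results$mask)],
    n = x$n, k = x$k, C = x$C
  )
}

#' Optimal subsets of a search
#'
#' All subsets attaining the minimal CVE, in rank order.
#' @param search a `channel_search`.
#' @return tibble like [tidy.channel_search()] restricted to the optima, with
#'   a `channels` list-column.
#' @export
optimal_subsets <- function(search) {
  ranked <- tidy(search)
  opt <- ranked[ranked$cve == min(ranked$cve), ]
  opt$channels <- subset_channels_list(opt$mask, search$channel_ids)
  opt
}

#' Channel occurrence in the top subsets
#'
#' How many of the top-ranked subsets contain each channel.
#' @param search a `channel_search`.
#' @return tibble with `channel`, `count`, `top_k`.
#' @export
channel_occurrence <- function(search) {
  K <- nrow(search$top)
  counts <- vapply(search$channel_ids, function(ch) {
    sum(vapply(search$top$channels, function(cc) ch %in% cc, logical(1)))
  }, integer(1))
  tibble::tibble(channel = search$channel_ids, count = counts, top_k = K)
}

#' Weight-sign consistency in the top subsets
#'
#' For each channel: in how many of the top subsets its full-data refit
#' weight is positive, negative, or absent. A channel is sign-consistent if
#' all its non-absent weights share one sign. Positive weight means larger
#' oxy-Hb mean Z-scores at that channel push the decision toward the +1
#' group; negative toward the -1 group.
#'
#' @param search a `channel_search`.
#' @return tibble with `channel`, `n_positive`, `n_negative`, `n_absent`,
#'   `sign_consistent`, `sign`.
#' @export
sign_consistency <- function(search) {
  W <- search$top_weights
  K <- nrow(W)
  pos <- colSums(W > 0, na.rm = TRUE)
  neg <- colSums(W < 0, na.rm = TRUE)
  absent <- colSums(is.na(W))
  tibble::tibble(
    channel = search$channel_ids,
    n_positive = as.integer(pos),
    n_negative = as.integer(neg),
    n_absent = as.integer(absent),
    sign_consistent = (pos == 0 | neg == 0) & (pos + neg > 0),
    sign = dplyr::case_when(pos > 0 & neg == 0 ~ "+",
                            neg > 0 & pos == 0 ~ "-",
                            pos + neg == 0 ~ "absent",
                            TRUE ~ "mixed")
  )
}

#' Percentile rank of an accuracy in the exhaustive distribution
#'
#' Rank 1 is the best subset; the rank of an accuracy is one plus the number
#' of subsets scoring strictly higher. `top_fraction` is `rank / n`.
#'
#' @param accuracy accuracy in percent.
#' @param distribution numeric vector of accuracies, or a `channel_search`.
#' @return tibble with `rank`, `n`, `top_fraction`.
#' @examples
#' percentile_rank(60, c(50, 60, 70))   # rank 2 of 3
#' @export
percentile_rank <- function(accuracy, distribution) {
  if (inherits(distribution, "channel_search")) {
    distribution <- distribution$results$accuracy
  }
  if (!length(distribution)) stop("empty accuracy distribution", call. = FALSE)
  rank <- 1 + sum(distribution > accuracy)
  tibble::tibble(rank = rank, n = length(distribution),
                 top_fraction = rank / length(distribution))
}
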