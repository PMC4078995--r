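#' Two-sample t-test
#'
#' Pooled-variance two-sample t by default (`df = n_a + n_b - 2`), two-tailed;
#' the Welch variant is available with `pooled = FALSE`.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param pooled pooled-variance (default) or Welch.
#' @return tibble with `t`, `df`, `p`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 4, 6))
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("both groups degenerate (zero variance) with unequal means",
         call. = FALSE)
  }
  res <- stats::t.test(a, b, var.equal = pooled)
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value)
}

#' One-sample t-test
#'
#' `t = (mean(x) - mu0) / (sd(x) / sqrt(n))`, `df = n - 1`, two-tailed.
#'
#' @param x numeric sample of size >= 2 with nonzero SD.
#' @param mu0 null mean (default 0, the baseline of a Z-scored feature).
#' @return tibble with `t`, `df`, `p`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  stopifnot(length(x) >= 2)
  if (sd(x) == 0) stop("zero SD; one-sample t undefined", call. = FALSE)
  res <- stats::t.test(x, mu = mu0)
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control over a family of p-values (here the
#' per-channel tests).
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return tibble with `p`, `p_adj`, `significant`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, significant = adj <= q)
}

#' Channel-wise univariate screen
#'
#' The standard univariate baseline: for each channel, (i) a two-tailed
#' two-sample t-test on the mean Z-score features between the two groups, and
#' (ii) per group, a two-tailed one-sample t-test of the features against the
#' baseline value 0. Each family of 24 (or D) p-values is FDR-corrected
#' separately with Benjamini-Hochberg.
#'
#' @param features_df feature table from [fnirs_features()].
#' @param q FDR level (default 0.05).
#' @param unit `"trial"` (rows are trials, matching the classifier; default)
#'   or `"participant"` (features first averaged within participant).
#' @param pooled pooled-variance two-sample test (default).
#' @return tibble with one row per channel and family: `test` (`two_sample`,
#'   `one_sample_pos`, `one_sample_neg`), `channel`, `t`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
channel_screen <- function(features_df, q = 0.05,
                           unit = c("trial", "participant"), pooled = TRUE) {
  unit <- match.arg(unit)
  if (unit == "participant") {
    features_df <- features_df |>
      dplyr::group_by(.data$participant, .data$label) |>
      dplyr::summarise(dplyr::across(dplyr::matches("^ch\\d+$"), mean),
                       .groups = "drop")
  }
  fm <- features_matrix(features_df)
  D <- ncol(fm$X)
  pos <- fm$t == 1

  fam <- function(test, tt) {
    flags <- fdr_bh(tt$p, q = q)
    tibble::tibble(test = test, channel = fm$channel_ids,
                   t = tt$t, df = tt$df, p = tt$p,
                   p_adj = flags$p_adj, significant = flags$significant)
  }
  two <- dplyr::bind_rows(lapply(seq_len(D), function(j) {
    two_sample_t(fm$X[pos, j], fm$X[!pos, j], pooled = pooled)
  }))
  one_p <- dplyr::bind_rows(lapply(seq_len(D), function(j) {
    one_sample_t(fm$X[pos, j], 0)
  }))
  one_n <- dplyr::bind_rows(lapply(seq_len(D), function(j) {
    one_sample_t(fm$X[!pos, j], 0)
  }))
  dplyr::bind_rows(fam("two_sample", two),
                   fam("one_sample_pos", one_p),
                   fam("one_sample_neg", one_n))
}
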