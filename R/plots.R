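#' Rank-ordered accuracy curve of an exhaustive search
#'
#' Classification accuracy of every evaluated subset, best first — the
#' standard way to show how sharply the best combinations stand out from the
#' bulk of the subset distribution.
#'
#' @param object a `channel_search`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.channel_search <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$accuracy)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::labs(x = "rank-ordered subsets", y = "classification accuracy (%)",
                  title = sprintf("Exhaustive search over %d channel subsets",
                                  nrow(df))) +
    ggplot2::theme_minimal()
}

#' Top-K subset weight matrix heat map
#'
#' Rows are the top-ranked subsets, columns the channels; fill is the
#' full-data refit SVM weight (blank where the channel is absent from the
#' subset). Warm cells push the decision toward the +1 group, cool cells
#' toward the -1 group; consistently-colored columns are the sign-consistent
#' channels that drive the classification.
#'
#' @param search a `channel_search`.
#' @return a ggplot.
#' @export
plot_weight_matrix <- function(search) {
  W <- search$top_weights
  df <- tibble::as_tibble(W) |>
    dplyr::mutate(rank = seq_len(nrow(W))) |>
    tidyr::pivot_longer(-"rank", names_to = "channel", values_to = "weight") |>
    dplyr::mutate(channel = as.integer(sub("^ch", "", .data$channel)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = factor(.data$channel),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "lightyellow",
                                  high = "red", na.value = "grey15") +
    ggplot2::labs(x = "subset rank", y = "channel", fill = "weight",
                  title = sprintf("SVM weights across the best %d subsets",
                                  nrow(W))) +
    ggplot2::theme_minimal()
}

#' Channel occurrence bar chart for the top subsets
#'
#' @param search a `channel_search`.
#' @return a ggplot.
#' @export
plot_channel_occurrence <- function(search) {
  occ <- dplyr::left_join(channel_occurrence(search),
                          sign_consistency(search)[c("channel", "sign")],
                          by = "channel")
  ggplot2::ggplot(occ, ggplot2::aes(x = factor(.data$channel),
                                    y = .data$count, fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`+` = "red", `-` = "blue",
                                          absent = "grey70",
                                          mixed = "goldenrod")) +
    ggplot2::labs(x = "channel", y = sprintf("subsets (of top %d) containing channel",
                                             unique(occ$top_k)),
                  fill = "weight sign") +
    ggplot2::theme_minimal()
}
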