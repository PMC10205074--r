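# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum map
#'
#' Line plot of power (or contrast/coherence/MI) against frequency, one
#' line per channel, with the tagging frequencies marked.
#'
#' @param object An `ft_spectrum`.
#' @param channels Subset of channels to draw (default: all, or the mean if
#'   `summarise = TRUE`).
#' @param summarise Draw the channel mean only (default `FALSE`).
#' @param tags Frequencies to mark (default `c(2, 4)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ft_spectrum <- function(object, channels = NULL, summarise = FALSE,
                                 tags = c(2, 4), ...) {
  df <- tidy(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% as.character(channels))
  if (summarise) {
    df <- df |> group_by(.data$freq_hz) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      mutate(channel = "mean")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                   group = .data$channel)) +
    ggplot2::geom_vline(xintercept = tags, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(alpha = if (summarise) 1 else 0.4) +
    ggplot2::labs(x = "frequency (Hz)",
                  y = object$kind,
                  title = sprintf("%s spectrum (%s space)", object$kind, object$space)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster permutation result
#'
#' Per-node t values with significant-cluster membership highlighted.
#'
#' @param object An `ft_cluster_result`.
#' @param positions Optional nodes x 2 coordinate matrix for a spatial
#'   layout; by default nodes are placed on their index.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ft_cluster_result <- function(object, positions = NULL, ...) {
  n <- length(object$t)
  sig_nodes <- unlist(object$clusters$nodes[object$clusters$significant])
  df <- tibble(node = seq_len(n), t = object$t,
               significant = seq_len(n) %in% sig_nodes)
  if (!is.null(positions)) {
    df$x <- positions[, 1]; df$y <- positions[, 2]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$t)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                          shape = 1, size = 5, colour = "black") +
      ggplot2::scale_colour_gradient2()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$t,
                                          fill = .data$significant)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = c(-1, 1) * object$tcrit,
                          linetype = "dashed")
  }
  p + ggplot2::labs(title = sprintf("cluster test (%s design): %d significant cluster(s)",
                                    object$design, sum(object$clusters$significant))) +
    ggplot2::theme_minimal()
}

#' Plot jackknife power against block order with the fitted trend
#'
#' @param jk Tibble from [jackknife_trial_power()].
#' @param trend Optional [block_trend()] fit to overlay.
#' @return A ggplot object.
#' @export
plot_block_trend <- function(jk, trend = NULL) {
  p <- ggplot2::ggplot(jk, ggplot2::aes(x = .data$block, y = .data$jk_power)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "block", y = "jackknife power contrast") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    k <- trend$best_order
    bl <- sort(unique(jk$block))
    pred <- stats::predict(trend$fits[[k]], newdata = data.frame(block = bl))
    p <- p + ggplot2::geom_line(data = tibble(block = bl, jk_power = pred),
                                colour = "red")
  }
  p
}
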