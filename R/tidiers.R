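# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectrum map into a long tibble
#'
#' @param x An `ft_spectrum`.
#' @param ... Unused.
#' @return Tibble: `channel`, `freq_hz`, `value`, `kind`, `space`.
#' @export
tidy.ft_spectrum <- function(x, ...) {
  chan <- rownames(x$values) %||% as.character(seq_len(nrow(x$values)))
  tidyr::expand_grid(channel = chan, freq_hz = x$freqs_hz) |>
    mutate(value = as.vector(t(x$values)), kind = x$kind, space = x$space)
}

#' Tidy a transition-probability contrast
#'
#' @param x An `ft_tp_contrast`.
#' @param ... Unused.
#' @return One-row tibble: `condition`, `measurement`, `within`, `between`,
#'   `diff`, `p_value`, `p_corrected`.
#' @export
tidy.ft_tp_contrast <- function(x, ...) {
  tibble(condition = x$condition, measurement = x$measurement,
         within = mean(x$within), between = mean(x$between), diff = x$diff,
         p_value = x$p_value, p_corrected = x$p_corrected)
}

#' Tidy a cluster permutation result
#'
#' @param x An `ft_cluster_result`.
#' @param ... Unused.
#' @return The cluster table (without the node list column).
#' @export
tidy.ft_cluster_result <- function(x, ...) {
  dplyr::select(x$clusters, -"nodes")
}

#' Tidy a mixed ANOVA
#'
#' @param x An `ft_anova`.
#' @param ... Unused.
#' @return Tibble: `effect`, `df1`, `df2`, `F`, `p_value`, `pes`.
#' @export
tidy.ft_anova <- function(x, ...) x$table

#' Tidy a block-trend fit
#'
#' @param x An `ft_trend`.
#' @param order Polynomial order to report (default: the min-BIC order).
#' @param ... Unused.
#' @return Coefficient tibble for the chosen order.
#' @export
tidy.ft_trend <- function(x, order = NULL, ...) {
  k <- order %||% x$best_order
  dplyr::filter(x$table, .data$order == k)
}

#' @rdname tidy.ft_trend
#' @return `glance()`: one row per order with `order`, `bic`, `best`.
#' @export
glance.ft_trend <- function(x, ...) {
  tibble(order = seq_along(x$bic), bic = unname(x$bic),
         best = seq_along(x$bic) == x$best_order)
}
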