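# ggplot2 displays for the main result types.

#' Log-log degree distribution of a co-expression network
#'
#' @param object A `"coexpression_network"`.
#' @param ... Unused.
#' @return A ggplot: node count against degree on log10 axes, the usual
#'   display for checking a heavy-tailed (scale-free-like) connectivity
#'   pattern. No power-law fit is performed.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  degree_histogram(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot network statistics across correlation cutoffs
#'
#' @param sweep Output of [network_sweep()].
#' @return A ggplot with one facet per statistic (nodes, edges, average
#'   clustering coefficient, transitivity) against the cutoff.
#' @export
plot_network_sweep <- function(sweep) {
  sweep |>
    tidyr::pivot_longer(c("nodes", "edges", "clustering", "transitivity"),
                        names_to = "statistic", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = "Spearman coefficient cutoff", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare empirical cumulative distributions between groups
#'
#' The standard display for contrasting, e.g., correlation coefficients by
#' edge category or conservation scores by gene class.
#'
#' @param data Data frame in long form.
#' @param value,group Column names (strings) of the value and grouping
#'   variable.
#' @return A ggplot of ECDFs, one curve per group.
#' @export
plot_ecdf_comparison <- function(data, value, group) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[value]],
                                     colour = .data[[group]])) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
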