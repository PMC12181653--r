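#' Plot a cross-lagged network as a weight heatmap
#'
#' Wave-1 predictors on the y axis, wave-2 outcomes on the x axis; fill is
#' the standardized cross-lagged coefficient (autoregressive paths are not
#' shown). Edges below the display threshold are blanked.
#'
#' @param object A `clpn` network.
#' @param threshold Display threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clpn <- function(object, threshold = 0.05, ...) {
  edges <- threshold_for_display(object, threshold)
  edges$from <- factor(edges$from, levels = object$node_labels)
  edges$to <- factor(edges$to, levels = object$node_labels)
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$to, y = .data$from,
                                      fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev(object$node_labels)) +
    ggplot2::scale_x_discrete(limits = object$node_labels) +
    ggplot2::labs(x = "wave-2 outcome", y = "wave-1 predictor",
                  fill = "weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot expected-influence centralities
#'
#' @param object A [expected_influence()] table.
#' @param ... Unused.
#' @return A ggplot object with one panel per index.
#' @export
autoplot.centrality_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object[c("node", "in_ei", "out_ei")],
                              c("in_ei", "out_ei"),
                              names_to = "index", values_to = "value")
  long$node <- factor(long$node, levels = rev(object$node))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$value,
                                       yend = .data$node), linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "expected influence (signed sum of edge weights)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the case-dropping stability curve
#'
#' Median subsample-vs-full-sample centrality correlation against the drop
#' proportion, with a 5th-95th percentile ribbon and the 0.7 retention
#' threshold marked.
#'
#' @param object A [case_drop_bootstrap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_drop <- function(object, ...) {
  summ <- dplyr::summarise(
    dplyr::group_by(object$correlations, .data$proportion),
    mid = stats::median(.data$correlation, na.rm = TRUE),
    lo = stats::quantile(.data$correlation, 0.05, na.rm = TRUE),
    hi = stats::quantile(.data$correlation, 0.95, na.rm = TRUE),
    .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$proportion, y = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = sprintf("correlation with full-sample %s",
                              object$index)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot bootstrapped edge-weight intervals
#'
#' Edges ordered by point estimate, with percentile bootstrap intervals and
#' bootstrap means; heavy interval overlap warns against over-interpreting
#' edge order.
#'
#' @param object A [bootstrap_edges()] result.
#' @param max_edges Show at most this many edges by |estimate| (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_boot <- function(object, max_edges = 50, ...) {
  edges <- dplyr::mutate(object$edges,
                         edge = paste0(.data$from, "→", .data$to))
  edges <- dplyr::slice_max(edges, abs(.data$estimate), n = max_edges,
                            with_ties = FALSE)
  edges <- dplyr::arrange(edges, .data$estimate)
  edges$edge <- factor(edges$edge, levels = edges$edge)
  ggplot2::ggplot(edges, ggplot2::aes(y = .data$edge)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$boot_mean), size = 1,
                        shape = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "edge weight", y = NULL) +
    ggplot2::theme_minimal()
}
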