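# ggplot2 views of the main result types.

#' Plot a degree distribution
#'
#' @param graph An igraph object (or a tibble from
#'   [degree_distribution_tbl()]).
#' @return A ggplot.
#' @export
plot_degree_distribution <- function(graph) {
  tbl <- if (is.data.frame(graph)) graph else degree_distribution_tbl(graph)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot mixing-parameter sweep curves
#'
#' @param sweep A `qicd_sweep` tibble (possibly several row-bound together).
#' @return A ggplot of mean and max modularity against mu.
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("mean_q", "max_q"),
                              names_to = "summary", values_to = "q")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$q,
                                     colour = .data$algorithm,
                                     linetype = .data$summary)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset)) +
    ggplot2::labs(x = "mixing parameter (mu)", y = "modularity (Q)",
                  title = "Modularity across the mixing-parameter sweep") +
    ggplot2::theme_minimal()
}

#' @method autoplot qicd_sweep
#' @export
autoplot.qicd_sweep <- function(object, ...) plot_sweep(object)

#' Heatmap of partition-quality metrics per dataset
#'
#' @param scalars A tibble with columns `dataset`, `q`, `nmi`, `ari` (one row
#'   per dataset), e.g. row-bound `metric_report()$scalars`.
#' @return A ggplot tile map.
#' @export
plot_metric_heatmap <- function(scalars) {
  long <- tidyr::pivot_longer(scalars, dplyr::any_of(c("q", "nmi", "ari")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$dataset,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$value))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(title = "Partition quality per dataset", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plots of community-aggregated driver correlations
#'
#' @param corr A `qicd_correlation` result (with its `"aggregates"`
#'   attribute).
#' @return A ggplot, one facet per (variable, pair).
#' @export
plot_correlation <- function(corr) {
  aggs <- attr(corr, "aggregates")
  pts <- purrr::imap(aggs, function(a, var) {
    pairs <- if (length(a) == 3) {
      list(c("I2", "I1"), c("I3", "I1"), c("I3", "I2"))
    } else {
      list(c("I2", "I1"))
    }
    purrr::map(pairs, function(pr) {
      tibble::tibble(variable = var, pair = paste0(pr[1], pr[2]),
                     community = a[[pr[2]]]$community,
                     x = a[[pr[2]]]$value, y = a[[pr[1]]]$value)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$community)), size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable, .data$pair), scales = "free") +
    ggplot2::labs(x = "earlier aggregate", y = "later aggregate",
                  colour = "community",
                  title = "Community-aggregated driver correlations") +
    ggplot2::theme_minimal()
}

#' @method autoplot qicd_correlation
#' @export
autoplot.qicd_correlation <- function(object, ...) plot_correlation(object)

#' Network plot with vertices sized by a centrality
#'
#' @param graph An igraph object.
#' @param size_by `"degree"` or `"betweenness"`.
#' @param partition Optional partition tibble for vertex colors.
#' @return A ggplot built from a fixed-seed Fruchterman-Reingold layout.
#' @export
plot_network <- function(graph, size_by = c("degree", "betweenness"),
                         partition = NULL) {
  size_by <- match.arg(size_by)
  set.seed(42)
  lay <- igraph::layout_with_fr(graph)
  nodes <- tibble::tibble(
    unit_id = igraph::V(graph)$name,
    x = lay[, 1], y = lay[, 2],
    size = switch(size_by,
                  degree = igraph::degree(graph),
                  betweenness = igraph::betweenness(graph, directed = FALSE))
  )
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, partition, by = "unit_id")
  } else {
    nodes$community <- 1L
  }
  el <- igraph::as_edgelist(graph)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$unit_id)],
    y = nodes$y[match(el[, 1], nodes$unit_id)],
    xend = nodes$x[match(el[, 2], nodes$unit_id)],
    yend = nodes$y[match(el[, 2], nodes$unit_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     colour = factor(.data$community))) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$unit_id),
                       size = 2.5, vjust = -1) +
    ggplot2::labs(size = size_by, colour = "community") +
    ggplot2::theme_void()
}
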