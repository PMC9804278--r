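#' Plot a spatial graph
#'
#' Edges as segments, nodes as points coloured by kind (when present).
#'
#' @param object a [build_graph()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot spatial_graph
#' @export
autoplot.spatial_graph <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[, c("id", "x", "y")],
                                          from = "id", x0 = "x", y0 = "y"),
                            by = "from")
  edges <- dplyr::left_join(edges,
                            dplyr::rename(nodes[, c("id", "x", "y")],
                                          to = "id", x1 = "x", y1 = "y"),
                            by = "to")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      colour = "grey60", linewidth = 0.3)
  if ("kind" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 colour = .data$kind), size = 2)
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y), size = 2)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot predicted flows on the landscape
#'
#' Flagged edges (flow at or above the cutoff) drawn dark; the rest faint.
#'
#' @param object a [predict_flow()] result.
#' @param graph the graph the flows were predicted on (for coordinates).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot flow_table
#' @export
autoplot.flow_table <- function(object, graph, ...) {
  nodes <- graph$nodes
  df <- dplyr::left_join(object,
                         dplyr::rename(nodes[, c("id", "x", "y")],
                                       from = "id", x0 = "x", y0 = "y"),
                         by = "from")
  df <- dplyr::left_join(df,
                         dplyr::rename(nodes[, c("id", "x", "y")],
                                       to = "id", x1 = "x", y1 = "y"),
                         by = "to")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$flow,
                   alpha = .data$flagged),
      linewidth = 0.5) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 1.2, colour = "black") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.15, `TRUE` = 1)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)",
                  colour = "Flow", alpha = "Connected") +
    ggplot2::theme_minimal()
}

#' Plot a gravity-model AICc ranking
#'
#' @param object a [rank_models_aicc()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gravity_ranking
#' @export
autoplot.gravity_ranking <- function(object, ...) {
  df <- as_tibble(object)
  df$hypothesis <- stats::reorder(df$hypothesis, -df$aicc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aicc,
                                   y = .data$hypothesis)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged), size = 2.5) +
    ggplot2::labs(x = expression(Delta * "AICc"), y = NULL,
                  shape = "Converged") +
    ggplot2::theme_minimal()
}

#' Histogram of RDA loadings with outlier thresholds
#'
#' @param object an [fit_rda()] result.
#' @param axis constrained axis to plot.
#' @param threshold_sd threshold drawn as vertical lines.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rda_model
#' @export
autoplot.rda_model <- function(object, axis = 1, threshold_sd = 3.5, ...) {
  l <- object$loadings[, axis]
  thr <- mean(l) + c(-1, 1) * threshold_sd * sd(l)
  ggplot2::ggplot(tibble(loading = l),
                  ggplot2::aes(x = .data$loading)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = thr, linetype = 2, colour = "red") +
    ggplot2::labs(x = sprintf("Loading on constrained axis %d", axis),
                  y = "SNPs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
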