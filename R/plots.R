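#' Plot group trajectories with SEM ribbons
#'
#' One panel per unit/region, mean sample entropy per age window and group
#' with a shaded standard-error ribbon.
#'
#' @param object A [group_trajectory()] table.
#' @param units Which units to draw (default the whole brain).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_table <- function(object, units = "whole_brain", ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$unit %in% units) |>
    dplyr::mutate(panel = dplyr::if_else(.data$unit == "whole_brain",
                                         "whole brain",
                                         sprintf("region %d", .data$region_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_index, y = .data$mean,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "age window", y = "sample entropy (nats)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of differential complexity curves
#'
#' Regions by age windows, blue where the case group is less complex than
#' controls and red where it is more complex.
#'
#' @param object A [differential_curves()] tibble.
#' @param order Optional row order (e.g. a dendrogram leaf order).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.differential_curves <- function(object, order = NULL, ...) {
  d <- tibble::as_tibble(object) |> dplyr::filter(.data$unit == "region")
  if (!is.null(order)) {
    d$region_id <- factor(d$region_id, levels = unique(d$region_id)[order])
  } else {
    d$region_id <- factor(d$region_id)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_index, y = .data$region_id,
                                  fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white", high = "red3",
                                  midpoint = 0) +
    ggplot2::labs(x = "age window", y = "region",
                  fill = "case - control\n(nats)") +
    ggplot2::theme_minimal()
}

#' Plot a clustering of differential curves
#'
#' Per-cluster mean differential trajectories, one line per cluster.
#'
#' @param object A `cluster_result` from [cluster_curves()].
#' @param curves The differential curves the clustering was fit to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, curves, ...) {
  m <- if (is.matrix(curves)) curves else curves_matrix(curves)
  mc <- cluster_mean_curves(m[names(object$labels), , drop = FALSE],
                            object$labels)
  ggplot2::ggplot(mc$means,
                  ggplot2::aes(x = .data$window_index, y = .data$mean_diff,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age window", y = "mean differential entropy (nats)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
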