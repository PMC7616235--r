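#' Silhouette profile of a clustering result
#'
#' Mean silhouette against candidate cluster number, with the selected K
#' marked.
#'
#' @param object a `traj_clusters` object.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.traj_clusters <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = object$silhouette_by_k$k) +
    ggplot2::labs(x = "candidate number of clusters K",
                  y = "mean silhouette",
                  title = paste0("silhouette-selected K = ", object$K)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot clone trajectories in two embedding dimensions
#'
#' @param trajectories a `trajectory_set`.
#' @param dims two embedding dimensions to draw.
#' @param clusters optional `traj_clusters` to colour trajectories by
#'   cluster.
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, dims = c(1, 2), clusters = NULL) {
  tab <- tidy.trajectory_set(trajectories) |>
    dplyr::filter(.data$dim %in% dims) |>
    tidyr::pivot_wider(names_from = "dim", values_from = "value",
                       names_prefix = "d")
  xcol <- paste0("d", dims[1]); ycol <- paste0("d", dims[2])
  if (!is.null(clusters)) {
    tab <- dplyr::left_join(tab, clusters$assignment, by = "clone_id") |>
      dplyr::mutate(cluster = factor(.data$cluster))
    aes <- ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                        group = .data$clone_id, colour = .data$cluster)
  } else {
    aes <- ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                        group = .data$clone_id)
  }
  ggplot2::ggplot(tab, aes) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::labs(x = paste("embedding dim", dims[1]),
                  y = paste("embedding dim", dims[2])) +
    ggplot2::theme_minimal()
}

#' Spatial distribution bias across clones
#'
#' Dot plot of spleen/tumor frequency ratios on a log-friendly axis; bias 0
#' (tumor-confined clones) is shown at the axis floor.
#'
#' @param clones clone tibble with a `bias` column
#'   ([spatial_distribution_bias()]).
#' @param group optional column name to facet/colour by (e.g. a cluster
#'   label).
#' @return A ggplot.
#' @export
plot_spatial_bias <- function(clones, group = NULL) {
  floor_val <- min(clones$bias[clones$bias > 0], 1) / 10
  tab <- dplyr::mutate(clones, bias_plot = pmax(.data$bias, floor_val))
  aes <- if (is.null(group)) {
    ggplot2::aes(x = "", y = .data$bias_plot)
  } else {
    ggplot2::aes(x = factor(.data[[group]]), y = .data$bias_plot)
  }
  ggplot2::ggplot(tab, aes) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = group %||% "", y = "spleen / tumor frequency") +
    ggplot2::theme_minimal()
}
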