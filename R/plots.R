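# Diagnostic plots: correlation-matrix raster and embedding scatter.

#' Raster plot of a correlation matrix
#'
#' Draws the matrix with the conventional colour scale for bounded
#' coefficients: blue at 0 (no net positive correlation), white at 0.5, red
#' at 1. When the matrix has been reordered by cluster
#' ([reorder_matrix()]), alternating grey/black bars along both margins mark
#' the cluster blocks.
#'
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  labels <- rownames(object)
  df <- tidy(object)
  df$dataset_m <- factor(df$dataset_m, levels = labels)
  df$dataset_n <- factor(df$dataset_n, levels = rev(labels))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset_m,
                                        y = .data$dataset_n,
                                        fill = .data$coefficient)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#1f4e9c", mid = "white",
                                  high = "#c0202a", midpoint = 0.5,
                                  limits = c(0, 1),
                                  name = "bounded r") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  blocks <- attr(object, "blocks")
  if (!is.null(blocks) && length(blocks) > 1) {
    ends <- cumsum(blocks)
    starts <- c(0, head(ends, -1))
    n <- length(labels)
    bars <- tibble(xmin = starts + 0.5, xmax = ends + 0.5,
                   shade = rep(c("a", "b"), length.out = length(blocks)))
    p <- p +
      ggplot2::geom_rect(data = bars, inherit.aes = FALSE,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      fill = NULL),
                         ymin = n + 0.6, ymax = n + 1.1,
                         fill = rep(c("grey25", "grey65"),
                                    length.out = nrow(bars))) +
      ggplot2::geom_rect(data = bars, inherit.aes = FALSE,
                         ggplot2::aes(ymin = n - .data$xmax + 1,
                                      ymax = n - .data$xmin + 1, fill = NULL),
                         xmin = -0.1, xmax = 0.4,
                         fill = rep(c("grey25", "grey65"),
                                    length.out = nrow(bars)))
  }
  p
}

#' Scatter plot of an SVD embedding
#'
#' Plots the first two embedding axes; the third is mapped to point size so
#' a flat figure still hints at the 3-D structure.
#'
#' @param object An `axis_projection`.
#' @param colour Optional vector (length N, aligned with the projection
#'   rows) used to colour points, e.g. cluster labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot axis_projection
#' @export
autoplot.axis_projection <- function(object, colour = NULL, ...) {
  df <- as_tibble(object)
  axes <- attr(object, "axes")
  if (!is.null(colour)) df$colour <- factor(colour)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2,
                                        size = .data$s3)) +
    ggplot2::scale_size_continuous(range = c(1, 3.5),
                                   name = sprintf("axis %d", axes[3])) +
    ggplot2::labs(x = sprintf("SVD axis %d", axes[1]),
                  y = sprintf("SVD axis %d", axes[2])) +
    ggplot2::theme_minimal()
  if (!is.null(colour))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.8) +
      ggplot2::labs(colour = "cluster")
  else p + ggplot2::geom_point(alpha = 0.8)
}

#' Embedding plot of a clustering result, coloured by terminal cluster
#'
#' @param object An `mds_clustering` from [cluster_datasets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mds_clustering
#' @export
autoplot.mds_clustering <- function(object, ...) {
  assignment <- tidy(object$tree)
  cl <- assignment$cluster_path[match(object$projection$dataset_id,
                                      assignment$dataset_id)]
  autoplot(object$projection, colour = cl)
}
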