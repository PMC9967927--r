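#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot individual ordination scores
#'
#' Scatter plot of the first two principal components, coloured by
#' population when labels are available.
#'
#' @param object A [pca()] result.
#' @param components Two component indices to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot marker_pca
#' @export
autoplot.marker_pca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  px <- paste0("PC", components[1])
  py <- paste0("PC", components[2])
  ev <- object$explained_variance
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[px]], .data[[py]]))
  p <- if (all(is.na(sc$population))) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$population), alpha = 0.8)
  }
  p +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", px, 100 * ev[components[1]]),
      y = sprintf("%s (%.1f%%)", py, 100 * ev[components[2]]),
      colour = "Population"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise distance matrix
#'
#' Heat-map of pairwise Nei distances among populations.
#'
#' @param object A [distance_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nei_dist
#' @export
autoplot.nei_dist <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::bind_rows(
    long,
    dplyr::rename(long, pop_a = "pop_b", pop_b = "pop_a"),
    tibble::tibble(pop_a = object$labels, pop_b = object$labels, distance = 0)
  )
  long$pop_a <- factor(long$pop_a, levels = object$labels)
  long$pop_b <- factor(long$pop_b, levels = object$labels)
  ggplot2::ggplot(long, ggplot2::aes(.data$pop_a, .data$pop_b, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Nei's D") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a UPGMA phenogram
#'
#' Rectangular dendrogram of an ultrametric phenogram, drawn with ggplot2
#' from the tree's node heights.
#'
#' @param tree A [upgma()] phenogram (any `phylo` with branch lengths works).
#' @return A ggplot.
#' @export
plot_phenogram <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n_tip)]) - depth # height above the leaves
  # leaf y positions in plotted order, internal nodes midway over children
  ord <- tree$edge[tree$edge[, 2] <= n_tip, 2]
  y <- numeric(max(tree$edge))
  y[ord] <- seq_along(ord)
  for (node in rev(sort(unique(tree$edge[, 1])))) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    y[node] <- mean(y[children])
  }
  seg_v <- tibble::tibble(
    x = height[tree$edge[, 1]], xend = height[tree$edge[, 2]],
    y = y[tree$edge[, 2]], yend = y[tree$edge[, 2]]
  )
  seg_h <- dplyr::bind_rows(lapply(unique(tree$edge[, 1]), function(node) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    tibble::tibble(x = height[node], xend = height[node],
                   y = min(y[children]), yend = max(y[children]))
  }))
  labs <- tibble::tibble(x = height[seq_len(n_tip)],
                         y = y[seq_len(n_tip)], label = tree$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(seg_v, seg_h),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       hjust = 1.1, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Nei's D / 2", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}
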