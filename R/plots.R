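#' Plot a semantic-space embedding
#'
#' Scatterplot of the first two embedding dimensions, optionally coloured
#' and labelled by a per-stimulus grouping such as the modal name.
#'
#' @param object a [embed_space()] result.
#' @param labels optional named character vector: label per stimulus.
#' @param dims which two dimensions to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.space_embedding <- function(object, labels = NULL, dims = c(1, 2),
                                     ...) {
  df <- tibble::tibble(
    stimulus = rownames(object$coords),
    x = object$coords[, dims[1]],
    y = object$coords[, dims[2]]
  )
  if (!is.null(labels)) df$label <- labels[df$stimulus]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = sprintf("Dimension %d (%.0f%%)", dims[1],
                  100 * object$explained_variance[dims[1]]),
      y = sprintf("Dimension %d (%.0f%%)", dims[2],
                  100 * object$explained_variance[dims[2]])
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                        colour = .data$label),
                           size = 2.5, show.legend = FALSE)
  }
}

#' Plot a preference-quantile sweep
#'
#' Cluster count, silhouette and (when available) ARI against the
#' preference quantile q; non-converged runs are hollow.
#'
#' @param object a [q_sweep()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.q_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "q", "n_clusters", "silhouette", "ari", "converged"),
    cols = c("n_clusters", "silhouette", "ari"),
    names_to = "metric", values_to = "value"
  )
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "preference quantile q", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an acoustic decision map
#'
#' Shaded multinomial decision regions over the first two acoustic
#' principal components, with the stimuli on top.
#'
#' @param object a [multinomial_decision_map()] result.
#' @param pc_scores optional stimulus x 2 score matrix to overlay.
#' @param labels optional label per stimulus for the overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.decision_map <- function(object, pc_scores = NULL, labels = NULL,
                                  ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$predicted), alpha = 0.35) +
    ggplot2::theme_minimal() +
    ggplot2::labs(fill = "predicted class")
  if (!is.null(pc_scores)) {
    pts <- tibble::tibble(PC1 = pc_scores[, 1], PC2 = pc_scores[, 2])
    if (!is.null(labels)) {
      pts$label <- labels
      p <- p + ggplot2::geom_text(data = pts,
                                  ggplot2::aes(label = .data$label), size = 2.5)
    } else {
      p <- p + ggplot2::geom_point(data = pts, size = 0.8)
    }
  }
  p
}

#' Plot a dimensionality sweep of the triad embedding
#'
#' Normalized negative WAIC (larger is better) and any reference
#' correlations against the embedding dimensionality.
#'
#' @param object a [dimension_sweep()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dimension_sweep <- function(object, ...) {
  keep <- c("d", "neg_waic_norm", grep("^r_", names(object), value = TRUE))
  df <- tidyr::pivot_longer(dplyr::select(object, dplyr::all_of(keep)),
                            cols = -"d", names_to = "metric",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$d)) +
    ggplot2::labs(x = "embedding dimensionality d", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cladogram
#'
#' Dendrogram of the average-linkage tree as segments, tips at height 0.
#'
#' @param object a [hierarchical_cladogram()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cladogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  tip_x <- setNames(seq_len(n), hc$order)
  # x position and height of every merge node
  node_x <- numeric(nrow(hc$merge)); node_h <- hc$height
  get_x <- function(ref, row) {
    if (ref < 0) tip_x[as.character(-ref)] else node_x[ref]
  }
  segs <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    xl <- get_x(hc$merge[i, 1], i); xr <- get_x(hc$merge[i, 2], i)
    hl <- if (hc$merge[i, 1] < 0) 0 else node_h[hc$merge[i, 1]]
    hr <- if (hc$merge[i, 2] < 0) 0 else node_h[hc$merge[i, 2]]
    node_x[i] <- (xl + xr) / 2
    segs[[i]] <- tibble::tibble(
      x = c(xl, xr, xl), xend = c(xl, xr, xr),
      y = c(hl, hr, node_h[i]), yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  tips <- tibble::tibble(x = unname(tip_x),
                         label = (hc$labels %||% as.character(seq_len(n)))[hc$order])
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 2.8) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(stimulus = names(x$assignment),
                 cluster = unname(x$assignment),
                 is_exemplar = names(x$assignment) %in% x$exemplars)
}

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, q = x$q, damping = x$damping,
                 converged = x$converged, iterations = x$iterations,
                 net_similarity = x$net_similarity)
}

#' @export
tidy.space_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(stimulus = rownames(x$coords)),
                   tibble::as_tibble(x$coords))
}

#' @export
glance.space_embedding <- function(x, ...) {
  tibble::tibble(k = ncol(x$coords), method = x$method,
                 variance_explained = sum(x$explained_variance))
}

#' @export
tidy.embedding_posterior <- function(x, ...) {
  m <- x$mean_distance_matrix
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(stimulus_a = rownames(m)[idx[, 1]],
                 stimulus_b = colnames(m)[idx[, 2]],
                 mean_distance = m[idx])
}

#' @export
glance.embedding_posterior <- function(x, ...) {
  w <- waic(x$pointwise_loglik)
  dplyr::bind_cols(
    tibble::tibble(d = x$config$d, n_draws = dim(x$draws)[1],
                   n_triads = x$n_triads, waic = w$waic, p_waic = w$p_waic),
    x$diagnostics
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
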