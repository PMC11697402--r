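#' Heatmap of an interaction-density matrix
#'
#' @param object a `density_matrix` from [interaction_density()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot density_matrix
#' @export
autoplot.density_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(object$D))
  names(df) <- c("bin_a", "bin_b", "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_a, y = .data$bin_b,
                                   fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Interaction\ndensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Performance overview of a recovery benchmark
#'
#' Per-network distribution of robust-Z performance scores across gene
#' sets, ordered by overall centralized rank (best on top).
#'
#' @param object a `recovery_benchmark` from [benchmark_recovery()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot recovery_benchmark
#' @export
autoplot.recovery_benchmark <- function(object, ...) {
  ord <- rev(object$networks$network)
  df <- object$results
  df$network <- factor(df$network, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$network)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.8, fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "Performance (robust Z vs degree-matched nulls)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-fold precision@k of a cross-validation run
#'
#' @param object a `cv_precision` tibble from [cross_validate()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_precision
#' @export
autoplot.cv_precision <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$p_at_k)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mean_p_at_k"),
                        linetype = 2) +
    ggplot2::labs(x = "Fold", y = "Precision@k",
                  title = paste("Held-out interaction prediction,",
                                attr(object, "algorithm"))) +
    ggplot2::theme_minimal()
}

#' Composite-size decay across support thresholds
#'
#' Edge counts of global composites G_k for a range of k, on a log scale.
#'
#' @param support a support index from [count_edge_support()].
#' @param k_max largest threshold to show (default: max observed support).
#' @return a ggplot object.
#' @export
plot_composite_sizes <- function(support, k_max = NULL) {
  k_max <- k_max %||% max(support$support)
  df <- tibble::tibble(
    k = seq_len(k_max),
    n_edges = vapply(seq_len(k_max), function(k) sum(support$support >= k), 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$n_edges)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Minimum supporting networks (k)",
                  y = "Interactions in G_k") +
    ggplot2::theme_minimal()
}
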