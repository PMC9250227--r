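#' Plot a depth-robustness curve
#'
#' Spearman correlation (or mean square deviation) against sequencing depth,
#' one point per replicate with the per-depth mean overlaid. Depth is on a
#' log axis.
#'
#' @param object A `downsample_curve` from [depth_robustness()].
#' @param metric `"spearman_r"` or `"mean_square_deviation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot downsample_curve
#' @export
autoplot.downsample_curve <- function(object,
                                      metric = c("spearman_r",
                                                 "mean_square_deviation"),
                                      ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$depth, y = .data[[metric]])) +
    geom_point(alpha = 0.4) +
    stat_summary(fun = mean, geom = "line", colour = "steelblue") +
    scale_x_log10() +
    labs(x = "target depth (reads per sample)",
         y = switch(metric,
                    spearman_r = "Spearman r vs truth",
                    mean_square_deviation = "mean square deviation"),
         title = "Fiber-fraction accuracy vs sequencing depth") +
    theme_bw()
}

#' Plot estimated cluster proportions per sample
#'
#' Stacked per-sample composition bars of the fitted cluster fractions.
#'
#' @param object A `fiber_proportions` from [deconvolve_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fiber_proportions
#' @export
autoplot.fiber_proportions <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$sample_id, y = .data$fraction,
                   fill = .data$cluster)) +
    geom_col(position = "fill") +
    labs(x = "sample", y = "estimated fraction", fill = "cluster",
         title = "Deconvolved nuclei-type composition") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Heatmap of a signature matrix
#'
#' Mean marker expression per cluster on a log1p color scale.
#'
#' @param object A [signature_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_matrix
#' @export
autoplot.signature_matrix <- function(object, ...) {
  df <- as_tibble(object$values, rownames = "gene")
  long <- tidyr::pivot_longer(df, cols = -"gene", names_to = "cluster",
                              values_to = "mean_cpm")
  ggplot(long, aes(x = .data$cluster, y = .data$gene,
                   fill = log1p(.data$mean_cpm))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log1p(mean CPM)") +
    labs(x = "cluster", y = "marker gene",
         title = "Cluster expression signatures") +
    theme_bw()
}

#' Dot plot of detected markers
#'
#' Fold change and in-cluster detection fraction per marker and cluster.
#'
#' @param object A `marker_table` from [find_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_table
#' @export
autoplot.marker_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$cluster, y = .data$gene,
                 size = .data$pct_in, colour = .data$log_fold_change)) +
    geom_point() +
    ggplot2::scale_colour_viridis_c() +
    labs(x = "cluster", y = "marker gene", size = "detected in cluster",
         colour = "ln fold change", title = "Cluster markers") +
    theme_bw()
}
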