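#' Plot PCA loadings of food-group frequencies
#'
#' Scatter of variable loadings on the first two principal components,
#' labelled by variable name — the standard way of reading dietary
#' patterns off a PCA of food-group frequencies.
#'
#' @param pca A `meddiet_pca` from [pca_loadings()].
#' @return A ggplot object.
#' @export
plot_pca_loadings <- function(pca) {
  df <- pca$loadings
  evr <- pca$explained_variance_ratio
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 1, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$variable),
                       size = 2.6, vjust = -0.6, check_overlap = TRUE) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * evr[2]),
      title = "PCA loadings of cumulative food-group frequencies"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of mean random-forest variable importances
#'
#' @param summary A `meddiet_rf_summary`.
#' @param top_n Number of top variables shown (default 30).
#' @param threshold Optional importance threshold drawn as a reference
#'   line (default 0.01, the selection rule).
#' @return A ggplot object.
#' @export
plot_importances <- function(summary, top_n = 30, threshold = 0.01) {
  df <- head(summary$importances, top_n)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_importance, y = .data$variable)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "mean importance over repeats", y = NULL,
                  title = "Random-forest variable importance") +
    ggplot2::theme_minimal()
}
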