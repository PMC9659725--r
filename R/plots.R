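# ggplot2 views of the main result types. These mirror the figures a
# behavioral/proteomic study reports: survival curves for the feeding
# latency, score distributions per arm, an ordered expression heatmap, and
# a PCA score plot with group ellipses.

#' @method autoplot ecsig_km
#' @export
autoplot.ecsig_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Latency to feed (s)",
                  y = "Fraction not having eaten",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Boxplot of composite emotionality scores per arm and session
#'
#' @param scores Output of [emotionality_scores()].
#' @return A ggplot.
#' @export
plot_emotionality <- function(scores) {
  check_columns(scores, c("group", "session", "emotionality"), "scores")
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$group, y = .data$emotionality,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = NULL, y = "Emotionality score (composite z)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @method autoplot ecsig_bicluster
#' @export
autoplot.ecsig_bicluster <- function(object, ...) {
  cm <- object$centered
  ord_r <- object$rows$order
  ord_c <- object$cols$order
  long <- as_tibble(cm, rownames = "protein") %>%
    tidyr::pivot_longer(-"protein", names_to = "sample",
                        values_to = "abundance") %>%
    mutate(
      protein = factor(.data$protein, levels = rownames(cm)[ord_r]),
      sample = factor(.data$sample, levels = colnames(cm)[ord_c])
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$protein,
                                     fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Centered\nabundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot ecsig_pca
#' @export
autoplot.ecsig_pca <- function(object, ...) {
  ve <- round(100 * object$var_explained[1:2], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.68, linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2]),
                  colour = "Group") +
    ggplot2::theme_minimal()
}
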