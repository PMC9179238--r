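#' Plot HRDCC time courses
#'
#' Per-population percentage against DIM, faceted by population, for one
#' matrix of a study result table.
#'
#' @param object An `hrdcc_result` tibble from [run_study_hrdcc()].
#' @param matrix `"milk"` or `"blood"`.
#' @param nodes Populations to show (default: the lymphocyte subsets).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrdcc_result <- function(object, matrix = "milk",
                                  nodes = c("gdT", "CD4T", "CD8T", "NK", "B"),
                                  ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::filter(df, .data$matrix == !!matrix, .data$node %in% nodes,
                      .data$mode == df$mode[1], is.finite(.data$percent))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim, y = .data$percent,
                                   colour = .data$animal_id)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::labs(x = "DIM", y = "% of parent", colour = "cow") +
    ggplot2::theme_minimal()
}

#' Plot a haptoglobin series with detected episodes
#'
#' @param data Haptoglobin series (`dim`, `value`).
#' @param episodes Episode tibble from [detect_episodes()].
#' @param threshold Episode threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_episodes <- function(data, episodes, threshold) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dim, y = .data$value))
  if (nrow(episodes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = episodes,
      ggplot2::aes(xmin = .data$start_dim, xmax = .data$end_dim,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15)
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "DIM", y = "haptoglobin (a.u.)") +
    ggplot2::theme_minimal()
}
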