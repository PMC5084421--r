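# ggplot2 views of the main result types.

#' Manhattan plot of score tracks
#'
#' @param tracks A tidy track tibble (raw tracks or axis scores).
#' @param tests Optional subset of tests to plot.
#' @return A ggplot object (position vs value, population x test facets).
#' @export
plot_manhattan <- function(tracks, tests = NULL) {
  if (!is.null(tests)) tracks <- tracks[tracks$test %in% tests, ]
  ggplot2::ggplot(tracks[!is.na(tracks$value), ],
                  ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$value,
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        cols = ggplot2::vars(.data$test), scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = "score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.score_correlations <- function(object, ...) {
  ord <- rownames(object$corr)[object$order]
  df <- as_tibble(object$corr, rownames = "test_a") %>%
    tidyr::pivot_longer(-"test_a", names_to = "test_b", values_to = "r") %>%
    dplyr::mutate(test_a = factor(.data$test_a, levels = ord),
                  test_b = factor(.data$test_b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$test_a, .data$test_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.sweep_axes_fa <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$test, fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
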