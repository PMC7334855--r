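#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a trait x tissue enrichment profile
#'
#' Tiles are -log10 empirical enrichment p; cells passing the FDR threshold
#' are starred.
#'
#' @param object an `enrichment_profile` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tissue, y = .data$trait,
                               fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = dplyr::filter(object, .data$significant),
      label = "*", colour = "white", size = 5) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] * p)) +
    ggplot2::labs(x = "tissue", y = "trait") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a correlation matrix
#'
#' @param object a `correlation_matrix` tibble from [modality_correlation()]
#'   or [trait_correlation()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  axes <- names(object)[1:2]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[axes[2]]], y = .data[[axes[1]]],
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = dplyr::filter(object, .data$significant),
      label = "*", size = 5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Null distribution of a circular-rotation sum test
#'
#' Histogram of the rotated sums with the observed statistic marked.
#'
#' @param x a `sum_test` object.
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(x, bins = 40) {
  df <- tibble::tibble(null_T = x$null_T)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_T)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70") +
    ggplot2::geom_vline(xintercept = x$T_obs, colour = "red") +
    ggplot2::labs(x = "rotated sum", y = "count",
                  subtitle = sprintf("observed = %.3g, p = %.3g",
                                     x$T_obs, x$p_emp)) +
    ggplot2::theme_minimal()
}

#' Transfer efficiency per histone mark
#'
#' Bar chart of peak-level transfer efficiencies, one bar per mark (or any
#' grouping present in the lift reports).
#'
#' @param results lift report tibble with an added `mark` column, or a named
#'   list of lift reports (names become marks).
#' @return A ggplot object.
#' @export
plot_transfer_efficiency <- function(results) {
  if (is.data.frame(results)) results <- list(all = results)
  df <- purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(mark = nm, efficiency = transfer_efficiency(r))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mark, y = .data$efficiency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "transfer efficiency") +
    ggplot2::theme_minimal()
}
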