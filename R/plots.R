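# ggplot2 views of screen and response results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-order plot of a screen summary
#'
#' Per-guide mean frameshift rate (points) with +/- SD bars, ordered by
#' rank — the standard view of a guide screen readout.
#'
#' @param summary Tibble from [summarize_screen()].
#' @return A ggplot object.
#' @export
plot_screen_ranks <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$rank, y = .data$mean_frameshift)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_frameshift - dplyr::coalesce(.data$sd_frameshift, 0),
      ymax = .data$mean_frameshift + dplyr::coalesce(.data$sd_frameshift, 0)),
      width = 0.3, color = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "guide rank (by mean frameshift rate)",
                  y = "frameshift rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.editing_concordance <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "rate, condition 1", y = "rate, condition 2",
      subtitle = sprintf("slope = %.2f, r^2 = %.3f", object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.editing_regression <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$frameshift_rate, y = .data$response)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frameshift editing rate", y = "response",
                  subtitle = sprintf("slope = %.2f, r^2 = %.3f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.editing_pca <- function(object, color = "group", ...) {
  aes <- if (color %in% names(object$samples)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, color = .data[[color]])
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(object$samples, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de Tibble from [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc, y = -log10(.data$padj),
                                   color = .data$de_flag)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                name = "DE") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
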