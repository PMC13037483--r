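#' Parity plot of predicted versus experimental retention time
#'
#' @param x A `qsrr_eval` object or its residual tibble.
#' @return A ggplot: predicted vs experimental RT by partition with
#'   the identity line.
#' @export
plot_parity <- function(x) {
  res <- if (inherits(x, "qsrr_eval")) x$residuals else x
  ggplot2::ggplot(res, ggplot2::aes(x = .data$y_exp, y = .data$y_pred,
                                    colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Experimental RT (min)", y = "Predicted RT (min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Residual plots for a fitted retention model
#'
#' @param x A `qsrr_eval` object or its residual tibble.
#' @param type `"fitted"` (residual vs predicted RT) or `"index"`
#'   (residual vs compound count).
#' @return A ggplot faceted by partition.
#' @export
plot_residuals <- function(x, type = c("fitted", "index")) {
  type <- match.arg(type)
  res <- if (inherits(x, "qsrr_eval")) x$residuals else x
  res$count <- seq_len(nrow(res))
  p <- if (type == "fitted") {
    ggplot2::ggplot(res, ggplot2::aes(x = .data$y_pred, y = .data$residual)) +
      ggplot2::labs(x = "Predicted RT (min)", y = "Residual (min)")
  } else {
    ggplot2::ggplot(res, ggplot2::aes(x = .data$count, y = .data$residual)) +
      ggplot2::labs(x = "Compound", y = "Residual (min)")
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~partition, scales = "free_x") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qsrr_eval <- function(object, ...) plot_parity(object)

#' Selection-frequency plot for a GA consensus
#'
#' @param object A `qsrr_ga` object.
#' @param top Show the `top` most frequently selected descriptors.
#' @param ... Unused.
#' @return A ggplot bar chart of selection frequency, final-mask
#'   members highlighted.
#' @export
autoplot.qsrr_ga <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(object$frequency, .data$frequency, n = top,
                         with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$descriptor, .data$frequency),
    y = .data$frequency, fill = .data$in_final)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Selection frequency across GA runs",
                  fill = "In final mask") +
    ggplot2::theme_minimal()
}

#' Sensitivity-ranking plot for neural-network descriptors
#'
#' @param object A `qsrr_sensitivity` tibble from [ann_sensitivity()].
#' @param ... Unused.
#' @return A ggplot bar chart of mean absolute predicted-RT change.
#' @export
autoplot.qsrr_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$descriptor, .data$mean_abs_change),
    y = .data$mean_abs_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "Mean |change in predicted RT| (min)") +
    ggplot2::theme_minimal()
}

#' GA fitness-trace plot
#'
#' @param object A `qsrr_ga_run` object.
#' @param ... Unused.
#' @return A ggplot of the elitist best fitness per generation.
#' @export
autoplot.qsrr_ga_run <- function(object, ...) {
  df <- tibble(generation = seq_along(object$fitness_trace),
               fitness = object$fitness_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$fitness)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Generation", y = "Best penalized fitness") +
    ggplot2::theme_minimal()
}
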