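#' Plot per-sample Gini impurity curves
#'
#' One curve per annotation sample with its impurity-minimising
#' thresholds marked, plus the chosen conservative threshold as a
#' dashed line.
#'
#' @param object A `threshold_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_result
#' @export
autoplot.threshold_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$threshold, y = .data$impurity,
                               colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$minimizers, size = 2.5) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "similarity threshold", y = "weighted Gini impurity",
                  colour = "sample",
                  title = sprintf("Impurity minimisation (chosen threshold %.2f)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.threshold_result
#' @export
plot_gini_curves <- function(object, ...) autoplot.threshold_result(object, ...)

#' Plot a threshold sweep
#'
#' Percentage of concept occurrences matched as a function of the
#' similarity threshold, per direction, faceted by grouping; optionally
#' marks the chosen threshold.
#'
#' @param sweep Output of [threshold_sweep()].
#' @param threshold Optional chosen threshold to mark.
#' @return A ggplot.
#' @export
plot_threshold_sweep <- function(sweep, threshold = NULL) {
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(x = .data$threshold, y = .data$percentage,
                                    colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~grouping) +
    ggplot2::labs(x = "similarity threshold", y = "% of occurrences matched",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Plot an overlap report by domain
#'
#' Matched percentage per concept domain, direction and grouping.
#'
#' @param object An `overlap_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_report
#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$domain != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$percentage,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(population ~ grouping) +
    ggplot2::labs(x = NULL, y = "% of occurrences matched", fill = NULL,
                  title = sprintf("Overlap at similarity threshold %.2f",
                                  attr(object, "threshold"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.overlap_report
#' @export
plot_overlap <- function(object, ...) autoplot.overlap_report(object, ...)
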