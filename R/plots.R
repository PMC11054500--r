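#' Plot a walk trace
#'
#' Planar (east/north) view of the recorded positions, coloured by the
#' reported accuracy radius; optionally overlays the kept/removed decision of
#' the exclusion filters.
#'
#' @param object a `walk_trace`.
#' @param filter_report optional [apply_filters()] result for the same trace;
#'   removed samples are cross-marked.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.walk_trace <- function(object, filter_report = NULL, ...) {
  enu <- to_enu(object)
  df <- dplyr::bind_cols(enu, tibble(acc = object$acc))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$acc), size = 1.2) +
    ggplot2::scale_colour_viridis_c(name = "accuracy [m]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "east [m]", y = "north [m]",
                  title = sprintf("%s (%s)", attr(object, "path_type"),
                                  attr(object, "label"))) +
    ggplot2::theme_minimal()
  if (!is.null(filter_report)) {
    rem <- df[filter_report$removed$index, ]
    p <- p + ggplot2::geom_point(data = rem, shape = 4, colour = "red", size = 2)
  }
  p
}

#' Plot per-path-type error distributions
#'
#' Box plot of absolute percentage error by path type and algorithm, the
#' standard view for comparing how path shape affects each estimator.
#'
#' @param errors tibble with columns `path_type`, `algorithm`, `ape`
#'   (absolute percentage error), e.g. from [evaluate_cohort()].
#' @return a ggplot object.
#' @export
plot_error_by_path <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = .data$path_type, y = .data$ape,
                                       fill = .data$algorithm)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "absolute error [%]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot pooled cross-validated classifier metrics
#'
#' @param report a `classifier_report` from [train_evaluate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.classifier_report <- function(report, ...) {
  long <- tidyr::pivot_longer(report$metrics, -"model",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
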