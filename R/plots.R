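#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_line geom_col
#'   geom_errorbar geom_abline scale_fill_gradient2 labs theme_minimal
#'   autoplot facet_wrap position_dodge
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-class metrics
#'
#' Bar chart of per-class precision, recall and F1 for a metrics report.
#'
#' @param object A `tcm_metrics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcm_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$label, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = NULL,
         title = sprintf("Per-class metrics (accuracy %.3f)",
                         object$accuracy)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot repeated-CV summaries
#'
#' Point-and-interval plot of the cross-validation mean and 95% CI per
#' metric.
#'
#' @param object A `tcm_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcm_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$metric, y = .data$mean)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.2) +
    labs(x = NULL, y = "score",
         title = sprintf("Repeated CV (%d scores per metric)",
                         df$n_scores[1])) +
    theme_minimal()
}

#' Plot an accuracy-scaling grid
#'
#' Heat map of test accuracy over per-class sample size and number of
#' pattern types.
#'
#' @param object A `tcm_scaling_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcm_scaling_grid <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$n_classes), y = factor(.data$per_class_n),
             fill = .data$accuracy)) +
    geom_tile() +
    scale_fill_gradient2(low = "#67001f", mid = "#f7f7f7", high = "#053061",
                         midpoint = 0.7, limits = c(0, 1)) +
    labs(x = "number of syndrome pattern types",
         y = "per-class sample size", fill = "accuracy") +
    theme_minimal()
}

#' Plot a sample-size planning fit
#'
#' Crossing points with the fitted line; censored class counts are omitted.
#'
#' @param object A `tcm_scaling_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcm_scaling_fit <- function(object, ...) {
  used <- dplyr::filter(object$crossings, !.data$censored)
  ggplot(used, aes(x = .data$n_classes, y = .data$per_class_n)) +
    geom_point(size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "#b2182b") +
    labs(x = "number of syndrome pattern types",
         y = sprintf("minimal per-class size for accuracy %.2f",
                     object$threshold),
         title = sprintf("Y = %.2f X + %.2f (p = %.2g)", object$slope,
                         object$intercept, object$p_value)) +
    theme_minimal()
}
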