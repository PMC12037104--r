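# ggplot2 views of streams, detections and before/after comparisons.

#' Plot an error stream with its detections
#'
#' Shows the running error rate of an ordered misclassification stream,
#' with optional warning/drift markers.
#'
#' @param object An `"error_stream"`.
#' @param events Optional `"drift_events"` for the same stream.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.error_stream <- function(object, events = NULL, ...) {
  df <- as_tibble(unclass(object))
  df$running_rate <- cumsum(df$error) / df$position
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$running_rate)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = sprintf("stream position (ordered by %s)",
                              attr(object, "ordering_key")),
                  y = "running error rate") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- as_tibble(unclass(events))
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$position, colour = .data$level,
                   linetype = .data$detector)) +
      ggplot2::scale_colour_manual(values = c(warning = "orange",
                                              drift = "red3"))
  }
  p
}

#' Plot a covariate track with drift events
#'
#' The covariate (a clinical variable or a metabolite used as one) is drawn
#' along the stream order as a grey-scale strip, with warning/drift
#' positions highlighted - the visual used to inspect a nominated
#' confounding factor.
#'
#' @param stream An `"error_stream"`.
#' @param clinical Clinical tibble (may include metabolite columns).
#' @param covariate Column to display.
#' @param events Optional `"drift_events"`.
#' @return A ggplot object.
#' @export
plot_covariate_track <- function(stream, clinical, covariate, events = NULL) {
  df <- as_tibble(unclass(stream))
  df$value <- clinical[[covariate]][match(df$sample_id, clinical$sample_id)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = 1,
                                        fill = .data$value)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "grey10",
                                 name = covariate) +
    ggplot2::labs(x = "stream position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(events) && nrow(events)) {
    ev <- as_tibble(unclass(events))
    p <- p + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$position,
                              colour = .data$level)) +
      ggplot2::scale_colour_manual(values = c(warning = "orange",
                                              drift = "red3"))
  }
  p
}

#' Plot a before/after comparison report
#'
#' Paired classifier accuracies before and after confounder correction,
#' per scaling method and classifier family.
#'
#' @param object A `"comparison_report"` from [compare_before_after()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("accuracy_before", "accuracy_after"),
                        names_to = "stage", values_to = "accuracy",
                        names_prefix = "accuracy_")
  long$stage <- factor(long$stage, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$accuracy,
                                     group = .data$scaling)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$scaling)) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = NULL, y = "test accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
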