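#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-participant classification accuracy
#'
#' Bar chart of the participant-wise accuracy of an [participant_accuracy()]
#' report, with the unweighted mean as a reference line.
#'
#' @param object an `accuracy_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- object$by_participant
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$subject), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "participant", y = "accuracy (%)",
      title = sprintf("Participant-wise accuracy (mean %.1f%%)", object$mean_accuracy)
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot an aggregated relevance pattern as a channel-by-time heat map
#'
#' The 1200-vector is reshaped to 12 channels x 100 stance samples. With
#' `top_k` set, only the `top_k` most relevant variables are shown (the rest
#' are blanked), reproducing the reduced-relevance view.
#'
#' @param object an `aggregated_relevance`.
#' @param top_k optional number of top-relevance variables to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot aggregated_relevance
#' @export
autoplot.aggregated_relevance <- function(object, top_k = NULL, ...) {
  df <- dplyr::mutate(feature_info(seq_along(object$values)), relevance = object$values)
  if (!is.null(top_k)) {
    keep <- rank_variables(object)[seq_len(top_k)]
    df$relevance[!df$index %in% keep] <- NA_real_
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample,
    y = factor(.data$channel, levels = rev(gait_channels())),
    fill = .data$relevance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "grey95", high = "grey10",
      na.value = "white", limits = c(0, 1), name = "relevance"
    ) +
    ggplot2::labs(
      x = "stance phase (%)", y = NULL,
      title = if (is.null(top_k)) {
        "Aggregated absolute relevance"
      } else {
        sprintf("Top %d relevance variables", top_k)
      }
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aggregated_relevance
#' @param agg an `aggregated_relevance`.
#' @export
plot_relevance_map <- function(agg, top_k = NULL) autoplot(agg, top_k = top_k)

#' Plot the accuracy-versus-variables ablation curve
#'
#' @param object an `accuracy_curve` from [ablation_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "number of retained variables",
      y = "mean accuracy (%)",
      title = "Classification accuracy vs. retained top-relevance variables"
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
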