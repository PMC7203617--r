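#' Histogram of distraction ratios by group
#'
#' Log-scale histogram of per-stimulus distraction ratios, ASD versus NC.
#' Zero ratios cannot be shown on a log axis; they are collapsed into the
#' leftmost bin at `zero_at`.
#'
#' @param records Ratio tibble from [distraction_ratios()] joined with a
#'   `group` column.
#' @param value Which ratio to plot: `"d"` (default) or `"d_flr"`.
#' @param bins Number of histogram bins.
#' @param zero_at Plotting position of zero ratios.
#' @return A ggplot object.
#' @export
plot_distraction_hist <- function(records, value = c("d", "d_flr"),
                                  bins = 30, zero_at = 1e-4) {
  value <- match.arg(value)
  v <- records[[value]]
  df <- tibble::tibble(value = pmax(v, zero_at), group = records$group)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(ASD = "#c0392b", NC = "#2980b9")) +
    ggplot2::labs(x = sprintf("distraction ratio (%s, log scale)", value),
                  y = "stimulus windows", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `lopo_eval`.
#' @param ... Unused.
#' @return A ggplot tile plot of the 2x2 LOPO confusion matrix.
#' @export
autoplot.lopo_eval <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "pred", "n")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white",
                       size = 6) +
    ggplot2::scale_y_discrete(limits = rev(c("ASD", "NC"))) +
    ggplot2::labs(
      x = "predicted", y = "true",
      title = sprintf("LOPO accuracy %.2f", object$accuracy)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a shuffle-test null distribution
#'
#' Histogram of null accuracies with the observed accuracy marked.
#'
#' @param object A `shuffle_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shuffle_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 25, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed$accuracy,
                        color = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      x = "null accuracy (label shuffles)", y = "count",
      title = sprintf("observed %.3f, p = %.3f (B = %d)",
                      object$observed$accuracy, object$p, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
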