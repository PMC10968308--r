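#' Plot an ECG signal, optionally shading rejected windows
#'
#' @param object An [ecg_signal()].
#' @param verdicts Optional window-verdict tibble from [classify_signal()];
#'   unacceptable windows are shaded and coloured by triggering rule.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_signal <- function(object, verdicts = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(verdicts)) {
    wlen <- if (nrow(verdicts) > 1) verdicts$start_s[2] - verdicts$start_s[1] else 2
    bad <- dplyr::filter(verdicts, .data$label == "unacceptable")
    if (nrow(bad) > 0) {
      p <- p + ggplot2::geom_rect(
        data = bad,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$start_s + wlen,
                     ymin = -Inf, ymax = Inf, fill = .data$reason),
        alpha = 0.25, inherit.aes = FALSE
      ) + ggplot2::labs(fill = "rejection rule")
    }
  }
  p
}

#' Plot a label series as a quality timeline
#'
#' @param object A [label_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_series <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = 0, ymax = 1, fill = .data$label)
    ) +
    ggplot2::scale_fill_manual(
      values = c(acceptable = "#2b8cbe", unacceptable = "#e34a33")
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
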