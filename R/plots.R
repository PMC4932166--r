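#' Plot a synthetic session
#'
#' Facetted trace plot of the six channels with the scheduled events shaded.
#'
#' @param object A `synth_session` from [synthesize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synth_session <- function(object, ...) {
  long <- tidyr::pivot_longer(object$recording, -"t",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = recording_channels)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if (nrow(object$truth) > 0) {
    shade <- object$truth
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$onset, xmax = .data$onset + .data$duration),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a recognition summary
#'
#' Stacked per-pattern outcome rates.
#'
#' @param object A `recognition_summary` from [summarize_recognition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recognition_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_pattern[c("pattern", "correct_rate", "reject_rate", "miss_rate")],
    -"pattern", names_to = "outcome", values_to = "rate"
  )
  long$outcome <- factor(sub("_rate$", "", long$outcome),
                         levels = c("miss", "reject", "correct"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pattern, y = .data$rate,
                                     fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "rate (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
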