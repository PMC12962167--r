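#' Plot a heartbeat-probability map
#'
#' @param object An [hbp_map()].
#' @param peaks Optional [peak_seq()] to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbp_map <- function(object, peaks = NULL, ...) {
  fps <- attr(object, "fps") %||% 1
  df <- tibble(time_s = object$frame_index / fps, probability = object$probability)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$probability)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "heartbeat probability") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks$index / fps,
                                 linetype = 3, colour = "grey60")
  }
  p
}

#' Plot a pulse trace
#'
#' @param object A [pulse_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pulse_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "#d7301f") +
    ggplot2::labs(x = "time (s)", y = sprintf("amplitude (%s)", attr(object, "units"))) +
    ggplot2::theme_minimal()
}
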