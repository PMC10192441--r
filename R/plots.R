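# ggplot2 helpers for traces, diagnostics and transcripts.

#' Plot an EAR trace with detected blink events
#'
#' @param trace Tibble with `frame` and `ear_mean` (e.g. from
#'   [make_ear_trace()] or pipeline diagnostics).
#' @param events Optional blink-event tibble from [detect_blinks()]; events
#'   are shaded, intentional ones darker.
#' @param cfg A [blink_config()]; its threshold is drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_ear_trace <- function(trace, events = NULL, cfg = blink_config()) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$frame, y = .data$ear_mean)) +
    ggplot2::geom_hline(yintercept = cfg$threshold_t, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frame", y = "eye aspect ratio",
                  title = "EAR trace (dashed: open/closed threshold)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame,
                   ymin = -Inf, ymax = Inf, alpha = .data$kind),
      fill = "firebrick") +
      ggplot2::scale_alpha_manual(values = c(NATURAL = 0.15, INTENTIONAL = 0.35),
                                  name = "blink")
  }
  p
}

#' Plot the per-frame gaze path and state sequence
#'
#' @param diagnostics Per-frame tibble from [classify_frames()] /
#'   [run_pipeline()].
#' @return A ggplot object: normalised pupil coordinates over time, coloured
#'   by the classified frame state.
#' @export
plot_gaze_path <- function(diagnostics) {
  d <- tidyr_longer(diagnostics)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$value,
                                  colour = .data$state)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~ .data$coord, ncol = 1) +
    ggplot2::labs(x = "frame", y = "normalised pupil position",
                  title = "Pupil position within the eye box") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_longer <- function(diagnostics) {
  bind_rows(
    tibble(frame = diagnostics$frame, value = diagnostics$gx,
           state = diagnostics$state, coord = "gx"),
    tibble(frame = diagnostics$frame, value = diagnostics$gy,
           state = diagnostics$state, coord = "gy"))
}

#' Plot a pipeline result: EAR trace, states and emitted phrases
#' @param object An `eyespeak_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eyespeak_result
#' @export
autoplot.eyespeak_result <- function(object, ...) {
  p <- plot_ear_trace(object$diagnostics, object$blinks)
  if (nrow(object$transcript) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$transcript$end_frame,
                                 colour = "darkgreen", linetype = "dotted") +
      ggplot2::annotate("text", x = object$transcript$end_frame,
                        y = max(object$diagnostics$ear_mean, na.rm = TRUE),
                        label = object$transcript$phrase, angle = 90,
                        vjust = -0.4, hjust = 1, size = 3)
  }
  p
}
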