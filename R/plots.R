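# ggplot2 autoplot() methods for the main result types.

#' Plot a proximity graph over its embedded points
#'
#' @param object A `trial_graph`.
#' @param hubs Optional [select_hubs()] result to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trial_graph <- function(object, hubs = NULL, ...) {
  pts <- tibble::tibble(x = object$points[, 1L], y = object$points[, 2L],
                        node = seq_len(object$n))
  ed <- tidy.trial_graph(object)
  seg <- dplyr::mutate(ed,
                       x = pts$x[.data$from], y = pts$y[.data$from],
                       xend = pts$x[.data$to], yend = pts$y[.data$to])
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "darkgreen", linewidth = 0.3, alpha = 0.7) +
    ggplot2::geom_point(size = 1.5, color = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (%d nodes, %d edges)", object$kind,
                                  object$n, nrow(object$edges)),
                  x = "MDS axis 1", y = "MDS axis 2") +
    ggplot2::theme_minimal()
  if (!is.null(hubs)) {
    map <- object$collapsed_map
    nodes <- if (is.null(map)) hubs$selected else unique(map[hubs$selected])
    p <- p + ggplot2::geom_point(data = pts[nodes, ], shape = 21,
                                 size = 3, color = "red", stroke = 0.8)
  }
  p
}

#' Plot an evoked estimate waveform
#'
#' @param object An `evoked_estimate` (from [grand_average()] or a
#'   baseline miner).
#' @param reference Optional second `evoked_estimate` (e.g. the
#'   all-trial average) drawn for comparison.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evoked_estimate <- function(object, reference = NULL, ...) {
  df <- tibble::tibble(time = object$times, value = object$waveform,
                       which = "selected")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      time = reference$times, value = reference$waveform,
      which = "reference"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(selected = "black", reference = "steelblue")) +
    ggplot2::labs(x = "time from onset (s)", y = "amplitude",
                  color = NULL,
                  title = sprintf("Evoked estimate (%d trial%s)",
                                  object$n_selected,
                                  if (object$n_selected == 1) "" else "s")) +
    ggplot2::theme_minimal()
}

#' Plot a mining result: embedding, graph, hubs and waveforms
#'
#' @param object An [mine_trials()] result.
#' @param ... Unused.
#' @return A ggplot of the hub-annotated embedding.
#' @export
autoplot.st_mining <- function(object, ...) {
  g <- gabriel_graph(object$points)
  autoplot.trial_graph(g, hubs = object$selection) +
    ggplot2::labs(title = sprintf(
      "Gabriel graph: %d/%d hubs at k = %d (SNR %.2f vs %.2f all-trial)",
      length(object$selection$selected), nrow(object$points),
      object$config$degree_k, object$snr, object$snr_all))
}

#' Plot a trial-subsampling reliability curve
#'
#' @param curve A [subsampling_curve()] tibble.
#' @return A ggplot with one panel per tracked quantity.
#' @export
plot_subsampling <- function(curve) {
  long <- tidyr::pivot_longer(
    curve, c("amplitude", "latency", "snr"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "fraction of trials (acquisition order)", y = NULL) +
    ggplot2::theme_minimal()
}
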