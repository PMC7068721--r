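#' Plot an ERP waveform
#'
#' Line plot of one waveform with optional shading of an analysis window.
#'
#' @param object An `erp_waveform`.
#' @param window Optional one-row window tibble or `c(start, end)` ms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erp_waveform <- function(object, window = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = expression("Amplitude (" * mu * "V)"),
      title = attr(object, "condition"),
      subtitle = sprintf(
        "%s, n = %s epochs", attr(object, "channel"),
        format(attr(object, "n_epochs"))
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    w <- resolve_window(window)
    p <- p + ggplot2::annotate("rect",
      xmin = w$start, xmax = w$end,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Overlay the three condition averages of a session
#'
#' @param es An `erp_epochs` object.
#' @param channel Channel, default `"Fz"`.
#' @param window Optional window to shade.
#' @return A ggplot object.
#' @export
plot_condition_waveforms <- function(es, channel = "Fz", window = NULL) {
  d <- purrr::map_dfr(CONDITIONS, function(cc) {
    wf <- condition_average(es, cc, channel)
    mutate(as_tibble(wf), condition = cc)
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time_ms, y = .data$amplitude_uv, colour = .data$condition
  )) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = expression("Amplitude (" * mu * "V)"),
      colour = "Condition"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    w <- resolve_window(window)
    p <- p + ggplot2::annotate("rect",
      xmin = w$start, xmax = w$end,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Plot leave-one-out latencies of a jackknife test
#'
#' @param object A `jackknife_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jackknife_result <- function(object, ...) {
  ggplot2::ggplot(object$latencies, ggplot2::aes(
    x = .data$cell, y = .data$latency_ms
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(
      x = NULL, y = "Leave-one-out peak latency (ms)",
      subtitle = sprintf(
        "%s = %.3f (corrected), p = %.3g, n = %d",
        object$statistic_type, object$corrected_statistic,
        object$p_value, object$n_subjects
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scatter the delta-P3 marker against the outcome score per cohort
#'
#' @param markers Marker table with `delta_uv`, `outcome`, `cohort`.
#' @return A ggplot object with per-cohort least-squares lines.
#' @export
plot_marker_association <- function(markers) {
  ggplot2::ggplot(markers, ggplot2::aes(
    x = .data$delta_uv, y = .data$outcome, colour = .data$cohort
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = expression(Delta * "P3 (" * mu * "V)"),
      y = "Outcome composite score", colour = "Cohort"
    ) +
    ggplot2::theme_minimal()
}
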