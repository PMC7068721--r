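#' Age-specific component window registry
#'
#' Analysis windows for mean amplitude and peak latency per component and age
#' point. At 1 month the morphology is a unitary early negativity (N1)
#' followed by P3 and Nc; by 5 months the N1 is replaced by a P1/N2 complex
#' and the late components peak earlier:
#'
#' | age | N1 | P1 | N2 | P3 | Nc |
#' |-----|----|----|----|----|----|
#' | 1m  | 50–150 | — | — | 250–450 | 550–750 |
#' | 5m  | — | 60–80 | 90–110 | 200–400 | 500–700 |
#'
#' @param age_point Optional `"1m"` or `"5m"` to filter the registry.
#' @return Tibble with `component`, `age_point`, `t_start_ms`, `t_end_ms`,
#'   `polarity`.
#' @examples
#' component_windows("1m")
#' @export
component_windows <- function(age_point = NULL) {
  reg <- tibble(
    component = c("N1", "P3", "Nc", "P1", "N2", "P3", "Nc"),
    age_point = c("1m", "1m", "1m", "5m", "5m", "5m", "5m"),
    t_start_ms = c(50, 250, 550, 60, 90, 200, 500),
    t_end_ms = c(150, 450, 750, 80, 110, 400, 700),
    polarity = c("-", "+", "-", "+", "-", "+", "-")
  )
  if (!is.null(age_point)) {
    age_point <- match.arg(age_point, c("1m", "5m"))
    reg <- filter(reg, .data$age_point == !!age_point)
  }
  reg
}

#' Look up one component's analysis window
#'
#' @param component Component name.
#' @param age_point `"1m"` or `"5m"`.
#' @return One-row tibble from [component_windows()]. Requesting a component
#'   undefined at an age point (e.g. N1 at 5 months) is a registry error.
#' @examples
#' get_window("P3", "1m")
#' @export
get_window <- function(component, age_point) {
  w <- filter(
    component_windows(),
    .data$component == !!component, .data$age_point == !!age_point
  )
  if (nrow(w) != 1) {
    abort(sprintf("Component %s is not defined at age point %s.", component, age_point),
      class = "oddballerp_registry_error"
    )
  }
  w
}

#' Average kept epochs of one condition into a waveform
#'
#' Pointwise mean over valid, kept (post-equalization) epochs of the given
#' condition at one channel (Fz by default, the analysis electrode for the
#' frontal novelty response).
#'
#' @param es An `erp_epochs` object.
#' @param condition Condition label.
#' @param channel Channel name, default `"Fz"`.
#' @return An `erp_waveform`: tibble with `time_ms`, `amplitude_uv`;
#'   attributes `n_epochs`, `condition`, `channel`.
#' @export
condition_average <- function(es, condition, channel = "Fz") {
  stopifnot(inherits(es, "erp_epochs"))
  ch <- match(channel, es$channel_names)
  if (is.na(ch)) abort(sprintf("Unknown channel %s.", channel))
  sel <- which(es$info$valid & es$info$kept & es$info$condition == condition)
  if (length(sel) == 0) {
    abort(sprintf("No kept epochs for condition %s.", condition),
      class = "oddballerp_empty_error"
    )
  }
  amp <- colMeans(matrix(es$data[sel, ch, , drop = FALSE], nrow = length(sel)))
  new_waveform(es$time_ms, amp,
    n_epochs = length(sel),
    condition = condition, channel = channel
  )
}

new_waveform <- function(time_ms, amplitude_uv, n_epochs = NA_integer_,
                         condition = NA_character_, channel = "Fz") {
  out <- tibble(time_ms = time_ms, amplitude_uv = amplitude_uv)
  attr(out, "n_epochs") <- n_epochs
  attr(out, "condition") <- condition
  attr(out, "channel") <- channel
  class(out) <- c("erp_waveform", class(out))
  out
}

resolve_window <- function(window, component = NULL, age_point = NULL) {
  if (is.null(window)) window <- get_window(component, age_point)
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    return(list(
      start = window$t_start_ms, end = window$t_end_ms,
      polarity = window$polarity %||% "+"
    ))
  }
  list(start = window[[1]], end = window[[2]], polarity = "+")
}

#' Window mean amplitude of a waveform
#'
#' Arithmetic mean of the samples with `t_start <= t <= t_end` (inclusive
#' endpoints on the sampling grid).
#'
#' @param waveform An `erp_waveform` (or tibble with `time_ms`,
#'   `amplitude_uv`).
#' @param window One-row window tibble (e.g. from [get_window()]) or a
#'   length-2 numeric `c(start, end)` in ms.
#' @param component,age_point Alternative to `window`: look the window up in
#'   the registry.
#' @return Mean amplitude in microvolts.
#' @examples
#' w <- tibble::tibble(time_ms = seq(-200, 800, 2), amplitude_uv = 5)
#' mean_amplitude(w, c(250, 450))
#' @export
mean_amplitude <- function(waveform, window = NULL, component = NULL, age_point = NULL) {
  w <- resolve_window(window, component, age_point)
  tol <- 1e-9
  sel <- waveform$time_ms >= w$start - tol & waveform$time_ms <= w$end + tol
  if (!any(sel)) {
    abort("Window lies outside the epoch time axis.", class = "oddballerp_window_error")
  }
  if (w$start < min(waveform$time_ms) - tol || w$end > max(waveform$time_ms) + tol) {
    abort("Window extends beyond the epoch time axis.", class = "oddballerp_window_error")
  }
  mean(waveform$amplitude_uv[sel])
}

#' Peak latency within a window
#'
#' Latency of the maximum (positive components) or minimum (negative
#' components) sample inside the window; ties are broken by the earliest
#' sample.
#'
#' @inheritParams mean_amplitude
#' @param polarity `"+"` or `"-"`; overrides the window's polarity.
#' @return Latency in ms. Attribute `"on_boundary"` flags a peak on the
#'   window edge.
#' @export
peak_latency <- function(waveform, window = NULL, component = NULL,
                         age_point = NULL, polarity = NULL) {
  w <- resolve_window(window, component, age_point)
  pol <- polarity %||% w$polarity
  tol <- 1e-9
  sel <- which(waveform$time_ms >= w$start - tol & waveform$time_ms <= w$end + tol)
  if (length(sel) == 0) {
    abort("Window lies outside the epoch time axis.", class = "oddballerp_window_error")
  }
  amp <- waveform$amplitude_uv[sel]
  i <- if (pol == "-") which.min(amp) else which.max(amp)
  lat <- waveform$time_ms[sel[i]]
  attr(lat, "on_boundary") <- i == 1L || i == length(sel)
  lat
}

#' Measure all components for one subject session
#'
#' Computes, per condition, the condition average at Fz and every registry
#' component's window mean amplitude and (diagnostic, subject-level) peak
#' latency for the session's age point.
#'
#' @param es An `erp_epochs` object (preprocessed and equalized).
#' @param age_point `"1m"` or `"5m"`.
#' @param subject_id Optional identifier carried into the output.
#' @param channel Analysis channel, default `"Fz"`.
#' @return Tidy tibble: `subject_id`, `age_point`, `condition`, `component`,
#'   `mean_amp_uv`, `peak_latency_ms`, `n_epochs`.
#' @export
measure_components <- function(es, age_point, subject_id = NA_character_, channel = "Fz") {
  reg <- component_windows(age_point)
  purrr::map_dfr(CONDITIONS, function(cc) {
    wf <- condition_average(es, cc, channel)
    purrr::map_dfr(seq_len(nrow(reg)), function(i) {
      w <- reg[i, ]
      tibble(
        subject_id = subject_id, age_point = age_point, condition = cc,
        component = w$component,
        mean_amp_uv = mean_amplitude(wf, w),
        peak_latency_ms = as.numeric(peak_latency(wf, w)),
        n_epochs = attr(wf, "n_epochs")
      )
    })
  })
}

#' Jackknife leave-one-out latency test
#'
#' Implements the leave-one-out grand-average approach to ERP latency
#' inference: for each cell of the within-subject design, n grand averages of
#' size n-1 are formed (omitting one subject at a time) and the peak latency
#' of each is measured. The requested contrast is then run on these
#' leave-one-out latencies, and the test statistic is deflated to undo the
#' artificial reduction of error variance that averaging induces:
#' `t_corrected = t / (n - 1)` for a two-level (paired t) contrast and
#' `F_corrected = F / (n - 1)^2` for a repeated-measures F, with p-values
#' computed from the corrected statistic.
#'
#' @param data Long tibble with columns `subject`, `cell` (factor; the
#'   within-subject design cell, e.g. condition or age), `time_ms`,
#'   `amplitude_uv` — one waveform per subject and cell on a shared time
#'   grid.
#' @param window One-row window tibble or `c(start, end)` ms.
#' @param polarity `"+"` or `"-"`.
#' @param correct Report corrected statistics (default) or raw.
#' @return A `jackknife_result` with the leave-one-out latencies, raw and
#'   corrected statistic, degrees of freedom, p-value and boundary flags.
#'   `tidy()` and `glance()` methods are provided.
#' @export
jackknife_latency_test <- function(data, window, polarity = "+", correct = TRUE) {
  stopifnot(all(c("subject", "cell", "time_ms", "amplitude_uv") %in% names(data)))
  data$cell <- factor(data$cell)
  data$subject <- factor(data$subject)
  subjects <- levels(data$subject)
  cells <- levels(data$cell)
  n <- length(subjects)
  if (n < 3) {
    abort("Jackknife latency inference needs at least 3 subjects.",
      class = "oddballerp_config_error"
    )
  }
  tgrid <- sort(unique(data$time_ms))
  # waveform cube: subject x cell x time
  cube <- array(NA_real_, c(n, length(cells), length(tgrid)))
  for (i in seq_len(n)) {
    for (j in seq_along(cells)) {
      d <- data[data$subject == subjects[i] & data$cell == cells[j], ]
      if (nrow(d) != length(tgrid)) {
        abort(sprintf(
          "Subject %s is missing cell %s (or is off the shared time grid).",
          subjects[i], cells[j]
        ), class = "oddballerp_config_error")
      }
      cube[i, j, ] <- d$amplitude_uv[order(d$time_ms)]
    }
  }
  boundary <- FALSE
  loo <- purrr::map_dfr(seq_len(n), function(i) {
    purrr::map_dfr(seq_along(cells), function(j) {
      ga <- colMeans(cube[-i, j, , drop = FALSE][, 1, , drop = TRUE], na.rm = FALSE)
      if (n == 2) ga <- cube[-i, j, ] # degenerate, guarded above
      lat <- peak_latency(new_waveform(tgrid, ga), window, polarity = polarity)
      boundary <<- boundary || attr(lat, "on_boundary")
      tibble(
        left_out = subjects[i], cell = cells[j],
        latency_ms = as.numeric(lat)
      )
    })
  })
  if (length(cells) == 2) {
    wide <- tidyr::pivot_wider(loo, names_from = "cell", values_from = "latency_ms")
    d <- wide[[cells[2]]] - wide[[cells[1]]]
    sd_d <- sd(d)
    raw <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
    corrected <- raw / (n - 1)
    stat_type <- "t"
    df1 <- NA_real_
    df2 <- n - 1
    p <- 2 * pt(-abs(if (correct) corrected else raw), df = df2)
  } else {
    an <- rm_anova(
      rename(loo, subject_id = "left_out", latency = "latency_ms"),
      dv = "latency", within = "cell", subject = "subject_id"
    )
    eff <- an[an$effect == "cell", ]
    raw <- eff$statistic
    corrected <- raw / (n - 1)^2
    stat_type <- "F"
    df1 <- eff$df1
    df2 <- eff$df2
    p <- pf(if (correct) corrected else raw, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(
      latencies = loo, statistic_type = stat_type,
      raw_statistic = raw, corrected_statistic = corrected,
      statistic = if (correct) corrected else raw,
      correction = if (correct) "jackknife" else "none",
      df1 = df1, df2 = df2, p_value = p, n_subjects = n,
      peak_on_boundary = boundary
    ),
    class = "jackknife_result"
  )
}

#' @export
print.jackknife_result <- function(x, ...) {
  lbl <- if (x$statistic_type == "t") {
    sprintf("t(%d) = %.3f", x$df2, x$statistic)
  } else {
    sprintf("F(%d, %d) = %.3f", x$df1, x$df2, x$statistic)
  }
  cat(sprintf(
    "<jackknife_result> %s (%s), p = %.4g, n = %d%s\n",
    lbl, x$correction, x$p_value, x$n_subjects,
    if (x$peak_on_boundary) " [peak on window boundary]" else ""
  ))
  invisible(x)
}

#' @export
tidy.jackknife_result <- function(x, ...) {
  tibble(
    term = "cell", statistic_type = x$statistic_type,
    raw_statistic = x$raw_statistic, statistic = x$statistic,
    df1 = x$df1, df2 = x$df2, p_value = x$p_value,
    correction = x$correction
  )
}

#' @export
glance.jackknife_result <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    statistic = x$statistic, p_value = x$p_value,
    peak_on_boundary = x$peak_on_boundary
  )
}
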