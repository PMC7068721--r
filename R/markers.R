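#' Within-session habituation difference score
#'
#' Splits the kept epochs of one condition into a first and a second half by
#' original presentation order (odd counts assign the middle epoch to the
#' first half), averages each half, and subtracts the second half's window
#' mean amplitude from the first half's. Positive scores indicate a response
#' decrement over the session (habituation); scores near zero indicate no
#' amplitude change.
#'
#' @param es An `erp_epochs` object (preprocessed; the split uses kept
#'   epochs, i.e. after equalization by default).
#' @param condition Condition label.
#' @param window One-row window tibble or `c(start, end)` ms (typically the
#'   age-appropriate P3 window).
#' @param channel Analysis channel, default `"Fz"`.
#' @return One-row tibble: `condition`, `n_first`, `n_second`,
#'   `first_half_mean_uv`, `second_half_mean_uv`, `score_uv`, `defined`.
#'   With fewer than 2 kept epochs the score is undefined (`NA`, flagged).
#' @export
habituation_score <- function(es, condition, window, channel = "Fz") {
  stopifnot(inherits(es, "erp_epochs"))
  ch <- match(channel, es$channel_names)
  sel <- which(es$info$valid & es$info$kept & es$info$condition == condition)
  sel <- sel[order(es$info$ordinal[sel])]
  m <- length(sel)
  if (m < 2) {
    warn(sprintf("Condition %s has %d kept epoch(s); habituation score undefined.", condition, m))
    return(tibble(
      condition = condition, n_first = m, n_second = 0L,
      first_half_mean_uv = NA_real_, second_half_mean_uv = NA_real_,
      score_uv = NA_real_, defined = FALSE
    ))
  }
  n_first <- ceiling(m / 2)
  half_mean <- function(idx) {
    x <- es$data[idx, ch, , drop = FALSE]
    amp <- colMeans(matrix(x, nrow = length(idx)))
    mean_amplitude(new_waveform(es$time_ms, amp), window)
  }
  first <- half_mean(sel[seq_len(n_first)])
  second <- half_mean(sel[(n_first + 1):m])
  tibble(
    condition = condition, n_first = n_first, n_second = m - n_first,
    first_half_mean_uv = first, second_half_mean_uv = second,
    score_uv = first - second, defined = TRUE
  )
}

#' Habituation scores for all conditions of a session
#'
#' @inheritParams habituation_score
#' @param age_point Age point used to look up the P3 window when `window` is
#'   not given.
#' @param subject_id Optional identifier carried into the output.
#' @return Tibble with one row per condition (see [habituation_score()]).
#' @export
habituation_scores <- function(es, window = NULL, age_point = NULL,
                               subject_id = NA_character_, channel = "Fz") {
  if (is.null(window)) window <- get_window("P3", age_point)
  out <- purrr::map_dfr(CONDITIONS, function(cc) {
    habituation_score(es, cc, window, channel)
  })
  mutate(out, subject_id = subject_id, .before = 1)
}

#' Developmental delta-P3 change score
#'
#' The delta-P3 marker quantifies the developmental shift from an
#' intensity-driven to a novelty-driven P3: the Infrequent minus Trial Unique
#' P3 mean-amplitude contrast at 5 months is subtracted from the same
#' contrast at 1 month. A positive delta-P3 indexes a shift toward novelty
#' responding between the age points. Defined only for subjects with valid P3
#' measures for both conditions at both ages; incomplete subjects are
#' excluded with a reason.
#'
#' @param measures Tidy measures table (e.g. rows of [measure_components()]
#'   bound over subjects/sessions) with columns `subject_id`, `age_point`,
#'   `condition`, `component`, `mean_amp_uv`.
#' @return Tibble with `subject_id`, `contrast_1m_uv`, `contrast_5m_uv`,
#'   `delta_uv`. Excluded subjects are recorded in attribute `"excluded"`.
#' @examples
#' m <- tidyr::expand_grid(
#'   subject_id = "s1", age_point = c("1m", "5m"),
#'   condition = c("Infrequent", "TrialUnique"), component = "P3"
#' )
#' m$mean_amp_uv <- c(9, 5, 5, 9)
#' delta_p3(m)
#' @export
delta_p3 <- function(measures) {
  p3 <- measures %>%
    filter(.data$component == "P3", .data$condition %in% c("Infrequent", "TrialUnique")) %>%
    select("subject_id", "age_point", "condition", "mean_amp_uv") %>%
    tidyr::pivot_wider(names_from = c("condition", "age_point"), values_from = "mean_amp_uv")
  needed <- c("Infrequent_1m", "TrialUnique_1m", "Infrequent_5m", "TrialUnique_5m")
  for (col in setdiff(needed, names(p3))) p3[[col]] <- NA_real_
  complete <- stats::complete.cases(p3[needed])
  excluded <- tibble(
    subject_id = p3$subject_id[!complete],
    reason = vapply(which(!complete), function(i) {
      missing <- needed[is.na(unlist(p3[i, needed]))]
      paste("missing", paste(missing, collapse = ", "))
    }, character(1))
  )
  out <- p3[complete, ] %>%
    mutate(
      contrast_1m_uv = .data$Infrequent_1m - .data$TrialUnique_1m,
      contrast_5m_uv = .data$Infrequent_5m - .data$TrialUnique_5m,
      delta_uv = .data$contrast_1m_uv - .data$contrast_5m_uv
    ) %>%
    select("subject_id", "contrast_1m_uv", "contrast_5m_uv", "delta_uv")
  attr(out, "excluded") <- excluded
  out
}

#' Expected measured P3 quantities implied by a template
#'
#' Closed-form ground truth for recovery tests: the expected window mean of a
#' Gaussian component template, including the session-average habituation
#' decay. The inclusive-endpoint sample mean on a regular grid equals, to
#' high accuracy, the midpoint-rule Gaussian integral over
#' `[t_start - dt/2, t_end + dt/2]` divided by the widened window length.
#'
#' @param template A [component_template()].
#' @param window One-row window tibble or `c(start, end)` ms.
#' @param condition Condition label.
#' @param n_trials Number of presentations over which the decay is averaged
#'   (`k = 0 .. n_trials - 1`); 1 gives the undecayed first-trial value.
#' @param sample_rate_hz Sampling grid, Hz.
#' @return Expected window mean amplitude in microvolts.
#' @export
template_window_mean <- function(template, window, condition,
                                 n_trials = 1, sample_rate_hz = 500) {
  w <- resolve_window(window)
  dt <- 1000 / sample_rate_hz
  a <- w$start - dt / 2
  b <- w$end + dt / 2
  mu <- template$peak_latency_ms
  s <- template$width_ms
  base <- template$amplitude_by_condition[[condition]] * s * sqrt(2 * pi) *
    (pnorm((b - mu) / s) - pnorm((a - mu) / s)) / (b - a)
  r <- template$habituation_rate[[condition]]
  decay <- if (r == 0 || n_trials == 1) {
    mean((1 - r)^(seq_len(n_trials) - 1))
  } else {
    (1 - (1 - r)^n_trials) / (n_trials * r)
  }
  base * decay
}

#' Expected window mean of a template under the measurement operator
#'
#' The preprocessing chain is linear and deterministic for the embedded
#' component: band-pass filtering, baseline subtraction and the window mean
#' commute with amplitude scaling. This helper pushes a unit-amplitude
#' Gaussian bump through the designed FIR filter (numerically, by
#' delay-compensated convolution with the actual kernel), subtracts the
#' pre-stimulus baseline if configured, and takes the window mean — giving
#' the exact noise-free expectation of what [measure_components()] reports
#' for that template, per microvolt of peak amplitude.
#'
#' @param template A [component_template()].
#' @param window One-row window tibble or `c(start, end)` ms.
#' @param condition Condition label.
#' @param n_trials Presentations over which the habituation decay is
#'   averaged.
#' @param cfg A [preprocess_config()]; its filter and baseline settings
#'   define the operator. `NULL` skips filtering (then this reduces to
#'   [template_window_mean()] with the configured baseline handling).
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Expected measured window mean amplitude in microvolts.
#' @export
measured_template_mean <- function(template, window, condition, n_trials = 1,
                                   cfg = preprocess_config(),
                                   sample_rate_hz = 500) {
  shape <- filtered_unit_shape(
    template$peak_latency_ms, template$width_ms,
    resolve_window(window), cfg, sample_rate_hz
  )
  r <- template$habituation_rate[[condition]]
  decay <- if (r == 0 || n_trials == 1) {
    1
  } else {
    (1 - (1 - r)^n_trials) / (n_trials * r)
  }
  template$amplitude_by_condition[[condition]] * shape * decay
}

# Window mean of a unit-amplitude Gaussian bump after FIR filtering and
# baseline correction; cached on (mu, sigma, window, filter, fs).
filtered_unit_shape <- function(mu, sigma, w, cfg, fs) {
  key <- paste(mu, sigma, w$start, w$end, fs,
    if (is.null(cfg)) "raw" else paste(cfg$hp_hz, cfg$lp_hz, cfg$filter_order,
      cfg$filter_window, cfg$baseline_correct),
    sep = "|"
  )
  cached <- shape_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  dt <- 1000 / fs
  if (is.null(cfg)) {
    grid <- seq(-500, 1000, by = dt)
    y <- exp(-(grid - mu)^2 / (2 * sigma^2))
    baseline_correct <- TRUE
  } else {
    h <- design_fir(cfg, fs)
    half_ms <- (length(h) %/% 2) * dt
    grid <- seq(-500 - half_ms, 1000 + half_ms, by = dt)
    g <- exp(-(grid - mu)^2 / (2 * sigma^2))
    delay <- cfg$filter_order %/% 2
    y_full <- fft_convolve(g, h)
    y <- y_full[delay + seq_along(grid)]
    baseline_correct <- cfg$baseline_correct
  }
  if (baseline_correct) {
    pre <- if (is.null(cfg)) 200 else cfg$epoch_pre_ms
    y <- y - mean(y[grid >= -pre - 1e-9 & grid <= 1e-9])
  }
  val <- mean(y[grid >= w$start - 1e-9 & grid <= w$end + 1e-9])
  shape_cache[[key]] <- val
  val
}

shape_cache <- new.env(parent = emptyenv())
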