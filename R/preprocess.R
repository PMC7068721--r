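#' Preprocessing configuration
#'
#' Parameters of the standard infant ERP preprocessing chain: a 0.5–30 Hz
#' zero-phase Blackman-windowed FIR band-pass (order 5500), a 32 ms stimulus
#' timing-offset correction, epoching from 200 ms before to 800 ms after
#' stimulus onset, peak-to-peak artifact rejection above 200 microvolts and
#' flatline rejection below 0.1 microvolts, trial-count equalization to the
#' smallest valid condition, and exclusion of datasets with fewer than 15
#' trials per condition.
#'
#' @param hp_hz,lp_hz Band-pass edges, Hz.
#' @param filter_order FIR order (number of taps minus one).
#' @param filter_window Window for the FIR design: `"blackman"`, `"hamming"`
#'   or `"hanning"`.
#' @param zero_phase If `TRUE` the group delay is fully compensated.
#' @param offset_ms Stimulus timing delay; markers are advanced this far
#'   toward the true acoustic onset (later in the recording).
#' @param epoch_pre_ms,epoch_post_ms Epoch window around onset, ms.
#' @param reject_ptp_uv Peak-to-peak rejection threshold, microvolts.
#' @param flatline_ptp_uv Flatline rejection threshold, microvolts.
#' @param min_trials_per_condition Inclusion threshold after equalization.
#' @param baseline_correct Subtract the mean of the pre-stimulus interval
#'   (epoch start to 0 ms) per channel.
#' @param reject_channels `"all"` (an epoch is rejected if any channel trips a
#'   threshold — the strictest reading) or `"Fz"` (only the analysis channel).
#' @param equalize_seed Seed for the equalization down-sampling.
#' @return An object of class `preprocess_config`.
#' @examples
#' preprocess_config()
#' @export
preprocess_config <- function(hp_hz = 0.5, lp_hz = 30,
                              filter_order = 5500,
                              filter_window = c("blackman", "hamming", "hanning"),
                              zero_phase = TRUE,
                              offset_ms = 32,
                              epoch_pre_ms = 200, epoch_post_ms = 800,
                              reject_ptp_uv = 200, flatline_ptp_uv = 0.1,
                              min_trials_per_condition = 15,
                              baseline_correct = TRUE,
                              reject_channels = c("all", "Fz"),
                              equalize_seed = 1L) {
  filter_window <- match.arg(filter_window)
  reject_channels <- match.arg(reject_channels)
  if (!(hp_hz < lp_hz)) abort("hp_hz must be below lp_hz.", class = "oddballerp_config_error")
  if (epoch_pre_ms < 0 || epoch_post_ms <= 0) {
    abort("Epoch window must span stimulus onset.", class = "oddballerp_config_error")
  }
  structure(
    list(
      hp_hz = hp_hz, lp_hz = lp_hz, filter_order = as.integer(filter_order),
      filter_window = filter_window, zero_phase = zero_phase,
      offset_ms = offset_ms,
      epoch_pre_ms = epoch_pre_ms, epoch_post_ms = epoch_post_ms,
      reject_ptp_uv = reject_ptp_uv, flatline_ptp_uv = flatline_ptp_uv,
      min_trials_per_condition = as.integer(min_trials_per_condition),
      baseline_correct = baseline_correct,
      reject_channels = reject_channels,
      equalize_seed = as.integer(equalize_seed)
    ),
    class = "preprocess_config"
  )
}

#' FIR band-pass kernel for a configuration
#'
#' Windowed-sinc band-pass design via [signal::fir1()].
#'
#' @param cfg A [preprocess_config()].
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Numeric vector of `filter_order + 1` taps.
#' @export
design_fir <- function(cfg, sample_rate_hz) {
  if (cfg$lp_hz >= sample_rate_hz / 2) {
    abort("lp_hz must be below the Nyquist frequency.", class = "oddballerp_config_error")
  }
  win <- switch(cfg$filter_window,
    blackman = signal::blackman(cfg$filter_order + 1),
    hamming = signal::hamming(cfg$filter_order + 1),
    hanning = signal::hanning(cfg$filter_order + 1)
  )
  as.numeric(signal::fir1(cfg$filter_order,
    c(cfg$hp_hz, cfg$lp_hz) / (sample_rate_hz / 2),
    type = "pass", window = win
  ))
}

#' Magnitude response of the designed filter
#'
#' @param cfg A [preprocess_config()].
#' @param sample_rate_hz Sampling rate, Hz.
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @return Numeric vector of magnitude gains.
#' @examples
#' filter_response(preprocess_config(), 500, c(0.05, 10, 30))
#' @export
filter_response <- function(cfg, sample_rate_hz, freq_hz) {
  h <- design_fir(cfg, sample_rate_hz)
  k <- seq_along(h) - 1
  vapply(
    freq_hz,
    function(f) abs(sum(h * exp(-2i * pi * f * k / sample_rate_hz))),
    numeric(1)
  )
}

# Linear convolution by FFT with composite-length zero padding. H may be a
# precomputed kernel spectrum of length nf (shared across channels).
fft_convolve <- function(x, h, H = NULL, nf = NULL) {
  n <- length(x) + length(h) - 1L
  nf <- nf %||% nextn(n, c(2, 3, 5))
  X <- fft(c(x, numeric(nf - length(x))))
  if (is.null(H)) H <- fft(c(h, numeric(nf - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

#' Zero-phase band-pass filter a recording
#'
#' Applies the windowed FIR design per channel by linear convolution, fully
#' compensating the group delay (`filter_order / 2` samples), so that the
#' filter is zero-phase: features are not shifted in time. Channel means (DC)
#' are removed before filtering; the signal is zero-padded at the edges.
#'
#' @param rec An `erp_recording`.
#' @param cfg A [preprocess_config()].
#' @return The recording with filtered `signal`.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "erp_recording"))
  h <- design_fir(cfg, rec$sample_rate_hz)
  n <- nrow(rec$signal)
  if (n <= length(h)) {
    abort(sprintf(
      "Recording has %d samples but the filter kernel needs more than %d (%.1f s at %g Hz).",
      n, length(h), length(h) / rec$sample_rate_hz, rec$sample_rate_hz
    ), class = "oddballerp_length_error")
  }
  delay <- cfg$filter_order %/% 2
  out <- rec
  nf <- nextn(n + length(h) - 1L, c(2, 3, 5))
  H <- fft(c(h, numeric(nf - length(h))))
  take <- if (cfg$zero_phase) delay + seq_len(n) else seq_len(n)
  # real kernel: two channels ride one complex FFT (linearity of convolution)
  j <- 1
  while (j <= ncol(rec$signal)) {
    x1 <- rec$signal[, j]
    x1 <- x1 - mean(x1)
    if (j + 1 <= ncol(rec$signal)) {
      x2 <- rec$signal[, j + 1]
      x2 <- x2 - mean(x2)
      z <- complex(real = c(x1, numeric(nf - n)), imaginary = c(x2, numeric(nf - n)))
      y <- fft(fft(z) * H, inverse = TRUE) / nf
      out$signal[, j] <- Re(y)[take]
      out$signal[, j + 1] <- Im(y)[take]
      j <- j + 2
    } else {
      out$signal[, j] <- fft_convolve(x1, h, H = H, nf = nf)[take]
      j <- j + 1
    }
  }
  out$filtered <- TRUE
  out
}

# Round half away from zero (documented marker-offset rounding rule).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Correct event markers for the stimulus timing delay
#'
#' Sound onset lags the logged marker by a fixed delay; markers are advanced
#' (moved later in the recording) by `round(offset_ms * rate / 1000)` samples,
#' rounding half away from zero. Events shifted past the end of the recording
#' are dropped with a warning.
#'
#' @param events Event tibble with `onset_sample` (and optionally `onset_s`).
#' @param cfg A [preprocess_config()] (uses `offset_ms`).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param n_samples Recording length; events shifted beyond it are dropped.
#' @return The event tibble with shifted onsets.
#' @examples
#' ev <- tibble::tibble(onset_sample = c(100L, 200L))
#' apply_timing_offset(ev, preprocess_config(offset_ms = 32), 500, 1000)
#' @export
apply_timing_offset <- function(events, cfg, sample_rate_hz, n_samples = Inf) {
  if (cfg$offset_ms < 0) abort("offset_ms must be >= 0.", class = "oddballerp_config_error")
  shift <- round_half_away(cfg$offset_ms * sample_rate_hz / 1000)
  events$onset_sample <- as.integer(events$onset_sample + shift)
  if ("onset_s" %in% names(events)) {
    events$onset_s <- events$onset_s + shift / sample_rate_hz
  }
  beyond <- events$onset_sample > n_samples
  if (any(beyond)) {
    warn(sprintf("%d event(s) shifted beyond the recording end were dropped.", sum(beyond)))
    events <- events[!beyond, , drop = FALSE]
  }
  events
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts one epoch per event from `epoch_pre_ms` before to `epoch_post_ms`
#' after onset (inclusive endpoints: at 500 Hz a -200..800 ms epoch has 501
#' samples) and optionally subtracts the per-channel baseline mean (epoch
#' start to 0 ms). Events too close to either edge of the recording are
#' dropped and counted. The timing-offset correction is applied to the event
#' markers first unless `apply_offset = FALSE`.
#'
#' @param rec An `erp_recording` (normally already filtered).
#' @param cfg A [preprocess_config()].
#' @param apply_offset Apply [apply_timing_offset()] to the events first.
#' @return An `erp_epochs` object: `data` (trials x channels x time array,
#'   microvolts), `time_ms`, `info` tibble (`trial`, `condition`, `ordinal`,
#'   `stimulus_id`, `valid`, `reason`, `kept`), `sample_rate_hz`,
#'   `channel_names`, `n_dropped_edge`.
#' @export
epoch <- function(rec, cfg = preprocess_config(), apply_offset = TRUE) {
  stopifnot(inherits(rec, "erp_recording"))
  fs <- rec$sample_rate_hz
  events <- rec$events
  if (apply_offset) {
    events <- apply_timing_offset(events, cfg, fs, nrow(rec$signal))
  }
  pre <- round(cfg$epoch_pre_ms * fs / 1000)
  post <- round(cfg$epoch_post_ms * fs / 1000)
  rel <- seq(-pre, post)
  time_ms <- rel / fs * 1000
  n <- nrow(rec$signal)
  in_range <- events$onset_sample - pre >= 1 & events$onset_sample + post <= n
  n_dropped <- sum(!in_range)
  if (n_dropped > 0) {
    inform(sprintf("%d event(s) too close to the recording edge were excluded.", n_dropped))
  }
  events <- events[in_range, , drop = FALSE]
  ne <- nrow(events)
  dat <- array(0, dim = c(ne, length(CHANNELS), length(rel)))
  bl <- which(rel <= 0)
  idx <- outer(events$onset_sample, rel, "+") # ne x time sample indices
  for (ch in seq_along(CHANNELS)) {
    m <- matrix(rec$signal[idx, ch], nrow = ne)
    if (cfg$baseline_correct) m <- m - rowMeans(m[, bl, drop = FALSE])
    dat[, ch, ] <- m
  }
  structure(
    list(
      data = dat,
      time_ms = time_ms,
      info = tibble(
        trial = events$trial %||% seq_len(nrow(events)),
        condition = factor(as.character(events$condition), levels = CONDITIONS),
        ordinal = events$ordinal %||% NA_integer_,
        stimulus_id = events$stimulus_id %||% NA_character_,
        valid = TRUE, reason = "none", kept = TRUE
      ),
      sample_rate_hz = fs,
      channel_names = CHANNELS,
      n_dropped_edge = n_dropped
    ),
    class = "erp_epochs"
  )
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf(
    "<erp_epochs> %d epochs x %d channels x %d samples (%g..%g ms)\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], min(x$time_ms), max(x$time_ms)
  ))
  cnt <- epoch_counts(x)
  cat("  valid/kept per condition: ",
    paste(sprintf("%s %d/%d", cnt$condition, cnt$n_valid, cnt$n_kept), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-condition epoch bookkeeping
#'
#' @param es An `erp_epochs` object.
#' @return Tibble with per-condition totals, valid counts, kept counts and
#'   rejection-reason counts.
#' @export
epoch_counts <- function(es) {
  es$info %>%
    group_by(condition = .data$condition, .drop = FALSE) %>%
    summarise(
      n_total = n(),
      n_valid = sum(.data$valid),
      n_kept = sum(.data$kept & .data$valid),
      n_ptp = sum(.data$reason == "ptp"),
      n_flatline = sum(.data$reason == "flatline"),
      .groups = "drop"
    )
}

#' Reject artifactual and flatline epochs
#'
#' An epoch is invalid if any monitored channel's peak-to-peak amplitude
#' (maximum minus minimum within the epoch) exceeds `reject_ptp_uv`
#' (reason `"ptp"`), or falls below `flatline_ptp_uv` (reason `"flatline"`).
#' Validity depends only on each epoch's own samples, so rejection is
#' idempotent and invariant to epoch order.
#'
#' @param es An `erp_epochs` object.
#' @param cfg A [preprocess_config()]; `reject_channels` selects whether all
#'   eight channels or only Fz are monitored.
#' @return The epoch set with `valid`, `reason` updated (and `kept` cleared
#'   for invalid epochs).
#' @export
reject_artifacts <- function(es, cfg = preprocess_config()) {
  stopifnot(inherits(es, "erp_epochs"))
  ch <- if (cfg$reject_channels == "Fz") match("Fz", es$channel_names) else seq_along(es$channel_names)
  n_ep <- dim(es$data)[1]
  nt <- dim(es$data)[3]
  ptp <- matrix(0, n_ep, length(ch))
  for (k in seq_along(ch)) {
    m <- matrix(es$data[, ch[k], ], nrow = n_ep)
    mx <- m[, 1]
    mn <- m[, 1]
    for (t in 2:nt) { # running per-epoch range over time
      mx <- pmax(mx, m[, t])
      mn <- pmin(mn, m[, t])
    }
    ptp[, k] <- mx - mn
  }
  too_big <- rowSums(ptp > cfg$reject_ptp_uv) > 0
  flat <- rowSums(ptp < cfg$flatline_ptp_uv) > 0
  es$info$valid <- !(too_big | flat)
  es$info$reason <- ifelse(too_big, "ptp", ifelse(flat, "flatline", "none"))
  es$info$kept <- es$info$kept & es$info$valid
  es
}

#' Equalize valid trial counts across conditions
#'
#' Identifies the condition with the fewest valid trials and takes a seeded
#' random sample of the same size, without replacement, from each other
#' condition. Kept epochs retain their original within-condition ordinals, so
#' presentation order (and the habituation half-split) is preserved.
#'
#' @param es An `erp_epochs` object with validity computed.
#' @param seed Seed for the down-sampling; defaults to the configuration's
#'   `equalize_seed`.
#' @param cfg A [preprocess_config()].
#' @return The epoch set with `kept` down-sampled to the minimum count. If
#'   any condition has zero valid trials the set is marked unusable
#'   (`attr(es, "usable") = FALSE`) and `kept` cleared.
#' @export
equalize_trials <- function(es, seed = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(es, "erp_epochs"))
  seed <- seed %||% cfg$equalize_seed
  valid_idx <- split(which(es$info$valid), es$info$condition[es$info$valid])
  counts <- vapply(CONDITIONS, function(cc) length(valid_idx[[cc]] %||% integer(0)), integer(1))
  if (any(counts == 0)) {
    es$info$kept <- FALSE
    attr(es, "usable") <- FALSE
    warn("At least one condition has zero valid trials; dataset marked unusable.")
    return(es)
  }
  m <- min(counts)
  keep <- logical(nrow(es$info))
  withr::with_seed(seed, {
    for (cc in CONDITIONS) {
      idx <- valid_idx[[cc]]
      keep[if (length(idx) > m) sort(sample(idx, m)) else idx] <- TRUE
    }
  })
  es$info$kept <- keep
  attr(es, "usable") <- TRUE
  es
}

#' Dataset inclusion decision
#'
#' A dataset enters analysis only if, after rejection and equalization, every
#' condition retains at least `min_trials_per_condition` trials.
#'
#' @param es An `erp_epochs` object.
#' @param cfg A [preprocess_config()].
#' @return List with `include` (logical) and `counts` (kept trials per
#'   condition).
#' @export
inclusion_filter <- function(es, cfg = preprocess_config()) {
  cnt <- epoch_counts(es)
  counts <- setNames(cnt$n_kept, as.character(cnt$condition))
  list(
    include = all(counts >= cfg$min_trials_per_condition),
    counts = counts,
    threshold = cfg$min_trials_per_condition
  )
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass filter, timing-offset correction, epoching with baseline
#' correction, artifact/flatline rejection, trial-count equalization and the
#' inclusion decision, in that order.
#'
#' @param rec An `erp_recording`.
#' @param cfg A [preprocess_config()].
#' @param equalize_seed Optional override of the equalization seed.
#' @return List with `epochs` (the final `erp_epochs`), `inclusion` (from
#'   [inclusion_filter()]) and `qc` (per-condition counts tibble).
#' @export
preprocess_session <- function(rec, cfg = preprocess_config(), equalize_seed = NULL) {
  rec <- bandpass_filter(rec, cfg)
  es <- epoch(rec, cfg)
  es <- reject_artifacts(es, cfg)
  es <- equalize_trials(es, seed = equalize_seed, cfg = cfg)
  inc <- inclusion_filter(es, cfg)
  list(epochs = es, inclusion = inc, qc = epoch_counts(es))
}
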