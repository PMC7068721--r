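#' Synthesize a continuous multi-channel EEG recording
#'
#' Forward model for one session. The stimulus-locked response is a sum of
#' Gaussian component bumps (see [component_template()]); each event adds its
#' templates scaled by the condition amplitude and by the habituation decay
#' `(1 - rate)^(ordinal - 1)`. A single response time course is generated and
#' projected to the eight channels through fixed frontocentral gains (Fz
#' strongest, as the frontal novelty response predicts). On top of this the
#' simulator adds broadband noise (an even mix of white and 1/f pink noise),
#' a slow sinusoidal drift emulating sweat-induced baseline wander, and — in a
#' randomly chosen `artifact_epoch_fraction` of trials — a 7 Hz, 400 ms burst
#' with 500 microvolt peak-to-peak amplitude on one random channel, guaranteed
#' to trip the 200 microvolt rejection rule.
#'
#' @param subject A [subject_spec()].
#' @param sequence A `stimulus_sequence` from [generate_sequence()].
#' @param duration_s Optional fixed recording duration. The default extends
#'   1.5 s past the last onset; if given and the sequence extends beyond it,
#'   an error is raised.
#' @return An `erp_recording`: list with `signal` (time x 8 channel matrix,
#'   microvolts), `sample_rate_hz`, `channel_names`, `reference`
#'   (`"left mastoid"`), `events` (the sequence tibble), `subject`
#'   (the subject specification), and `artifact_trials` (ground-truth
#'   injected trial indices).
#' @examples
#' des <- oddball_design(n_frequent = 16, n_infrequent = 2, n_trial_unique = 2)
#' rec <- synthesize_recording(
#'   subject_spec("s1", seed = 3),
#'   generate_sequence(des, seed = 3)
#' )
#' dim(rec$signal)
#' @export
synthesize_recording <- function(subject, sequence, duration_s = NULL) {
  stopifnot(inherits(subject, "subject_spec"), inherits(sequence, "stimulus_sequence"))
  design <- attr(sequence, "design")
  fs <- design$sample_rate_hz
  need_s <- max(sequence$onset_s) + 1.5
  if (is.null(duration_s)) {
    duration_s <- need_s
  } else if (duration_s < need_s) {
    abort(sprintf(
      "Sequence extends to %.1f s but duration_s is %.1f s.", need_s, duration_s
    ), class = "oddballerp_config_error")
  }
  n_samp <- ceiling(duration_s * fs)
  n_trials <- nrow(sequence)
  gains <- c(Fz = 1, FC1 = 0.9, FC2 = 0.9, C1 = 0.8, Cz = 0.8, C2 = 0.8, CP1 = 0.7, CP2 = 0.7)

  # Deterministic single-timecourse ERP layer.
  erp <- numeric(n_samp)
  for (tpl in subject$templates) {
    sigma_samp <- tpl$width_ms / 1000 * fs
    half <- ceiling(4 * sigma_samp)
    rel <- seq(-half, half)
    kernel <- exp(-(rel - 0)^2 / (2 * sigma_samp^2))
    # responses are locked to the acoustic onset, which lags the marker
    peak_off <- round((tpl$peak_latency_ms + (design$stimulus_delay_ms %||% 0)) / 1000 * fs)
    amps <- tpl$amplitude_by_condition[as.character(sequence$condition)] *
      (1 - tpl$habituation_rate[as.character(sequence$condition)])^(sequence$ordinal - 1)
    for (i in seq_len(n_trials)) {
      idx <- sequence$onset_sample[i] + peak_off + rel
      ok <- idx >= 1 & idx <= n_samp
      erp[idx[ok]] <- erp[idx[ok]] + amps[i] * kernel[ok]
    }
  }
  signal <- matrix(0, n_samp, 8)

  withr::with_seed(subject$seed, {
    tt <- (seq_len(n_samp) - 1) / fs
    phases <- if (subject$drift_amplitude_uv > 0) runif(8, 0, 2 * pi) else numeric(8)
    for (j in 1:8) {
      col <- erp * gains[j]
      if (subject$noise_sd_uv > 0) {
        col <- col + subject$noise_sd_uv * sqrt(0.5) *
          (rnorm(n_samp) + pink_shape(rnorm(n_samp)))
      }
      if (subject$drift_amplitude_uv > 0) {
        col <- col + subject$drift_amplitude_uv *
          sin(2 * pi * tt / subject$drift_period_s + phases[j])
      }
      signal[, j] <- col
    }
    n_art <- round(subject$artifact_epoch_fraction * n_trials)
    artifact_trials <- sort(sample(n_trials, n_art))
    if (n_art > 0) {
      burst_len <- round(0.4 * fs)
      tt_b <- seq_len(burst_len) / fs
      burst <- 250 * sin(2 * pi * 7 * tt_b)
      delay_samp <- round((design$stimulus_delay_ms %||% 0) / 1000 * fs)
      for (i in artifact_trials) {
        ch <- sample(8, 1)
        start <- sequence$onset_sample[i] + delay_samp + round(0.05 * fs)
        idx <- start + seq_len(burst_len) - 1L
        ok <- idx <= n_samp
        signal[idx[ok], ch] <- signal[idx[ok], ch] + burst[ok]
      }
    }
  })

  structure(
    list(
      signal = unname(signal),
      sample_rate_hz = fs,
      channel_names = CHANNELS,
      reference = "left mastoid",
      events = sequence,
      subject = subject,
      artifact_trials = artifact_trials
    ),
    class = "erp_recording"
  )
}

# Shape unit-variance white noise into unit-variance 1/f pink noise via
# frequency-domain 1/sqrt(f) scaling (FFT at a composite padded length).
pink_shape <- function(x) {
  n <- length(x)
  nf <- nextn(n, c(2, 3, 5))
  sp <- fft(c(x, numeric(nf - n)))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1) # fold to two-sided frequency magnitude
  sp <- sp / sqrt(f)
  sp[1] <- 0
  out <- Re(fft(sp, inverse = TRUE))[seq_len(n)] / nf
  out / sd(out)
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf(
    "<erp_recording> %s (%s, %s): %d samples x %d channels @ %g Hz, %d events\n",
    x$subject$subject_id, x$subject$cohort, x$subject$age_point,
    nrow(x$signal), ncol(x$signal), x$sample_rate_hz, nrow(x$events)
  ))
  invisible(x)
}

#' @export
as_tibble.erp_recording <- function(x, ...) {
  sig <- as.data.frame(x$signal)
  names(sig) <- x$channel_names
  dplyr::bind_cols(
    tibble(time_s = (seq_len(nrow(x$signal)) - 1) / x$sample_rate_hz),
    sig
  )
}
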