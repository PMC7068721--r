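# Shared fixtures, all generated in code.

# Small session design: 60 trials, enough for preprocessing paths.
small_design <- function(...) {
  oddball_design(n_frequent = 40, n_infrequent = 10, n_trial_unique = 10, ...)
}

# Widely spaced design: ISIs long enough that adjacent responses never
# overlap, and no hardware delay, so epoching at the marker gives window
# means that are analytically predictable.
sparse_design <- function(n_frequent = 4, n_infrequent = 4, n_trial_unique = 4) {
  oddball_design(
    n_frequent = n_frequent, n_infrequent = n_infrequent,
    n_trial_unique = n_trial_unique,
    isi_mean_ms = 3000, isi_min_ms = 3000, isi_max_ms = 3000,
    stimulus_delay_ms = 0
  )
}

# Noise-free subject: deterministic forward model only.
clean_subject <- function(age_point = "1m", templates = NULL, seed = 1, ...) {
  subject_spec("clean",
    age_point = age_point,
    templates = templates %||% age_templates(age_point),
    noise_sd_uv = 0, drift_amplitude_uv = 0, artifact_epoch_fraction = 0,
    seed = seed, ...
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build an erp_epochs object directly from a trials x channels x time array.
make_epochs <- function(dat, time_ms, conditions, ordinal = NULL, fs = 500) {
  n <- dim(dat)[1]
  conditions <- factor(as.character(conditions),
    levels = c("Frequent", "Infrequent", "TrialUnique")
  )
  ordinal <- ordinal %||% as.integer(stats::ave(seq_len(n), conditions, FUN = seq_along))
  structure(
    list(
      data = dat, time_ms = time_ms,
      info = tibble::tibble(
        trial = seq_len(n), condition = conditions, ordinal = ordinal,
        stimulus_id = NA_character_, valid = TRUE, reason = "none", kept = TRUE
      ),
      sample_rate_hz = fs,
      channel_names = c("Fz", "FC1", "FC2", "C1", "Cz", "C2", "CP1", "CP2"),
      n_dropped_edge = 0L
    ),
    class = "erp_epochs"
  )
}

# Epochs whose Fz trace is given per trial; other channels copy Fz.
epochs_from_fz <- function(fz_matrix, time_ms, conditions, ...) {
  n <- nrow(fz_matrix)
  dat <- array(0, c(n, 8, ncol(fz_matrix)))
  for (ch in 1:8) dat[, ch, ] <- fz_matrix
  make_epochs(dat, time_ms, conditions, ...)
}

# Band-limited waveform noise: white noise smoothed by a short moving
# average, rescaled — emulates the residual noise on an averaged, 0.5-30 Hz
# filtered waveform (smooth, not sample-wise white).
smooth_noise <- function(n, sd_uv) {
  y <- stats::filter(rnorm(n + 20), rep(1 / 8, 8), sides = 2)
  y <- y[!is.na(y)][1:n]
  y / sd(y) * sd_uv
}

# Per-subject, per-cell waveforms for jackknife latency studies:
# lat_by_subject is a subjects x cells matrix of true peak latencies; noise
# is band-limited as on real averaged waveforms.
jk_data <- function(lat_by_subject, cells = c("A", "B"), noise_sd = 0, seed = 1) {
  time_ms <- seq(-200, 800, by = 2)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(lat_by_subject)), function(i) {
      purrr::map_dfr(seq_along(cells), function(j) {
        amp <- 10 * exp(-(time_ms - lat_by_subject[i, j])^2 / (2 * 40^2))
        if (noise_sd > 0) amp <- amp + smooth_noise(length(time_ms), noise_sd)
        tibble::tibble(
          subject = paste0("s", i), cell = cells[j],
          time_ms = time_ms, amplitude_uv = amp
        )
      })
    })
  })
}

# Independent analytic oracle: inclusive-endpoint sample mean of a Gaussian
# bump over a window equals the midpoint-rule integral over the half-sample
# widened window.
gauss_window_mean <- function(amp, mu, sigma, a, b, dt = 2) {
  amp * sigma * sqrt(2 * pi) *
    (pnorm((b + dt / 2 - mu) / sigma) - pnorm((a - dt / 2 - mu) / sigma)) /
    (b - a + dt)
}
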