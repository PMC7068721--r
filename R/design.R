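#' Oddball session design
#'
#' Describes one auditory-oddball session: how many trials of each condition
#' are presented, stimulus duration, and the inter-stimulus-interval (ISI)
#' jitter. Defaults reproduce the standard infant design: 1000 trials of which
#' 800 are Frequent pure tones, 100 Infrequent white-noise deviants and 100
#' Trial Unique novel sounds, each presented for 100 ms with a 5 ms on/off
#' ramp, with ISIs jittered uniformly between 650 and 750 ms (mean 700 ms),
#' sampled at 500 Hz.
#'
#' @param n_frequent,n_infrequent,n_trial_unique Trial counts per condition.
#' @param n_trials_total Total number of trials; must equal the sum of the
#'   per-condition counts.
#' @param stim_duration_ms Stimulus duration in ms.
#' @param ramp_ms On/off ramp in ms (metadata only; no audio is rendered).
#' @param isi_mean_ms,isi_min_ms,isi_max_ms ISI jitter in ms. The jitter is
#'   drawn uniformly on `[isi_min_ms, isi_max_ms]`.
#' @param sample_rate_hz Sampling rate of the EEG recording in Hz.
#' @param stimulus_delay_ms Hardware stimulus-delivery delay: the acoustic
#'   onset lags the logged event marker by this much (default 32 ms). The
#'   simulator places responses at marker + delay; the preprocessing offset
#'   correction compensates it.
#'
#' @return An object of class `oddball_design`.
#' @examples
#' oddball_design()
#' oddball_design(n_frequent = 40, n_infrequent = 10, n_trial_unique = 10)
#' @export
oddball_design <- function(n_frequent = 800,
                           n_infrequent = 100,
                           n_trial_unique = 100,
                           n_trials_total = n_frequent + n_infrequent + n_trial_unique,
                           stim_duration_ms = 100,
                           ramp_ms = 5,
                           isi_mean_ms = 700,
                           isi_min_ms = 650,
                           isi_max_ms = 750,
                           sample_rate_hz = 500,
                           stimulus_delay_ms = 32) {
  if (n_frequent + n_infrequent + n_trial_unique != n_trials_total) {
    abort(sprintf(
      "Condition counts (%d + %d + %d) do not sum to n_trials_total (%d).",
      n_frequent, n_infrequent, n_trial_unique, n_trials_total
    ), class = "oddballerp_config_error")
  }
  if (any(c(n_frequent, n_infrequent, n_trial_unique) < 0)) {
    abort("Trial counts must be non-negative.", class = "oddballerp_config_error")
  }
  if (!(isi_min_ms <= isi_mean_ms && isi_mean_ms <= isi_max_ms)) {
    abort("ISI bounds must satisfy isi_min_ms <= isi_mean_ms <= isi_max_ms.",
      class = "oddballerp_config_error"
    )
  }
  structure(
    list(
      n_trials_total = as.integer(n_trials_total),
      n_frequent = as.integer(n_frequent),
      n_infrequent = as.integer(n_infrequent),
      n_trial_unique = as.integer(n_trial_unique),
      stim_duration_ms = stim_duration_ms,
      ramp_ms = ramp_ms,
      isi_mean_ms = isi_mean_ms,
      isi_min_ms = isi_min_ms,
      isi_max_ms = isi_max_ms,
      sample_rate_hz = sample_rate_hz,
      stimulus_delay_ms = stimulus_delay_ms
    ),
    class = "oddball_design"
  )
}

#' @export
print.oddball_design <- function(x, ...) {
  cat(sprintf(
    "<oddball_design> %d trials (%d Frequent / %d Infrequent / %d TrialUnique)\n",
    x$n_trials_total, x$n_frequent, x$n_infrequent, x$n_trial_unique
  ))
  cat(sprintf(
    "  stimulus %g ms (ramp %g ms), ISI U[%g, %g] ms, %g Hz\n",
    x$stim_duration_ms, x$ramp_ms, x$isi_min_ms, x$isi_max_ms, x$sample_rate_hz
  ))
  invisible(x)
}

#' ERP component template
#'
#' A Gaussian-bump forward model for one ERP component: the component
#' contributes `amplitude * exp(-(t - peak_latency)^2 / (2 * width^2))`
#' microvolts to the stimulus-locked response. Amplitudes are signed (negative
#' components such as N1/Nc carry negative amplitudes) and condition-specific.
#' Habituation is modelled as exponential amplitude decay across the session:
#' the k-th presentation of a condition (k = 0, 1, ...) is scaled by
#' `(1 - habituation_rate)^k`.
#'
#' @param name Component label, one of `"N1"`, `"P1"`, `"N2"`, `"P3"`, `"Nc"`.
#' @param peak_latency_ms Latency of the Gaussian peak, ms post stimulus onset.
#' @param width_ms Gaussian standard deviation in ms.
#' @param amplitude_by_condition Named numeric vector of signed peak
#'   amplitudes in microvolts, names in
#'   `c("Frequent", "Infrequent", "TrialUnique")`.
#' @param habituation_rate Per-trial fractional decay in `[0, 1)`; scalar or
#'   named per condition.
#'
#' @return An object of class `component_template`.
#' @examples
#' component_template("P3", 330, 50,
#'   c(Frequent = 4, Infrequent = 9, TrialUnique = 5),
#'   habituation_rate = c(Frequent = 0.001, Infrequent = 0.002, TrialUnique = 0)
#' )
#' @export
component_template <- function(name, peak_latency_ms, width_ms,
                               amplitude_by_condition,
                               habituation_rate = 0) {
  name <- match.arg(name, c("N1", "P1", "N2", "P3", "Nc"))
  if (width_ms <= 0) abort("width_ms must be > 0.", class = "oddballerp_config_error")
  if (!all(is.finite(amplitude_by_condition))) {
    abort("Component amplitudes must be finite.", class = "oddballerp_config_error")
  }
  if (is.null(names(amplitude_by_condition))) {
    amplitude_by_condition <- setNames(rep_len(amplitude_by_condition, 3), CONDITIONS)
  }
  stopifnot(all(CONDITIONS %in% names(amplitude_by_condition)))
  if (length(habituation_rate) == 1 && is.null(names(habituation_rate))) {
    habituation_rate <- setNames(rep(habituation_rate, 3), CONDITIONS)
  }
  stopifnot(all(CONDITIONS %in% names(habituation_rate)))
  if (any(habituation_rate < 0 | habituation_rate >= 1)) {
    abort("habituation_rate must lie in [0, 1).", class = "oddballerp_config_error")
  }
  structure(
    list(
      name = name,
      polarity = if (mean(amplitude_by_condition[CONDITIONS]) >= 0) "+" else "-",
      peak_latency_ms = peak_latency_ms,
      width_ms = width_ms,
      amplitude_by_condition = amplitude_by_condition[CONDITIONS],
      habituation_rate = habituation_rate[CONDITIONS]
    ),
    class = "component_template"
  )
}

#' Default component template sets per age point
#'
#' Age-appropriate ERP morphology: at 1 month a unitary early negativity (N1)
#' followed by P3 and Nc; at 5 months the N1 is replaced by a faster P1/N2
#' complex, and P3/Nc peak earlier, reflecting the latency decrease with age.
#' P3 amplitudes and habituation rates are left to the caller (they carry the
#' cohort ground truth); the remaining components are condition-blind.
#'
#' @param age_point `"1m"` or `"5m"`.
#' @param p3_amplitude Named signed peak amplitudes (microvolts) for P3 per
#'   condition.
#' @param p3_habituation Named per-trial decay rates for P3 per condition.
#' @param p3_latency_ms P3 peak latency; defaults 330 ms at 1 month, 290 ms at
#'   5 months (within the age-specific analysis windows).
#' @return A list of [component_template()] objects.
#' @export
age_templates <- function(age_point = c("1m", "5m"),
                          p3_amplitude = c(Frequent = 4, Infrequent = 9, TrialUnique = 5),
                          p3_habituation = c(Frequent = 0.001, Infrequent = 0.002, TrialUnique = 0),
                          p3_latency_ms = if (age_point == "1m") 330 else 290) {
  age_point <- match.arg(age_point)
  p3 <- component_template("P3", p3_latency_ms, if (age_point == "1m") 50 else 45,
    p3_amplitude,
    habituation_rate = p3_habituation
  )
  if (age_point == "1m") {
    list(
      component_template("N1", 100, 25, c(Frequent = -5, Infrequent = -5, TrialUnique = -5)),
      p3,
      component_template("Nc", 650, 60, c(Frequent = -6, Infrequent = -6, TrialUnique = -6))
    )
  } else {
    list(
      component_template("P1", 70, 8, c(Frequent = 3, Infrequent = 3, TrialUnique = 3)),
      component_template("N2", 100, 10, c(Frequent = -3, Infrequent = -3, TrialUnique = -3)),
      p3,
      component_template("Nc", 600, 60, c(Frequent = -7, Infrequent = -7, TrialUnique = -7))
    )
  }
}

#' Subject-level simulation specification
#'
#' Bundles everything needed to synthesize one session of continuous EEG for
#' one subject at one age point: the component templates, noise and drift
#' parameters, the fraction of epochs contaminated by high-amplitude
#' artifacts, and the seed that makes the session reproducible.
#'
#' Noise defaults emulate awake infant EEG: 20 microvolt RMS broadband noise
#' (half white, half 1/f), a 50 microvolt slow sinusoidal drift with a 10 s
#' period standing in for sweat-induced baseline wander, and 35% of epochs
#' carrying a >200 microvolt transient (movement/fussing), which reproduces
#' the retained-trial counts reported for infant sessions (roughly 60 of 100
#' oddball trials surviving rejection).
#'
#' @param subject_id Subject identifier string.
#' @param cohort `"UK"` or `"Gambia"`.
#' @param age_point `"1m"` or `"5m"`.
#' @param state `"awake"` or `"asleep"`.
#' @param templates List of [component_template()] objects.
#' @param noise_sd_uv Broadband noise standard deviation, microvolts.
#' @param drift_amplitude_uv Amplitude of the slow sinusoidal drift, microvolts.
#' @param drift_period_s Period of the drift, seconds.
#' @param artifact_epoch_fraction Fraction of trials receiving an injected
#'   high-amplitude artifact, in `[0, 1]`.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   recording.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, cohort = c("UK", "Gambia"),
                         age_point = c("1m", "5m"),
                         state = c("awake", "asleep"),
                         templates = age_templates(age_point),
                         noise_sd_uv = 20,
                         drift_amplitude_uv = 50,
                         drift_period_s = 10,
                         artifact_epoch_fraction = 0.35,
                         seed = 1L) {
  cohort <- match.arg(cohort)
  age_point <- match.arg(age_point)
  state <- match.arg(state)
  if (artifact_epoch_fraction < 0 || artifact_epoch_fraction > 1) {
    abort("artifact_epoch_fraction must lie in [0, 1].", class = "oddballerp_config_error")
  }
  stopifnot(all(vapply(templates, inherits, logical(1), "component_template")))
  structure(
    list(
      subject_id = as.character(subject_id), cohort = cohort,
      age_point = age_point, state = state, templates = templates,
      noise_sd_uv = noise_sd_uv, drift_amplitude_uv = drift_amplitude_uv,
      drift_period_s = drift_period_s,
      artifact_epoch_fraction = artifact_epoch_fraction,
      seed = as.integer(seed)
    ),
    class = "subject_spec"
  )
}

#' Cohort-level ground truth presets
#'
#' Encodes the developmental pattern each simulated cohort realizes, in
#' template peak-amplitude units (microvolts):
#'
#' * `"UK"`: an intensity-driven response at 1 month (Infrequent white noise
#'   elicits the largest P3) crossing over to a novelty-driven response at 5
#'   months (Trial Unique largest), with habituation to the Infrequent sounds
#'   strengthening with age. True delta-P3 is positive.
#' * `"Gambia"`: the same intensity-driven pattern at 1 month but no crossover
#'   by 5 months — the Infrequent minus Trial Unique contrast is unchanged
#'   across age (true delta-P3 = 0) and habituation does not strengthen.
#'
#' The outcome composite score is linearly coupled to each subject's true
#' delta-P3: `outcome = outcome_mean + slope * delta_p3 + N(0, outcome_sd)`.
#' The default slope gives a population R-squared of 0.08 for the
#' within-cohort delta-P3/outcome association.
#'
#' @param preset `"UK"` or `"Gambia"`.
#' @param amplitude_subject_sd Between-subject SD of each true P3 condition
#'   amplitude, microvolts.
#' @param delta_p3_outcome_slope Outcome points per microvolt of true delta-P3.
#'   Default calibrated for population R-squared 0.08 under the preset.
#' @param outcome_mean,outcome_sd Mean and residual SD of the outcome
#'   composite score.
#' @return An object of class `cohort_truth`.
#' @examples
#' cohort_truth("UK")
#' cohort_truth("Gambia")$p3_amplitude
#' @export
cohort_truth <- function(preset = c("UK", "Gambia"),
                         amplitude_subject_sd = 1.5,
                         delta_p3_outcome_slope = NULL,
                         outcome_mean = NULL,
                         outcome_sd = 12) {
  preset <- match.arg(preset)
  amp <- if (preset == "UK") {
    list(
      `1m` = c(Frequent = 4, Infrequent = 9, TrialUnique = 5),
      `5m` = c(Frequent = 4, Infrequent = 5, TrialUnique = 9)
    )
  } else {
    # Infrequent and TrialUnique both decline mildly with age so the
    # Infrequent - TrialUnique contrast stays constant: no crossover,
    # true delta-P3 exactly zero.
    list(
      `1m` = c(Frequent = 4, Infrequent = 9, TrialUnique = 5),
      `5m` = c(Frequent = 4, Infrequent = 8.5, TrialUnique = 4.5)
    )
  }
  hab <- if (preset == "UK") {
    # 5-month Infrequent rate sized so the habituation gain across age is a
    # medium-large subject-level effect, matching the reported magnitude of
    # the developmental habituation change.
    list(
      `1m` = c(Frequent = 0.001, Infrequent = 0.002, TrialUnique = 0),
      `5m` = c(Frequent = 0.001, Infrequent = 0.020, TrialUnique = 0)
    )
  } else {
    list(
      `1m` = c(Frequent = 0.001, Infrequent = 0.004, TrialUnique = 0),
      `5m` = c(Frequent = 0.001, Infrequent = 0.004, TrialUnique = 0)
    )
  }
  outcome_mean <- outcome_mean %||% if (preset == "UK") 93.7 else 96.7
  # True delta-P3 combines four independent subject-level amplitude draws, so
  # its between-subject SD is 2 * amplitude_subject_sd.
  sd_delta <- 2 * amplitude_subject_sd
  delta_p3_outcome_slope <- delta_p3_outcome_slope %||%
    slope_for_rsq(0.08, sd_delta, outcome_sd)
  anthro <- if (preset == "UK") {
    list(
      `1m` = c(waz = -0.066, laz = -0.305, hcz = 0.698, wlz = 0.100),
      `5m` = c(waz = -0.136, laz = -0.030, hcz = 0.746, wlz = 0.147)
    )
  } else {
    list(
      `1m` = c(waz = -0.603, laz = -0.852, hcz = -0.285, wlz = 0.292),
      `5m` = c(waz = -0.447, laz = -0.492, hcz = -0.356, wlz = -0.104)
    )
  }
  structure(
    list(
      preset = preset,
      p3_amplitude = amp,
      habituation_rate = hab,
      amplitude_subject_sd = amplitude_subject_sd,
      delta_p3_outcome_slope = delta_p3_outcome_slope,
      outcome_mean = outcome_mean,
      outcome_sd = outcome_sd,
      anthro_mean = anthro
    ),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  d1 <- x$p3_amplitude$`1m`["Infrequent"] - x$p3_amplitude$`1m`["TrialUnique"]
  d5 <- x$p3_amplitude$`5m`["Infrequent"] - x$p3_amplitude$`5m`["TrialUnique"]
  cat(sprintf(
    "<cohort_truth> preset %s: true delta-P3 = %.1f uV (contrast %.1f at 1m, %.1f at 5m)\n",
    x$preset, d1 - d5, d1, d5
  ))
  invisible(x)
}

#' Slope giving a target population R-squared
#'
#' For `outcome = slope * x + noise` with `sd(x) = sd_x` and
#' `sd(noise) = outcome_sd`, returns the slope for which the population
#' R-squared of the regression of outcome on x equals `rsq`.
#'
#' @param rsq Target population R-squared in `[0, 1)`.
#' @param sd_x Between-subject SD of the predictor.
#' @param outcome_sd Residual SD of the outcome.
#' @return Slope in outcome units per predictor unit.
#' @examples
#' slope_for_rsq(0.08, 3, 12)
#' @export
slope_for_rsq <- function(rsq, sd_x, outcome_sd) {
  stopifnot(rsq >= 0, rsq < 1, sd_x > 0)
  sqrt(rsq / (1 - rsq)) * outcome_sd / sd_x
}
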