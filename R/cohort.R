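#' Generate a simulated infant cohort with known ground truth
#'
#' Draws, per subject: true condition-specific P3 amplitudes at both age
#' points (preset mean plus between-subject noise), correlated anthropometric
#' z-scores (WAZ/LAZ/HCZ/WLZ at 1 and 5 months), and an outcome composite
#' score linearly coupled to the subject's true delta-P3. Subject
#' specifications for EEG synthesis at both age points are stored so the
#' signal level can be materialized lazily, one session at a time (see
#' [run_cohort_pipeline()]); ground-truth marker columns are kept for
#' recovery tests.
#'
#' @param truths List of [cohort_truth()] presets (one per cohort).
#' @param n_per_cohort Subjects per cohort, >= 2.
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @param design An [oddball_design()] shared by all sessions.
#' @param noise_sd_uv,drift_amplitude_uv,artifact_epoch_fraction Signal-level
#'   parameters forwarded to every [subject_spec()].
#' @param preprocess A [preprocess_config()] defining the measurement
#'   operator for the measurement-scale truth columns (the filter and
#'   baseline settings the analysis will use); the truth is the noise-free
#'   expectation of the measured contrast under that operator.
#' @return An `erp_cohort`: list with `subjects` (tibble of covariates,
#'   outcome and truth columns, with per-age [subject_spec()]s in list
#'   columns `spec_1m`, `spec_5m` and sequence seeds), `design`, `truths`.
#'   Truth columns include the template-unit contrasts (`true_delta_p3`) and
#'   the measurement-scale expectations implied by the Gaussian forward model
#'   (`true_delta_p3_meas`, from [template_window_mean()] with the
#'   session-average habituation decay).
#' @export
generate_cohort <- function(truths = list(cohort_truth("UK"), cohort_truth("Gambia")),
                            n_per_cohort = 20, seed = 1L,
                            design = oddball_design(),
                            noise_sd_uv = 20, drift_amplitude_uv = 50,
                            artifact_epoch_fraction = 0.35,
                            preprocess = preprocess_config()) {
  if (n_per_cohort < 2) {
    abort("n_per_cohort must be >= 2.", class = "oddballerp_config_error")
  }
  if (is.null(names(truths))) {
    names(truths) <- vapply(truths, function(x) x$preset, character(1))
  }
  ages <- c("1m", "5m")
  rows <- list()
  sidx <- 0
  for (cname in names(truths)) {
    tr <- truths[[cname]]
    for (i in seq_len(n_per_cohort)) {
      sidx <- sidx + 1
      sid <- sprintf("%s_%03d", cname, i)
      sseed <- child_seed(seed, sidx)
      # subject-level true P3 amplitudes per condition x age
      amps <- withr::with_seed(child_seed(sseed, 1), {
        lapply(ages, function(a) {
          tr$p3_amplitude[[a]] + rnorm(3, 0, tr$amplitude_subject_sd)
        })
      })
      names(amps) <- ages
      contrast <- vapply(
        ages,
        function(a) amps[[a]]["Infrequent"] - amps[[a]]["TrialUnique"],
        numeric(1)
      )
      true_delta <- unname(contrast["1m"] - contrast["5m"])
      # measurement-scale expectations under the analysis operator
      meas <- vapply(ages, function(a) {
        tpl <- component_template("P3",
          if (a == "1m") 330 else 290,
          if (a == "1m") 50 else 45,
          amps[[a]],
          habituation_rate = tr$habituation_rate[[a]]
        )
        w <- get_window("P3", a)
        measured_template_mean(tpl, w, "Infrequent", design$n_infrequent,
          preprocess, design$sample_rate_hz
        ) -
          measured_template_mean(tpl, w, "TrialUnique", design$n_trial_unique,
            preprocess, design$sample_rate_hz
          )
      }, numeric(1))
      hab_truth <- vapply(ages, function(a) {
        tpl <- component_template("P3",
          if (a == "1m") 330 else 290,
          if (a == "1m") 50 else 45,
          amps[[a]],
          habituation_rate = tr$habituation_rate[[a]]
        )
        w <- get_window("P3", a)
        shape <- measured_template_mean(
          component_template("P3", tpl$peak_latency_ms, tpl$width_ms,
            c(Frequent = 1, Infrequent = 1, TrialUnique = 1)
          ),
          w, "Infrequent", 1, preprocess, design$sample_rate_hz
        )
        r <- tr$habituation_rate[[a]][["Infrequent"]]
        k <- seq_len(design$n_infrequent) - 1
        half <- ceiling(length(k) / 2)
        decay <- (1 - r)^k
        amps[[a]][["Infrequent"]] * shape *
          (mean(decay[seq_len(half)]) - mean(decay[(half + 1):length(k)]))
      }, numeric(1))
      anthro <- draw_anthro(tr, child_seed(sseed, 2))
      outcome <- withr::with_seed(child_seed(sseed, 3), {
        tr$outcome_mean + tr$delta_p3_outcome_slope * true_delta +
          rnorm(1, 0, tr$outcome_sd)
      })
      specs <- lapply(ages, function(a) {
        subject_spec(sid,
          cohort = if (cname %in% c("UK", "Gambia")) cname else "UK",
          age_point = a,
          state = if (a == "1m") "asleep" else "awake",
          templates = age_templates(a,
            p3_amplitude = amps[[a]],
            p3_habituation = tr$habituation_rate[[a]]
          ),
          noise_sd_uv = noise_sd_uv,
          drift_amplitude_uv = drift_amplitude_uv,
          artifact_epoch_fraction = artifact_epoch_fraction,
          seed = child_seed(sseed, match(a, ages) + 10)
        )
      })
      rows[[sidx]] <- tibble(
        subject_id = sid, cohort = cname,
        true_contrast_1m = unname(contrast["1m"]),
        true_contrast_5m = unname(contrast["5m"]),
        true_delta_p3 = true_delta,
        true_delta_p3_meas = unname(meas["1m"] - meas["5m"]),
        true_hab_1m = unname(hab_truth["1m"]),
        true_hab_5m = unname(hab_truth["5m"]),
        true_hab_gain = unname(hab_truth["5m"] - hab_truth["1m"]),
        outcome = outcome,
        !!!anthro,
        spec_1m = list(specs[[1]]), spec_5m = list(specs[[2]]),
        seq_seed_1m = child_seed(sseed, 21), seq_seed_5m = child_seed(sseed, 22)
      )
    }
  }
  structure(
    list(subjects = bind_rows(rows), design = design, truths = truths, seed = seed),
    class = "erp_cohort"
  )
}

# Correlated anthropometric z-scores at both ages: within-age cross-measure
# correlation 0.45, cross-age same-measure 0.7, cross-age cross-measure 0.3.
anthro_cor <- function() {
  R <- matrix(0.3, 8, 8)
  R[1:4, 1:4] <- 0.45
  R[5:8, 5:8] <- 0.45
  for (i in 1:4) {
    R[i, i + 4] <- 0.7
    R[i + 4, i] <- 0.7
  }
  diag(R) <- 1
  R
}

draw_anthro_matrix <- function(truth, n) {
  vars <- c("waz", "laz", "hcz", "wlz")
  mu <- c(truth$anthro_mean$`1m`[vars], truth$anthro_mean$`5m`[vars])
  z <- MASS::mvrnorm(n, mu, anthro_cor())
  if (n == 1) z <- matrix(z, nrow = 1)
  colnames(z) <- c(paste0(vars, "_1m"), paste0(vars, "_5m"))
  out <- as_tibble(z)
  for (v in vars) out[[paste0("d_", v)]] <- out[[paste0(v, "_5m")]] - out[[paste0(v, "_1m")]]
  out
}

draw_anthro <- function(truth, seed) {
  as.list(withr::with_seed(seed, draw_anthro_matrix(truth, 1)))
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf(
    "<erp_cohort> %d subjects (%s), design %d trials, seed %s\n",
    nrow(x$subjects),
    paste(names(table(x$subjects$cohort)), table(x$subjects$cohort),
      sep = " n=", collapse = ", "
    ),
    x$design$n_trials_total, format(x$seed)
  ))
  invisible(x)
}

#' Run the full analysis pipeline over a simulated cohort
#'
#' For every subject and age point: generate the stimulus sequence,
#' synthesize the recording, preprocess it (filter, offset, epoch, reject,
#' equalize, inclusion), measure the registry components at Fz, and compute
#' habituation scores. Sessions are materialized one at a time and discarded,
#' so memory stays flat. Returns tidy tables ready for the marker and
#' statistics layers.
#'
#' @param cohort An `erp_cohort` from [generate_cohort()].
#' @param cfg A [preprocess_config()].
#' @param progress Print one line per processed session.
#' @return List of tibbles: `measures` (per subject x age x condition x
#'   component), `habituation` (per subject x age x condition), `qc` (per
#'   session retention counts and inclusion decisions), and `markers`
#'   (per subject: delta-P3 joined with covariates, outcome and truth).
#' @export
run_cohort_pipeline <- function(cohort, cfg = preprocess_config(), progress = FALSE) {
  stopifnot(inherits(cohort, "erp_cohort"))
  measures <- list()
  habs <- list()
  qcs <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    row <- cohort$subjects[i, ]
    for (a in c("1m", "5m")) {
      spec <- row[[paste0("spec_", a)]][[1]]
      seqn <- generate_sequence(cohort$design, seed = row[[paste0("seq_seed_", a)]])
      rec <- synthesize_recording(spec, seqn)
      pp <- preprocess_session(rec, cfg, equalize_seed = child_seed(spec$seed, 99))
      qcs[[length(qcs) + 1]] <- pp$qc %>% mutate(
        subject_id = row$subject_id, cohort = row$cohort, age_point = a,
        included = pp$inclusion$include, .before = 1
      )
      if (!pp$inclusion$include) next
      measures[[length(measures) + 1]] <- measure_components(
        pp$epochs, a,
        subject_id = row$subject_id
      ) %>% mutate(cohort = row$cohort)
      habs[[length(habs) + 1]] <- habituation_scores(
        pp$epochs,
        age_point = a, subject_id = row$subject_id
      ) %>% mutate(cohort = row$cohort, age_point = a)
      if (progress) {
        inform(sprintf("processed %s %s", row$subject_id, a))
      }
    }
  }
  measures <- bind_rows(measures)
  habituation <- bind_rows(habs)
  qc <- bind_rows(qcs)
  markers <- delta_p3(measures) %>%
    left_join(
      select(
        cohort$subjects, "subject_id", "cohort", "outcome",
        dplyr::starts_with("true_"), dplyr::matches("^(waz|laz|hcz|wlz|d_)")
      ),
      by = "subject_id"
    )
  list(measures = measures, habituation = habituation, qc = qc, markers = markers)
}

#' Fast table-level cohort simulator
#'
#' Generates the marker table directly, without synthesizing EEG: true
#' delta-P3 per subject from the preset (between-subject SD as in
#' [cohort_truth()]), a measured delta-P3 equal to the true value plus
#' measurement error, covariates and the coupled outcome. Used for
#' statistical calibration studies where thousands of replicates are needed.
#'
#' @param truth A [cohort_truth()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param measurement_sd SD of the measurement error added to the true
#'   delta-P3, default 1 microvolt.
#' @return Tibble: `subject_id`, `cohort`, `true_delta_p3`, `delta_uv`,
#'   anthropometric z columns, `outcome`.
#' @export
simulate_marker_table <- function(truth, n, seed = 1L, measurement_sd = 1) {
  stopifnot(inherits(truth, "cohort_truth"), n >= 2)
  d1 <- truth$p3_amplitude$`1m`["Infrequent"] - truth$p3_amplitude$`1m`["TrialUnique"]
  d5 <- truth$p3_amplitude$`5m`["Infrequent"] - truth$p3_amplitude$`5m`["TrialUnique"]
  mean_delta <- unname(d1 - d5)
  sd_delta <- 2 * truth$amplitude_subject_sd
  withr::with_seed(seed, {
    true_delta <- rnorm(n, mean_delta, sd_delta)
    delta_uv <- true_delta + rnorm(n, 0, measurement_sd)
    outcome <- truth$outcome_mean + truth$delta_p3_outcome_slope * true_delta +
      rnorm(n, 0, truth$outcome_sd)
    anthro <- draw_anthro_matrix(truth, n)
  })
  bind_cols(
    tibble(
      subject_id = sprintf("%s_%03d", truth$preset, seq_len(n)),
      cohort = truth$preset,
      true_delta_p3 = true_delta, delta_uv = delta_uv, outcome = outcome
    ),
    anthro
  )
}
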