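#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run — cohort sizes, session design,
#' preprocessing parameters, seeds for each stochastic stage — into one
#' object that round-trips losslessly through YAML.
#'
#' @param n_per_cohort Subjects per cohort.
#' @param cohorts Character vector of [cohort_truth()] presets to simulate.
#' @param seed Master seed; sequence/signal/equalization seeds derive from it.
#' @param design List of [oddball_design()] arguments (or an
#'   `oddball_design`).
#' @param preprocess List of [preprocess_config()] arguments (or a
#'   `preprocess_config`).
#' @param noise_sd_uv,drift_amplitude_uv,artifact_epoch_fraction Signal-level
#'   generator parameters.
#' @return A `run_config` object.
#' @examples
#' cfg <- run_config(n_per_cohort = 2, design = list(
#'   n_frequent = 40, n_infrequent = 10, n_trial_unique = 10
#' ))
#' @export
run_config <- function(n_per_cohort = 20,
                       cohorts = c("UK", "Gambia"),
                       seed = 1L,
                       design = list(),
                       preprocess = list(),
                       noise_sd_uv = 20,
                       drift_amplitude_uv = 50,
                       artifact_epoch_fraction = 0.35) {
  if (n_per_cohort < 1) {
    abort("n_per_cohort must be at least 1 (and at least 2 for marker statistics).",
      class = "oddballerp_config_error"
    )
  }
  design <- if (inherits(design, "oddball_design")) design else do.call(oddball_design, design)
  preprocess <- if (inherits(preprocess, "preprocess_config")) {
    preprocess
  } else {
    do.call(preprocess_config, preprocess)
  }
  structure(
    list(
      n_per_cohort = as.integer(n_per_cohort), cohorts = cohorts,
      seed = as.integer(seed), design = design, preprocess = preprocess,
      noise_sd_uv = noise_sd_uv, drift_amplitude_uv = drift_amplitude_uv,
      artifact_epoch_fraction = artifact_epoch_fraction
    ),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    n_per_cohort = y$n_per_cohort %||% 20,
    cohorts = unlist(y$cohorts) %||% c("UK", "Gambia"),
    seed = y$seed %||% 1L,
    design = y$design %||% list(),
    preprocess = y$preprocess %||% list(),
    noise_sd_uv = y$noise_sd_uv %||% 20,
    drift_amplitude_uv = y$drift_amplitude_uv %||% 50,
    artifact_epoch_fraction = y$artifact_epoch_fraction %||% 0.35
  )
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- list(
    n_per_cohort = cfg$n_per_cohort, cohorts = as.list(cfg$cohorts),
    seed = cfg$seed,
    design = unclass(cfg$design), preprocess = unclass(cfg$preprocess),
    noise_sd_uv = cfg$noise_sd_uv, drift_amplitude_uv = cfg$drift_amplitude_uv,
    artifact_epoch_fraction = cfg$artifact_epoch_fraction
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the end-to-end pipeline and write a report bundle
#'
#' Simulates the configured cohorts, preprocesses every session, measures
#' components and markers, runs the statistical layer (repeated-measures
#' ANOVA of P3 amplitude by Condition x Age x Cohort, habituation ANOVA,
#' per-cohort delta-P3/outcome correlations with Fisher comparison, both
#' hierarchical regression models with FDR-corrected growth p-values), and
#' writes tidy TSV tables, JSON results and a provenance log to `out_dir`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @return List with `measures`, `habituation`, `qc`, `markers`, `stats` and
#'   `files` (paths written).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$n_per_cohort < 2) {
    abort("Marker statistics need n_per_cohort >= 2.", class = "oddballerp_config_error")
  }
  truths <- lapply(cfg$cohorts, cohort_truth)
  cohort <- generate_cohort(truths,
    n_per_cohort = cfg$n_per_cohort, seed = cfg$seed, design = cfg$design,
    noise_sd_uv = cfg$noise_sd_uv, drift_amplitude_uv = cfg$drift_amplitude_uv,
    artifact_epoch_fraction = cfg$artifact_epoch_fraction
  )
  res <- run_cohort_pipeline(cohort, cfg$preprocess)
  res$stats <- pipeline_stats(res)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(x, name) {
      p <- file.path(out_dir, name)
      readr::write_tsv(x, p)
      p
    }
    files <- c(
      measures = tsv(res$measures, "measures.tsv"),
      habituation = tsv(res$habituation, "habituation.tsv"),
      markers = tsv(
        select(res$markers, -dplyr::any_of(c("spec_1m", "spec_5m"))),
        "markers.tsv"
      ),
      qc = tsv(res$qc, "qc.tsv")
    )
    stats_path <- file.path(out_dir, "stats.json")
    jsonlite::write_json(res$stats, stats_path, auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(cfg, cfg_path)
    prov <- list(
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = cfg$seed,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("oddballerp")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    prov_path <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(prov, prov_path, auto_unbox = TRUE)
    files <- c(files, stats = stats_path, config = cfg_path, provenance = prov_path)
  }
  res$files <- files
  invisible(res)
}

# The statistical layer run over pipeline output tables.
pipeline_stats <- function(res) {
  out <- list()
  p3 <- filter(res$measures, .data$component == "P3")
  two_cohorts <- length(unique(p3$cohort)) == 2
  complete <- p3 %>%
    group_by(.data$subject_id) %>%
    filter(dplyr::n() == 6) %>%
    ungroup()
  if (length(unique(complete$subject_id)) >= 4) {
    out$p3_anova <- rm_anova(
      complete, "mean_amp_uv",
      within = c("condition", "age_point"),
      between = if (two_cohorts) "cohort" else NULL
    )
  }
  hab <- filter(res$habituation, .data$defined)
  hab_complete <- hab %>%
    group_by(.data$subject_id) %>%
    filter(dplyr::n() == 6) %>%
    ungroup()
  if (length(unique(hab_complete$subject_id)) >= 4) {
    out$habituation_anova <- rm_anova(
      hab_complete, "score_uv",
      within = c("condition", "age_point"),
      between = if (two_cohorts) "cohort" else NULL
    )
  }
  mk <- res$markers
  if (two_cohorts && all(table(mk$cohort) >= 4)) {
    cc <- correlate_and_compare(mk, "delta_uv", "outcome", "cohort")
    out$delta_p3_outcome <- cc$by_group
    out$correlation_comparison <- cc$comparison
  }
  for (m in 1:2) {
    fit <- try(hierarchical_regression(mk, model = m), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      out[[paste0("model", m)]] <- list(
        glance = glance(fit), coefficients = fit$coefficients,
        screening = fit$screening
      )
    }
  }
  # FDR over the growth-predictor p-values of the two models
  if (!is.null(out$model1) && !is.null(out$model2)) {
    p_growth <- c(
      out$model1$coefficients$p_value[out$model1$coefficients$term == out$model1$glance$selected],
      out$model2$coefficients$p_value[out$model2$coefficients$term == out$model2$glance$selected]
    )
    out$growth_p_fdr <- fdr_correct(p_growth)
  }
  out
}
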