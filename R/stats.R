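#' Repeated-measures mixed ANOVA with partial eta squared
#'
#' Fits a balanced repeated-measures ANOVA with up to two within-subject
#' factors and one between-subject factor via `stats::aov` with `Error()`
#' strata, and reports F, degrees of freedom, p and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)` within each effect's stratum) for
#' every main effect and interaction. Degrees of freedom are uncorrected
#' (sphericity assumed) by default; a Greenhouse–Geisser correction of the
#' p-values is available for designs with one within factor.
#'
#' @param data Long tibble with one row per subject and within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns (1 or 2).
#' @param between Optional between-subject factor column.
#' @param subject Subject identifier column, default `"subject_id"`.
#' @param sphericity `"none"` (default, matching integer-df reporting) or
#'   `"greenhouse-geisser"`.
#' @return Tibble: `effect`, `df1`, `df2`, `statistic`, `p_value`,
#'   `partial_eta_sq` (plus `gg_epsilon` when corrected).
#' @examples
#' d <- tidyr::expand_grid(subject_id = paste0("s", 1:8), condition = c("A", "B", "C"))
#' d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", within = "condition")
#' @export
rm_anova <- function(data, dv, within, between = NULL, subject = "subject_id",
                     sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  stopifnot(length(within) >= 1, length(within) <= 2)
  d <- as.data.frame(data)
  d$.subject <- factor(d[[subject]])
  for (f in c(within, between)) d[[f]] <- factor(d[[f]])
  d$.dv <- d[[dv]]

  # balance check: every subject must have every within-cell exactly once
  cells <- interaction(d[, within, drop = FALSE], drop = FALSE)
  tab <- table(d$.subject, cells)
  bad <- rownames(tab)[apply(tab != 1, 1, any)]
  if (length(bad) > 0) {
    abort(paste0(
      "Incomplete within-subject cells for subject(s): ",
      paste(bad, collapse = ", ")
    ), class = "oddballerp_balance_error")
  }

  w_term <- paste(within, collapse = "*")
  rhs <- if (is.null(between)) w_term else paste(between, "*", w_term)
  fml <- stats::as.formula(paste0(
    ".dv ~ ", rhs, " + Error(.subject/(", w_term, "))"
  ))
  fit <- aov(fml, data = d)
  # constant input up to rounding: every effect is exactly null
  degenerate <- var(d$.dv) < 1e-18 * (mean(d$.dv)^2 + 1)
  out <- purrr::map_dfr(summary(fit), function(stratum) {
    st <- stratum[[1]]
    terms <- rownames(st)
    resid_row <- grepl("Residuals", terms)
    if (!any(resid_row)) {
      return(tibble())
    }
    ss_err <- st[resid_row, "Sum Sq"]
    df_err <- st[resid_row, "Df"]
    eff <- which(!resid_row)
    purrr::map_dfr(eff, function(i) {
      ss <- st[i, "Sum Sq"]
      f <- st[i, "F value"]
      p <- st[i, "Pr(>F)"]
      if (!is.finite(f) || degenerate) {
        f <- 0
        p <- 1
      }
      tibble(
        effect = trimws(terms[i]),
        df1 = st[i, "Df"], df2 = df_err,
        statistic = f, p_value = p,
        partial_eta_sq = if (!degenerate && ss + ss_err > 0) ss / (ss + ss_err) else 0
      )
    })
  })
  if (sphericity == "greenhouse-geisser" && length(within) == 1) {
    eps <- gg_epsilon(d, within, subject = ".subject")
    out <- out %>% mutate(
      gg_epsilon = ifelse(grepl(within, .data$effect), eps, NA_real_),
      p_value = ifelse(
        grepl(within, .data$effect),
        pf(.data$statistic, .data$df1 * eps, .data$df2 * eps, lower.tail = FALSE),
        .data$p_value
      )
    )
  }
  out
}

# Greenhouse-Geisser epsilon from the within-cell covariance matrix
# (box correction; subjects x cells, cells averaged over any between groups).
gg_epsilon <- function(d, within, subject = ".subject") {
  wide <- tapply(d$.dv, list(d[[subject]], d[[within]]), mean)
  S <- stats::cov(wide)
  k <- ncol(S)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)` — the standard reconstruction from a reported
#' F and its degrees of freedom.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in `[0, 1]`.
#' @examples
#' pes_from_f(31.145, 2, 334)
#' @export
pes_from_f <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Paired contrast with Cohen's d
#'
#' Paired t test (two-sided) with Cohen's d computed as the mean difference
#' divided by the standard deviation of the differences.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return One-row tibble: `statistic` (t), `df`, `p_value`, `cohen_d`,
#'   `mean_diff`, `n`, `degenerate` (flag for zero difference variance with
#'   nonzero mean, where t is infinite).
#' @examples
#' paired_contrast(rnorm(10), rnorm(10))
#' @export
paired_contrast <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  n <- length(d)
  sd_d <- sd(d)
  if (sd_d < 1e-10 * (abs(mean(d)) + 1)) { # constant differences up to rounding
    degenerate <- mean(d) != 0
    if (degenerate) warn("Zero variance of differences with nonzero mean: t is infinite.")
    return(tibble(
      statistic = if (degenerate) Inf * sign(mean(d)) else 0,
      df = n - 1, p_value = if (degenerate) 0 else 1,
      cohen_d = if (degenerate) Inf * sign(mean(d)) else 0,
      mean_diff = mean(d), n = n, degenerate = degenerate
    ))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, cohen_d = mean(d) / sd_d,
    mean_diff = mean(d), n = n, degenerate = FALSE
  )
}

#' Per-group correlations and Fisher r-to-z comparison
#'
#' Pearson correlation of `x` and `y` within each group, then a comparison of
#' the two groups' coefficients through the Fisher transform:
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`. Both the one-sided and the
#' two-sided p-value of the comparison are reported.
#'
#' @param data Tibble with the variables.
#' @param x,y Column names of the two variables.
#' @param group Column name of the two-level grouping factor.
#' @return List with `by_group` (tibble: group, n, r, p_value) and
#'   `comparison` (tibble: z, p_one_sided, p_two_sided).
#' @examples
#' d <- tibble::tibble(
#'   g = rep(c("a", "b"), each = 30),
#'   x = rnorm(60), y = rnorm(60)
#' )
#' correlate_and_compare(d, "x", "y", "g")
#' @export
correlate_and_compare <- function(data, x, y, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group must have exactly two levels.")
  by_group <- purrr::map_dfr(levels(g), function(lev) {
    xi <- data[[x]][g == lev]
    yi <- data[[y]][g == lev]
    if (length(xi) < 4) abort("Each group needs at least 4 pairs.")
    if (sd(xi) == 0 || sd(yi) == 0) {
      warn(sprintf("Constant input in group %s: correlation undefined.", lev))
      return(tibble(group = lev, n = length(xi), r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(xi, yi)
    tibble(group = lev, n = length(xi), r = unname(ct$estimate), p_value = ct$p.value)
  })
  z1 <- atanh(by_group$r[1])
  z2 <- atanh(by_group$r[2])
  zstat <- (z1 - z2) / sqrt(1 / (by_group$n[1] - 3) + 1 / (by_group$n[2] - 3))
  comparison <- tibble(
    z = zstat,
    p_one_sided = pnorm(abs(zstat), lower.tail = FALSE),
    p_two_sided = 2 * pnorm(abs(zstat), lower.tail = FALSE)
  )
  list(by_group = by_group, comparison = comparison)
}

#' Hierarchical regression of outcome on growth then delta-P3
#'
#' Reproduces the two-step modelling of the outcome composite score. A
#' univariate screening step first fits each candidate growth predictor alone
#' and selects the one with the lowest univariate p (ties broken
#' alphabetically). The base model regresses the outcome on the selected
#' growth predictor; the full model adds the delta-P3 marker, and the
#' R-squared change is tested with the incremental F test. Model 1 screens
#' measures of infant size at 5 months (`waz_5m`, `laz_5m`); Model 2 screens
#' growth between the age points (`d_waz`, `d_laz`, `d_wlz`, `d_hcz`).
#' Candidate predictors correlated above |r| = 0.9 trigger a collinearity
#' warning.
#'
#' @param data Marker table with the outcome, candidate predictors and the
#'   marker column.
#' @param model 1 or 2, or a character vector of candidate columns.
#' @param outcome Outcome column, default `"outcome"`.
#' @param marker Marker column, default `"delta_uv"`.
#' @return A `hier_reg` object: screening table, selected predictor, base and
#'   full `lm` fits, coefficient table, `r2_null`, `r2_change` and its F test.
#'   `tidy()` and `glance()` methods are provided.
#' @export
hierarchical_regression <- function(data, model = 1, outcome = "outcome",
                                    marker = "delta_uv") {
  candidates <- if (is.character(model)) {
    model
  } else if (identical(as.integer(model), 1L)) {
    c("waz_5m", "laz_5m")
  } else if (identical(as.integer(model), 2L)) {
    c("d_waz", "d_laz", "d_wlz", "d_hcz")
  } else {
    abort("model must be 1, 2 or a character vector of candidate columns.")
  }
  missing_cols <- setdiff(c(outcome, marker, candidates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  d <- as.data.frame(data[stats::complete.cases(data[c(outcome, marker, candidates)]), ])

  if (length(candidates) > 1) {
    cm <- cor(d[candidates])
    high <- abs(cm[upper.tri(cm)]) > 0.9
    if (any(high)) {
      warn("Candidate predictors are collinear (|r| > 0.9); they are screened univariately.")
    }
  }
  screening <- purrr::map_dfr(candidates, function(v) {
    fit <- lm(stats::reformulate(v, outcome), data = d)
    cf <- summary(fit)$coefficients
    tibble(
      predictor = v, statistic = cf[v, "t value"],
      p_value = cf[v, "Pr(>|t|)"], r_squared = summary(fit)$r.squared
    )
  }) %>% arrange(.data$p_value, .data$predictor)
  selected <- screening$predictor[1]

  base_fit <- lm(stats::reformulate(selected, outcome), data = d)
  full_fit <- lm(stats::reformulate(c(selected, marker), outcome), data = d)
  r2_null <- summary(base_fit)$r.squared
  r2_full <- summary(full_fit)$r.squared
  cmp <- anova(base_fit, full_fit)
  cf <- summary(full_fit)$coefficients
  coef_tbl <- tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"], statistic = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
  structure(
    list(
      model = if (is.character(model)) "custom" else paste0("Model ", model),
      screening = screening, selected = selected,
      base_fit = base_fit, full_fit = full_fit,
      coefficients = coef_tbl,
      r2_null = r2_null, r2_full = r2_full,
      r2_change = r2_full - r2_null,
      f_change = cmp$F[2], df1_change = cmp$Df[2], df2_change = cmp$Res.Df[2],
      p_change = cmp$`Pr(>F)`[2],
      n = nrow(d), marker = marker
    ),
    class = "hier_reg"
  )
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf(
    "<hier_reg> %s: %s -> + %s (n = %d)\n  R2 null = %.3f, R2 change = %.3f (F(%d, %d) = %.3f, p = %.4g)\n",
    x$model, x$selected, x$marker, x$n, x$r2_null, x$r2_change,
    x$df1_change, x$df2_change, x$f_change, x$p_change
  ))
  invisible(x)
}

#' @export
tidy.hier_reg <- function(x, ...) x$coefficients

#' @export
glance.hier_reg <- function(x, ...) {
  tibble(
    model = x$model, selected = x$selected, n = x$n,
    r2_null = x$r2_null, r2_full = x$r2_full, r2_change = x$r2_change,
    f_change = x$f_change, p_change = x$p_change
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values via `stats::p.adjust(method = "BH")`; monotone
#' and bounded by 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_correct <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Match awake subjects to asleep subjects by good-trial counts
#'
#' Greedy nearest-count matching: each asleep subject is paired with the
#' unused awake subject whose kept-trial count is nearest and within the
#' tolerance; subjects with no admissible partner remain unmatched.
#'
#' @param asleep Tibble with `subject_id` and `n_trials` for the asleep group.
#' @param awake Tibble with `subject_id` and `n_trials` for the awake pool.
#' @param tolerance Maximum absolute count difference, default 5.
#' @return List with `matches` (asleep_id, awake_id, n_asleep, n_awake) and
#'   `unmatched` (asleep subject ids).
#' @examples
#' match_by_trial_count(
#'   tibble::tibble(subject_id = c("a1", "a2", "a3"), n_trials = c(50, 57, 62)),
#'   tibble::tibble(subject_id = c("w1", "w2", "w3"), n_trials = c(48, 90, 55))
#' )
#' @export
match_by_trial_count <- function(asleep, awake, tolerance = 5) {
  used <- rep(FALSE, nrow(awake))
  matches <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(asleep))) {
    diffs <- abs(awake$n_trials - asleep$n_trials[i])
    diffs[used] <- Inf
    j <- which.min(diffs)
    if (length(j) == 1 && is.finite(diffs[j]) && diffs[j] <= tolerance) {
      used[j] <- TRUE
      matches[[length(matches) + 1]] <- tibble(
        asleep_id = asleep$subject_id[i], awake_id = awake$subject_id[j],
        n_asleep = asleep$n_trials[i], n_awake = awake$n_trials[j]
      )
    } else {
      unmatched <- c(unmatched, asleep$subject_id[i])
    }
  }
  list(
    matches = if (length(matches)) bind_rows(matches) else
      tibble(asleep_id = character(), awake_id = character(),
             n_asleep = integer(), n_awake = integer()),
    unmatched = unmatched
  )
}

#' Condition-by-state check on P3 amplitudes
#'
#' Compares asleep- and awake-tested subjects after matching on good-trial
#' counts, then models P3 mean amplitude by Condition (within) and State
#' (between) in a repeated-measures mixed ANOVA.
#'
#' @param asleep_measures,awake_measures Tidy measure tables (one row per
#'   subject x condition) with columns `subject_id`, `condition`,
#'   `mean_amp_uv`, `n_epochs`.
#' @param tolerance Trial-count matching tolerance, default 5.
#' @return List with `matching` (from [match_by_trial_count()]) and `anova`
#'   (tibble with Condition, State and Condition:State effects).
#' @export
state_effect_check <- function(asleep_measures, awake_measures, tolerance = 5) {
  counts <- function(m) {
    m %>%
      group_by(subject_id = .data$subject_id) %>%
      summarise(n_trials = .data$n_epochs[1], .groups = "drop")
  }
  matching <- match_by_trial_count(counts(asleep_measures), counts(awake_measures), tolerance)
  if (nrow(matching$matches) < 2) {
    abort("Fewer than 2 matched pairs; state comparison is not possible.",
      class = "oddballerp_config_error"
    )
  }
  keep_asleep <- asleep_measures %>%
    filter(.data$subject_id %in% matching$matches$asleep_id) %>%
    mutate(state = "asleep")
  keep_awake <- awake_measures %>%
    filter(.data$subject_id %in% matching$matches$awake_id) %>%
    mutate(state = "awake")
  d <- bind_rows(keep_asleep, keep_awake)
  an <- rm_anova(d, "mean_amp_uv", within = "condition", between = "state")
  list(matching = matching, anova = an)
}
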