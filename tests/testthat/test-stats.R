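null_table <- function(n_subj, within_levels = 3, between = NULL, seed = 1) {
  d <- tidyr::expand_grid(
    subject_id = sprintf("s%03d", seq_len(n_subj)),
    condition = paste0("c", seq_len(within_levels))
  )
  if (!is.null(between)) {
    grp <- rep(between, length.out = n_subj)
    d$cohort <- grp[match(d$subject_id, sprintf("s%03d", seq_len(n_subj)))]
  }
  withr::with_seed(seed, {
    subj_eff <- rnorm(n_subj, 0, 1)
    d$y <- subj_eff[match(d$subject_id, unique(d$subject_id))] + rnorm(nrow(d))
  })
  d
}

test_that("degenerate all-equal data give zero F throughout", {
  d <- null_table(8)
  d$y <- 5
  an <- rm_anova(d, "y", within = "condition")
  expect_true(all(an$statistic == 0))
  expect_true(all(an$p_value == 1))
})

test_that("two-level within ANOVA F equals the squared paired t", {
  d <- null_table(12, within_levels = 2, seed = 3)
  an <- rm_anova(d, "y", within = "condition")
  wide <- tidyr::pivot_wider(d, names_from = condition, values_from = y)
  tt <- t.test(wide$c1, wide$c2, paired = TRUE)
  eff <- an[an$effect == "condition", ]
  expect_equal(eff$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(eff$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("partial eta squared reproduces F via the df identity on every effect", {
  d <- null_table(10, within_levels = 3, between = c("UK", "Gambia"), seed = 5)
  d$age_point <- NULL
  an <- rm_anova(d, "y", within = "condition", between = "cohort")
  expect_equal(
    an$partial_eta_sq,
    pes_from_f(an$statistic, an$df1, an$df2),
    tolerance = 1e-10
  )
  # reconstruction from a reported F and its degrees of freedom
  expect_equal(pes_from_f(31.145, 2, 334), 0.157, tolerance = 0.002)
})

test_that("the full Condition x Age x Cohort decomposition is reported", {
  d <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:12),
    condition = c("Frequent", "Infrequent", "TrialUnique"),
    age_point = c("1m", "5m")
  )
  d$cohort <- ifelse(d$subject_id <= "s06", "UK", "Gambia")
  withr::with_seed(8, d$y <- rnorm(nrow(d)))
  an <- rm_anova(d, "y", within = c("condition", "age_point"), between = "cohort")
  expect_setequal(
    an$effect,
    c(
      "cohort", "condition", "cohort:condition", "age_point",
      "cohort:age_point", "condition:age_point", "cohort:condition:age_point"
    )
  )
  # within-effect dfs match the design (2, 1, 2 numerator; subject strata denominators)
  expect_equal(an$df1[an$effect == "condition"], 2)
  expect_equal(an$df2[an$effect == "condition"], 20)
  expect_equal(an$df1[an$effect == "cohort:condition:age_point"], 2)
})

test_that("missing within-subject cells raise an error naming the subject", {
  d <- null_table(6)
  d <- d[-4, ]
  expect_error(rm_anova(d, "y", within = "condition"),
    class = "oddballerp_balance_error", regexp = "s002"
  )
})

test_that("paired contrasts match the textbook formulas", {
  withr::with_seed(4, {
    a <- rnorm(20, 1)
    b <- rnorm(20)
  })
  res <- paired_contrast(a, b)
  d <- a - b
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-12)
  expect_equal(res$cohen_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(res$statistic), 19), tolerance = 1e-12)
  # identical vectors: t = 0, d = 0
  res0 <- paired_contrast(a, a)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$cohen_d, 0)
  # zero-variance nonzero difference flags an infinite t
  expect_warning(res_inf <- paired_contrast(a + 1, a), "infinite")
  expect_true(res_inf$degenerate)
  expect_equal(res_inf$statistic, Inf)
})

test_that("per-group correlations and the Fisher comparison match closed forms", {
  withr::with_seed(6, {
    d <- tibble::tibble(
      g = rep(c("a", "b"), c(30, 50)),
      x = rnorm(80)
    )
    d$y <- 0.4 * d$x + rnorm(80)
  })
  res <- correlate_and_compare(d, "x", "y", "g")
  r1 <- cor(d$x[d$g == "a"], d$y[d$g == "a"])
  expect_equal(res$by_group$r[1], r1, tolerance = 1e-12)
  z_hand <- (atanh(res$by_group$r[1]) - atanh(res$by_group$r[2])) /
    sqrt(1 / (30 - 3) + 1 / (50 - 3))
  expect_equal(res$comparison$z, z_hand, tolerance = 1e-12)
  expect_equal(res$comparison$p_two_sided, 2 * res$comparison$p_one_sided)
  # y = x gives r = 1; equal r and n give z = 0
  d2 <- tibble::tibble(g = rep(c("a", "b"), each = 10), x = rnorm(20))
  d2$y <- d2$x
  res2 <- correlate_and_compare(d2, "x", "y", "g")
  expect_equal(res2$by_group$r, c(1, 1))
  # identical groups: z = 0
  d3 <- tibble::tibble(g = rep(c("a", "b"), each = 10), x = c(rnorm(10), rnorm(10)))
  d3$x <- rep(d3$x[1:10], 2)
  d3$y <- d3$x^2 + rep(rnorm(10), 2)
  res3 <- correlate_and_compare(d3, "x", "y", "g")
  expect_equal(res3$comparison$z, 0, tolerance = 1e-12)
})

test_that("hand-worked Fisher comparison: r .5 (n 30) vs .2 (n 50)", {
  # closed-form arithmetic, no simulation
  z <- (atanh(0.5) - atanh(0.2)) / sqrt(1 / 27 + 1 / 47)
  make_xy <- function(r, n, seed) {
    withr::with_seed(seed, {
      x <- rnorm(n)
      y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(rnorm(n))[, 1]
    })
    list(x = x, y = y)
  }
  # verify against the package on data constructed to have those sample r
  g1 <- make_xy(0.5, 30, 1)
  g2 <- make_xy(0.2, 50, 2)
  # force exact sample correlations by orthogonalization
  exactify <- function(x, y, r) {
    e <- stats::residuals(lm(y ~ x)) # orthogonal to x by construction
    r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  }
  y1 <- exactify(g1$x, g1$y, 0.5)
  y2 <- exactify(g2$x, g2$y, 0.2)
  d <- tibble::tibble(
    g = rep(c("a", "b"), c(30, 50)),
    x = c(g1$x, g2$x), y = c(y1, y2)
  )
  res <- correlate_and_compare(d, "x", "y", "g")
  expect_equal(res$by_group$r, c(0.5, 0.2), tolerance = 1e-10)
  expect_equal(res$comparison$z, z, tolerance = 1e-10)
})

test_that("hierarchical regression screens candidates and tests the R2 change", {
  withr::with_seed(10, {
    n <- 100
    d <- tibble::tibble(
      waz_5m = rnorm(n), laz_5m = rnorm(n),
      delta_uv = rnorm(n, 0, 3)
    )
    d$outcome <- 95 + 0.3 * d$laz_5m + 1.2 * d$delta_uv + rnorm(n, 0, 10)
  })
  fit <- hierarchical_regression(d, model = 1)
  # screening picks the lower univariate p
  p_waz <- summary(lm(outcome ~ waz_5m, d))$coefficients["waz_5m", 4]
  p_laz <- summary(lm(outcome ~ laz_5m, d))$coefficients["laz_5m", 4]
  expect_equal(fit$selected, if (p_laz <= p_waz) "laz_5m" else "waz_5m")
  # R2 change agrees with the two lm fits and the incremental F test
  base <- lm(stats::reformulate(fit$selected, "outcome"), d)
  full <- lm(stats::reformulate(c(fit$selected, "delta_uv"), "outcome"), d)
  expect_equal(fit$r2_change,
    summary(full)$r.squared - summary(base)$r.squared,
    tolerance = 1e-12
  )
  cmp <- anova(base, full)
  expect_equal(fit$f_change, cmp$F[2], tolerance = 1e-12)
  expect_equal(fit$p_change, cmp$`Pr(>F)`[2], tolerance = 1e-12)
  gl <- glance(fit)
  expect_true(all(c("r2_null", "r2_change", "p_change") %in% names(gl)))
})

test_that("regression coefficients match the normal-equation solution on 10 rows", {
  withr::with_seed(11, {
    d <- tibble::tibble(
      waz_5m = rnorm(10), laz_5m = rnorm(10), delta_uv = rnorm(10),
      outcome = rnorm(10, 95, 10)
    )
  })
  fit <- hierarchical_regression(d, model = 1)
  X <- cbind(1, d[[fit$selected]], d$delta_uv)
  beta <- solve(t(X) %*% X, t(X) %*% d$outcome)
  expect_equal(unname(coef(fit$full_fit)), as.numeric(beta), tolerance = 1e-10)
})

test_that("collinear candidate predictors trigger a warning", {
  withr::with_seed(12, {
    d <- tibble::tibble(waz_5m = rnorm(50))
    d$laz_5m <- d$waz_5m + rnorm(50, 0, 0.1)
    d$delta_uv <- rnorm(50)
    d$outcome <- rnorm(50, 95, 10)
  })
  expect_gt(cor(d$waz_5m, d$laz_5m), 0.9)
  expect_warning(hierarchical_regression(d, model = 1), "collinear")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.2), 0.2) # single p unchanged
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  # monotone non-decreasing in raw-p order
  withr::with_seed(13, p <- runif(20))
  adj <- fdr_correct(p)
  o <- order(p)
  expect_true(!is.unsorted(adj[o]))
  expect_true(all(adj <= 1))
  expect_error(fdr_correct(c(0.5, 1.2)))
})

test_that("trial-count matching is greedy-nearest within tolerance", {
  res <- match_by_trial_count(
    tibble::tibble(subject_id = c("a1", "a2", "a3"), n_trials = c(50, 57, 62)),
    tibble::tibble(subject_id = c("w1", "w2", "w3"), n_trials = c(48, 90, 55))
  )
  expect_equal(res$matches$asleep_id, c("a1", "a2"))
  expect_equal(res$matches$awake_id, c("w1", "w3"))
  expect_equal(res$unmatched, "a3")
  # brute-force oracle: every reported match is admissible and nearest among unused
  used <- character(0)
  for (k in seq_len(nrow(res$matches))) {
    m <- res$matches[k, ]
    expect_lte(abs(m$n_asleep - m$n_awake), 5)
    pool <- c(48, 90, 55)
    names(pool) <- c("w1", "w2", "w3")
    pool <- pool[setdiff(names(pool), used)]
    expect_equal(unname(abs(pool[m$awake_id] - m$n_asleep)), min(abs(pool - m$n_asleep)))
    used <- c(used, m$awake_id)
  }
})

test_that("state check detects amplitude scaling but keeps the interaction null", {
  make_measures <- function(ids, scale, seed) {
    base <- c(Frequent = 4, Infrequent = 9, TrialUnique = 5)
    withr::with_seed(seed, {
      purrr::map_dfr(ids, function(s) {
        tibble::tibble(
          subject_id = s, condition = names(base),
          mean_amp_uv = scale * (base + rnorm(3, 0, 0.8)) + rnorm(1, 0, 0.5),
          n_epochs = sample(45:55, 1)
        )
      })
    })
  }
  asleep <- make_measures(paste0("sl", 1:10), scale = 0.7, seed = 21)
  awake <- make_measures(paste0("aw", 1:12), scale = 1.0, seed = 22)
  res <- state_effect_check(asleep, awake)
  expect_gte(nrow(res$matching$matches), 8)
  an <- res$anova
  expect_true(all(c("state", "condition", "state:condition") %in% an$effect))
  # the scaling produces a state effect; identical groups would not
  res_same <- state_effect_check(asleep, dplyr::mutate(asleep,
    subject_id = paste0("x", subject_id)
  ))
  an_same <- res_same$anova
  expect_lt(an_same$statistic[an_same$effect == "state"], 1e-10)
})
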