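make_rec <- function(signal, fs = 500, events = NULL) {
  # bare recording wrapper for filter unit tests
  structure(
    list(
      signal = signal, sample_rate_hz = fs,
      channel_names = c("Fz", "FC1", "FC2", "C1", "Cz", "C2", "CP1", "CP2"),
      reference = "left mastoid",
      events = events %||% tibble::tibble(
        trial = integer(), condition = factor(character(),
          levels = c("Frequent", "Infrequent", "TrialUnique")
        ),
        ordinal = integer(), stimulus_id = character(),
        onset_s = numeric(), onset_sample = integer(), isi_ms = numeric()
      ),
      subject = NULL, artifact_trials = integer(0)
    ),
    class = "erp_recording"
  )
}

sine_mat <- function(freq, fs = 500, dur_s = 60) {
  tt <- (0:(dur_s * fs - 1)) / fs
  matrix(rep(sin(2 * pi * freq * tt), 8), ncol = 8)
}

fitted_amplitude <- function(x, freq, fs = 500) {
  tt <- (seq_along(x) - 1) / fs
  fit <- lm(x ~ sin(2 * pi * freq * tt) + cos(2 * pi * freq * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("band-pass filter passes 10 Hz nearly unchanged and kills slow drift", {
  cfg <- preprocess_config()
  rec10 <- make_rec(sine_mat(10))
  out10 <- bandpass_filter(rec10, cfg)
  mid <- 10000:20000
  amp10 <- fitted_amplitude(out10$signal[mid, 1], 10)
  expect_gt(amp10, 0.95) # < 5% passband attenuation

  rec_slow <- make_rec(sine_mat(0.05, dur_s = 120))
  out_slow <- bandpass_filter(rec_slow, cfg)
  mid2 <- 20000:40000
  amp_slow <- fitted_amplitude(out_slow$signal[mid2, 1], 0.05)
  expect_lt(amp_slow, 0.1) # > 90% stopband attenuation
  # realized attenuation matches the designed magnitude response within 1%
  designed <- filter_response(cfg, 500, 0.05)
  expect_lt(abs(amp_slow - designed), 0.01)
})

test_that("zero-phase filtering leaves a step symmetric about its edge", {
  n <- 20000
  x <- c(rep(0, n / 2), rep(1, n / 2))
  rec <- make_rec(matrix(rep(x, 8), ncol = 8))
  out <- bandpass_filter(rec, preprocess_config())
  y <- out$signal[, 1]
  # y minus its own value mirrored about the step midpoint is antisymmetric
  k <- 2000
  left <- y[(n / 2) - (1:k) + 1]
  right <- y[(n / 2) + (1:k)]
  expect_equal(left + right, rep(left[1] + right[1], k), tolerance = 1e-6)
})

test_that("recordings shorter than the filter kernel fail with the minimum length", {
  rec <- make_rec(matrix(0, 1000, 8))
  expect_error(bandpass_filter(rec, preprocess_config()),
    class = "oddballerp_length_error", regexp = "5501"
  )
})

test_that("timing offset shifts markers by the rounded sample count", {
  cfg32 <- preprocess_config(offset_ms = 32)
  ev <- tibble::tibble(onset_sample = c(100L, 200L))
  expect_equal(apply_timing_offset(ev, cfg32, 500)$onset_sample, c(116L, 216L))
  cfg0 <- preprocess_config(offset_ms = 0)
  expect_equal(apply_timing_offset(ev, cfg0, 500)$onset_sample, ev$onset_sample)
  # 3 ms at 500 Hz is 1.5 samples: rounds half away from zero to +2
  cfg3 <- preprocess_config(offset_ms = 3)
  expect_equal(apply_timing_offset(ev, cfg3, 500)$onset_sample, c(102L, 202L))
})

test_that("events shifted beyond the recording end are dropped with a warning", {
  ev <- tibble::tibble(onset_sample = c(100L, 995L))
  expect_warning(
    out <- apply_timing_offset(ev, preprocess_config(offset_ms = 32), 500, n_samples = 1000),
    "dropped"
  )
  expect_equal(out$onset_sample, 116L)
})

test_that("epochs span -200..800 ms with 501 samples at 500 Hz", {
  sq <- generate_sequence(sparse_design(2, 2, 2), seed = 1)
  rec <- synthesize_recording(clean_subject(), sq)
  es <- epoch(rec, preprocess_config(), apply_offset = FALSE)
  expect_equal(dim(es$data)[3], 501)
  expect_equal(range(es$time_ms), c(-200, 800))
  expect_equal(diff(es$time_ms)[1], 2)
})

test_that("baseline correction zeroes a constant signal", {
  sq <- generate_sequence(sparse_design(2, 2, 2), seed = 1)
  rec <- synthesize_recording(clean_subject(), sq)
  rec$signal[] <- 7.5
  es <- epoch(rec, preprocess_config(baseline_correct = TRUE), apply_offset = FALSE)
  expect_true(all(abs(es$data) < 1e-12))
})

test_that("events too close to the recording edge are excluded and counted", {
  sq <- generate_sequence(sparse_design(2, 2, 2), seed = 1)
  rec <- synthesize_recording(clean_subject(), sq)
  rec$events$onset_sample[1] <- 10L
  expect_message(
    es <- epoch(rec, preprocess_config(), apply_offset = FALSE),
    "edge"
  )
  expect_equal(es$n_dropped_edge, 1L)
  expect_equal(dim(es$data)[1], nrow(rec$events) - 1)
})

test_that("peak-to-peak and flatline rules reject with the recorded reason", {
  time_ms <- seq(-200, 800, by = 2)
  fz <- matrix(rnorm(5 * 501, sd = 5), nrow = 5)
  fz[2, 200] <- fz[2, 200] + 250 # transient on one epoch
  fz[4, ] <- 0 # flatline epoch
  es <- epochs_from_fz(fz, time_ms,
    conditions = c("Frequent", "Frequent", "Infrequent", "Infrequent", "TrialUnique")
  )
  es <- reject_artifacts(es, preprocess_config())
  expect_equal(es$info$valid, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(es$info$reason, c("none", "ptp", "none", "flatline", "none"))
})

test_that("rejection is permutation-invariant and idempotent", {
  time_ms <- seq(-200, 800, by = 2)
  set.seed(5)
  fz <- matrix(rnorm(30 * 501, sd = 40), nrow = 30)
  conds <- rep(c("Frequent", "Infrequent", "TrialUnique"), each = 10)
  es <- reject_artifacts(epochs_from_fz(fz, time_ms, conds), preprocess_config())
  perm <- sample(30)
  es_p <- reject_artifacts(
    epochs_from_fz(fz[perm, ], time_ms, conds[perm]),
    preprocess_config()
  )
  expect_equal(es_p$info$valid, es$info$valid[perm])
  # idempotence: re-running rejection changes nothing
  expect_identical(reject_artifacts(es, preprocess_config())$info, es$info)
})

test_that("equalization down-samples every condition to the minimum valid count", {
  time_ms <- seq(-200, 800, by = 2)
  n <- 80 + 23 + 61
  fz <- matrix(rnorm(n * 501, sd = 5), nrow = n)
  conds <- rep(c("Frequent", "Infrequent", "TrialUnique"), c(80, 23, 61))
  es <- reject_artifacts(epochs_from_fz(fz, time_ms, conds), preprocess_config())
  expect_true(all(es$info$valid))
  es <- equalize_trials(es, seed = 7)
  cnt <- epoch_counts(es)
  expect_equal(cnt$n_kept, rep(23L, 3))
  # kept sets are subsets of valid sets and preserve temporal order
  for (cc in levels(es$info$condition)) {
    kept <- which(es$info$kept & es$info$condition == cc)
    expect_true(all(es$info$valid[kept]))
    expect_true(!is.unsorted(es$info$ordinal[kept]))
  }
  # already-equal counts: nothing removed
  es_eq <- equalize_trials(
    reject_artifacts(
      epochs_from_fz(fz[c(1:23, 81:103, 104:126), ], time_ms,
        conds[c(1:23, 81:103, 104:126)]
      ),
      preprocess_config()
    ),
    seed = 3
  )
  expect_true(all(es_eq$info$kept))
  # determinism
  es_a <- equalize_trials(es, seed = 11)
  es_b <- equalize_trials(es, seed = 11)
  expect_identical(which(es_a$info$kept), which(es_b$info$kept))
})

test_that("a condition with zero valid trials marks the dataset unusable", {
  time_ms <- seq(-200, 800, by = 2)
  fz <- matrix(rnorm(20 * 501, sd = 5), nrow = 20)
  fz[11:20, ] <- 0 # all Infrequent epochs flatline
  conds <- rep(c("Frequent", "Infrequent"), each = 10)
  es <- reject_artifacts(epochs_from_fz(fz, time_ms, conds), preprocess_config())
  expect_warning(es <- equalize_trials(es, seed = 1), "unusable")
  expect_false(attr(es, "usable"))
  expect_true(all(!es$info$kept))
})

test_that("the inclusion boundary sits exactly at the configured trial count", {
  time_ms <- seq(-200, 800, by = 2)
  cfg <- preprocess_config()
  smallest_included <- NA
  for (m in c(1, 5, 14, 15, 16, 40)) {
    fz <- matrix(rnorm(3 * m * 501, sd = 5), nrow = 3 * m)
    conds <- rep(c("Frequent", "Infrequent", "TrialUnique"), each = m)
    es <- equalize_trials(
      reject_artifacts(epochs_from_fz(fz, time_ms, conds), cfg),
      seed = 1
    )
    inc <- inclusion_filter(es, cfg)
    expect_equal(inc$include, m >= 15)
    if (inc$include && is.na(smallest_included)) smallest_included <- m
  }
  expect_equal(smallest_included, cfg$min_trials_per_condition)
})

test_that("full preprocessing matches a straight-line reference implementation", {
  des <- small_design(sample_rate_hz = 500)
  sq <- generate_sequence(des, seed = 31)
  sub <- subject_spec("oracle", seed = 31, artifact_epoch_fraction = 0.15)
  rec <- synthesize_recording(sub, sq)
  cfg <- preprocess_config()
  pp <- preprocess_session(rec, cfg, equalize_seed = 55)

  # --- independent straight-line reference (no shared package code) ---
  fs <- 500
  h <- as.numeric(signal::fir1(5500, c(0.5, 30) / 250,
    type = "pass",
    window = signal::blackman(5501)
  ))
  n <- nrow(rec$signal)
  ref_sig <- matrix(0, n, 8)
  for (j in 1:8) {
    x <- rec$signal[, j] - mean(rec$signal[, j])
    y <- stats::convolve(x, rev(h), type = "open")
    ref_sig[, j] <- y[2750 + seq_len(n)]
  }
  onsets <- rec$events$onset_sample + 16L # 32 ms at 500 Hz
  keep <- onsets - 100 >= 1 & onsets + 400 <= n
  onsets <- onsets[keep]
  conds <- as.character(rec$events$condition)[keep]
  ne <- length(onsets)
  ref_epochs <- array(0, c(ne, 8, 501))
  for (i in seq_len(ne)) {
    seg <- ref_sig[onsets[i] + (-100:400), ]
    seg <- sweep(seg, 2, colMeans(seg[1:101, , drop = FALSE]))
    ref_epochs[i, , ] <- t(seg)
  }
  ref_valid <- logical(ne)
  for (i in seq_len(ne)) {
    ok <- TRUE
    for (j in 1:8) {
      r <- max(ref_epochs[i, j, ]) - min(ref_epochs[i, j, ])
      if (r > 200 || r < 0.1) ok <- FALSE
    }
    ref_valid[i] <- ok
  }
  m <- min(table(factor(conds, levels = levels(rec$events$condition))[ref_valid]))
  ref_kept <- logical(ne)
  withr::with_seed(55, {
    for (cc in levels(rec$events$condition)) {
      idx <- which(ref_valid & conds == cc)
      ref_kept[if (length(idx) > m) sort(sample(idx, m)) else idx] <- TRUE
    }
  })
  # --- comparison, epoch for epoch ---
  expect_equal(dim(pp$epochs$data), dim(ref_epochs))
  expect_equal(pp$epochs$data, ref_epochs, tolerance = 1e-8)
  expect_identical(pp$epochs$info$valid, ref_valid)
  expect_identical(pp$epochs$info$kept, ref_kept)
})
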