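#' Generate a randomized oddball stimulus sequence
#'
#' Produces one session's trial sequence: exactly the per-condition counts the
#' design specifies, in fully randomized order, with onset times separated by
#' stimulus duration plus an ISI drawn uniformly on the design's jitter
#' bounds. Trial Unique events carry unique stimulus identifiers (each used
#' once); Frequent and Infrequent trials reuse a single identifier each, as
#' they repeat the same physical stimulus.
#'
#' @param design An [oddball_design()].
#' @param seed Integer seed; sequences are deterministic given `design` and
#'   `seed`.
#' @param lead_in_s Silence before the first onset, seconds.
#' @return A `stimulus_sequence`: a tibble with columns `trial`, `condition`
#'   (factor Frequent/Infrequent/TrialUnique), `ordinal` (1-based presentation
#'   index within condition), `stimulus_id`, `onset_s`, `onset_sample`
#'   (1-based), `isi_ms` (interval following the trial). The design is
#'   attached as attribute `"design"`.
#' @examples
#' seq1 <- generate_sequence(oddball_design(), seed = 1)
#' table(seq1$condition)
#' @export
generate_sequence <- function(design = oddball_design(), seed = 1L, lead_in_s = 2) {
  stopifnot(inherits(design, "oddball_design"))
  n <- design$n_trials_total
  withr::with_seed(seed, {
    conditions <- sample(rep(
      factor(CONDITIONS, levels = CONDITIONS),
      c(design$n_frequent, design$n_infrequent, design$n_trial_unique)
    ))
    isi_ms <- runif(n, design$isi_min_ms, design$isi_max_ms)
  })
  # Onset k+1 = onset k + stimulus duration + ISI k.
  gaps_s <- (design$stim_duration_ms + isi_ms) / 1000
  onset_s <- lead_in_s + c(0, cumsum(gaps_s[-n]))
  ordinal <- stats::ave(seq_len(n), conditions, FUN = seq_along)
  stimulus_id <- character(n)
  stimulus_id[conditions == "Frequent"] <- "tone_500hz"
  stimulus_id[conditions == "Infrequent"] <- "white_noise"
  tu <- conditions == "TrialUnique"
  stimulus_id[tu] <- sprintf("TU_%04d", seq_len(sum(tu)))
  out <- tibble(
    trial = seq_len(n),
    condition = conditions,
    ordinal = as.integer(ordinal),
    stimulus_id = stimulus_id,
    onset_s = onset_s,
    onset_sample = as.integer(round(onset_s * design$sample_rate_hz)) + 1L,
    isi_ms = isi_ms
  )
  attr(out, "design") <- design
  class(out) <- c("stimulus_sequence", class(out))
  out
}

#' Draw inter-stimulus intervals from the design's jitter distribution
#'
#' Convenience sampler for the ISI jitter alone: uniform on
#' `[isi_min_ms, isi_max_ms]`.
#'
#' @param n Number of draws.
#' @param design An [oddball_design()].
#' @param seed Integer seed.
#' @return Numeric vector of ISIs in ms.
#' @examples
#' mean(draw_isis(1e4, seed = 7))
#' @export
draw_isis <- function(n, design = oddball_design(), seed = 1L) {
  stopifnot(inherits(design, "oddball_design"))
  withr::with_seed(seed, runif(n, design$isi_min_ms, design$isi_max_ms))
}
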