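#' Write and read continuous recordings as tab-separated text
#'
#' The columnar dialect stores one row per sample: `time_s`, then one column
#' per channel (`Fz` ... `CP2`) in microvolts. Event markers go to a separate
#' tab-separated file with `onset_sample`, `condition`, `stimulus_id` (plus
#' `trial` and `ordinal` for round-tripping).
#'
#' @param rec An `erp_recording`.
#' @param path Signal TSV path.
#' @param events_path Events TSV path; default replaces the extension with
#'   `_events.tsv`.
#' @return `write_recording_tsv` returns the paths invisibly;
#'   `read_recording_tsv` returns an `erp_recording`.
#' @export
write_recording_tsv <- function(rec, path, events_path = NULL) {
  stopifnot(inherits(rec, "erp_recording"))
  events_path <- events_path %||% sub("(\\.tsv)?$", "_events.tsv", path)
  sig <- as_tibble(rec)
  readr::write_tsv(sig, path)
  readr::write_tsv(
    select(
      rec$events, "onset_sample", "condition", "stimulus_id",
      dplyr::any_of(c("trial", "ordinal"))
    ),
    events_path
  )
  invisible(c(signal = path, events = events_path))
}

#' @rdname write_recording_tsv
#' @param sample_rate_hz Sampling rate of the stored signal, Hz.
#' @export
read_recording_tsv <- function(path, events_path = NULL, sample_rate_hz = 500) {
  events_path <- events_path %||% sub("(\\.tsv)?$", "_events.tsv", path)
  sig <- readr::read_tsv(path, show_col_types = FALSE)
  ev <- readr::read_tsv(events_path, show_col_types = FALSE)
  ev$condition <- factor(ev$condition, levels = CONDITIONS)
  if (!"ordinal" %in% names(ev)) {
    ev$ordinal <- as.integer(stats::ave(seq_len(nrow(ev)), ev$condition, FUN = seq_along))
  }
  if (!"trial" %in% names(ev)) ev$trial <- seq_len(nrow(ev))
  chans <- setdiff(names(sig), "time_s")
  structure(
    list(
      signal = unname(as.matrix(sig[chans])),
      sample_rate_hz = sample_rate_hz,
      channel_names = chans,
      reference = "left mastoid",
      events = ev,
      subject = NULL,
      artifact_trials = integer(0)
    ),
    class = "erp_recording"
  )
}

#' Write and read epoch sets as a text container
#'
#' Stores an `erp_epochs` object as a directory of per-epoch TSV files
#' (`epoch_0001.tsv`, ... with `time_ms` plus one column per channel) and a
#' JSON sidecar (`epochs.json`) holding labels, validity flags and sampling
#' metadata. Binary-free, diff-able, loadable anywhere.
#'
#' @param es An `erp_epochs` object.
#' @param dir Output directory (created if needed).
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` an
#'   `erp_epochs`.
#' @export
write_epochs <- function(es, dir) {
  stopifnot(inherits(es, "erp_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(dim(es$data)[1])) {
    m <- t(matrix(es$data[i, , ], nrow = dim(es$data)[2]))
    colnames(m) <- es$channel_names
    readr::write_tsv(
      bind_cols(tibble(time_ms = es$time_ms), as_tibble(m)),
      file.path(dir, sprintf("epoch_%04d.tsv", i))
    )
  }
  sidecar <- list(
    sample_rate_hz = es$sample_rate_hz,
    channel_names = es$channel_names,
    n_dropped_edge = es$n_dropped_edge,
    info = es$info
  )
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "epochs.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^epoch_\\d+\\.tsv$", full.names = TRUE))
  stopifnot(length(files) >= 1)
  first <- readr::read_tsv(files[1], show_col_types = FALSE)
  time_ms <- first$time_ms
  chans <- sidecar$channel_names
  dat <- array(0, c(length(files), length(chans), length(time_ms)))
  for (i in seq_along(files)) {
    m <- readr::read_tsv(files[i], show_col_types = FALSE)
    dat[i, , ] <- t(as.matrix(m[chans]))
  }
  info <- as_tibble(sidecar$info)
  info$condition <- factor(info$condition, levels = CONDITIONS)
  structure(
    list(
      data = dat, time_ms = time_ms, info = info,
      sample_rate_hz = sidecar$sample_rate_hz,
      channel_names = chans,
      n_dropped_edge = sidecar$n_dropped_edge
    ),
    class = "erp_epochs"
  )
}
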