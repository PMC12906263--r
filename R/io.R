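# Plain-text artifact IO: every stage reads and writes CSV/JSON so runs
# are auditable and each stage can be re-run from intermediates.

#' Write a simulated trial to disk
#'
#' One wide CSV per trial (`<id>_trial.csv`: time plus one column per
#' channel, `NA` in recording gaps) and a JSON sidecar
#' (`<id>_meta.json`) carrying participant metadata, sample rate, batch
#' windows and — when supplied — the generator's ground truth.
#'
#' @param recording a `trial_recording`.
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth`.
#' @return invisibly, the two file paths.
#' @export
write_trial <- function(recording, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- recording$meta$id
  csv <- file.path(dir, paste0(id, "_trial.csv"))
  json <- file.path(dir, paste0(id, "_meta.json"))
  df <- data.frame(time = recording$time)
  for (ch in names(recording$channels)) df[[ch]] <- recording$channels[[ch]]
  utils::write.csv(df, csv, row.names = FALSE)
  side <- list(
    meta = recording$meta,
    sample_rate = recording$sample_rate,
    duration = recording$duration,
    batch_windows = recording$batch_windows
  )
  if (!is.null(truth)) {
    side$truth <- list(
      events = truth$events,
      stride_table = truth$stride_table,
      offsets = truth$offsets
    )
  }
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a trial written by [write_trial()]
#'
#' @param dir directory containing the pair of files.
#' @param id participant identifier.
#' @return `list(recording, truth)`; `truth` is `NULL` when the sidecar
#'   holds none.
#' @export
read_trial <- function(dir, id) {
  csv <- file.path(dir, paste0(id, "_trial.csv"))
  json <- file.path(dir, paste0(id, "_meta.json"))
  if (!file.exists(csv) || !file.exists(json))
    schema_error("trial files for '%s' not found in %s", id, dir)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- utils::read.csv(csv)
  chans <- as.list(df[setdiff(names(df), "time")])
  bw <- as_windows(side$batch_windows)
  recording <- structure(
    list(meta = side$meta, sample_rate = side$sample_rate,
         duration = side$duration, batch_windows = bw,
         usable_windows = bw, time = df$time, channels = chans,
         trimmed = FALSE),
    class = "trial_recording"
  )
  truth <- NULL
  if (!is.null(side$truth)) {
    truth <- structure(side$truth, class = "ground_truth")
  }
  list(recording = recording, truth = truth)
}

#' List participant ids available in a trial directory
#' @param dir directory written by [write_trial()].
#' @return character vector of ids.
#' @export
list_trials <- function(dir) {
  f <- list.files(dir, pattern = "_trial\\.csv$")
  sub("_trial\\.csv$", "", f)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
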