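# Reading, validating and labelling per-trial gaze recordings.
#
# A gaze table is a plain CSV with columns `timestamp_us,u,v,valid`
# (timestamps in integer microseconds since trial start; u,v normalized
# equirectangular coordinates; valid 0/1). Tables may hold several trials,
# in which case `participant_id` and `trial_id` columns identify them.
# The trial manifest is a JSON array of
# {participant_id, trial_id, video_id, label} records with label in {0,1,2}
# (0 = novice, 1 = advanced, 2 = expert).

EXPERTISE_LEVELS <- c("novice", "advanced", "expert")

#' Construct a single-trial gaze recording
#'
#' Bundles the raw 250 Hz gaze samples of one video trial together with the
#' participant/trial/video identifiers and the expertise class label.
#'
#' @param participant_id character scalar.
#' @param trial_id integer trial index within participant.
#' @param video_id integer stimulus video identifier.
#' @param label integer expertise code: 0 novice, 1 advanced, 2 expert.
#' @param samples data.frame with columns `timestamp_us` (integer
#'   microseconds, strictly increasing), `u` in \[0,1), `v` in \[0,1\] and
#'   logical `valid`.
#' @param nominal_rate sampling rate in Hz (default 250).
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(participant_id, trial_id, video_id, label,
                            samples, nominal_rate = 250) {
  if (!label %in% 0:2)
    stop_gpn("gpn_metadata_error", "unknown expertise label code %s", label)
  samples <- as.data.frame(samples)
  need <- c("timestamp_us", "u", "v", "valid")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_gpn("gpn_format_error", "gaze table missing column(s): %s",
             paste(miss, collapse = ", "))
  if (nrow(samples) == 0L)
    stop_gpn("gpn_data_error", "trial %s/%s has no samples",
             participant_id, trial_id)
  if (is.unsorted(samples$timestamp_us, strictly = TRUE))
    stop_gpn("gpn_data_error",
             "non-monotone timestamps in trial %s/%s",
             participant_id, trial_id)
  if (any(samples$u < 0 | samples$u >= 1) || any(samples$v < 0 | samples$v > 1))
    stop_gpn("gpn_data_error",
             "gaze coordinates out of range in trial %s/%s",
             participant_id, trial_id)
  structure(list(participant_id = as.character(participant_id),
                 trial_id = as.integer(trial_id),
                 video_id = as.integer(video_id),
                 label = as.integer(label),
                 samples = data.frame(timestamp_us = as.numeric(samples$timestamp_us),
                                      u = as.numeric(samples$u),
                                      v = as.numeric(samples$v),
                                      valid = as.logical(samples$valid)),
                 nominal_rate = nominal_rate),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> participant %s, trial %d, video %d, label %d (%s)\n",
              x$participant_id, x$trial_id, x$video_id, x$label,
              EXPERTISE_LEVELS[x$label + 1L]))
  cat(sprintf("  %d samples @ %g Hz, tracking ratio %.3f\n",
              nrow(x$samples), x$nominal_rate, tracking_ratio(x)))
  invisible(x)
}

#' Read per-trial gaze recordings from a gaze table and a trial manifest
#'
#' @param path path to the gaze CSV (columns `timestamp_us,u,v,valid`, plus
#'   `participant_id,trial_id` when the file holds several trials).
#' @param manifest path to the JSON trial manifest, or an already-parsed
#'   data.frame with columns `participant_id,trial_id,video_id,label`.
#' @return list of [trial_recording] objects, samples sorted by timestamp.
#' @export
read_trials <- function(path, manifest) {
  if (!file.exists(path))
    stop_gpn("gpn_io_error", "gaze table not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_us", "u", "v", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_gpn("gpn_format_error", "gaze table %s missing column(s): %s",
             path, paste(miss, collapse = ", "))
  if (is.character(manifest)) {
    man <- jsonlite::fromJSON(manifest, simplifyDataFrame = TRUE)
  } else man <- as.data.frame(manifest)
  if (any(!man$label %in% 0:2))
    stop_gpn("gpn_metadata_error", "manifest holds unknown label code(s): %s",
             paste(unique(man$label[!man$label %in% 0:2]), collapse = ", "))
  if (anyDuplicated(man[c("participant_id", "trial_id")]))
    stop_gpn("gpn_metadata_error", "duplicate (participant, trial) in manifest")

  if (!"participant_id" %in% names(tab)) tab$participant_id <- man$participant_id[1]
  if (!"trial_id" %in% names(tab)) tab$trial_id <- man$trial_id[1]

  # coerce; rows with unparseable fields are rejected
  for (cn in c("timestamp_us", "u", "v"))
    tab[[cn]] <- suppressWarnings(as.numeric(tab[[cn]]))
  v1 <- as.logical(tab$valid)
  v2 <- suppressWarnings(as.numeric(tab$valid)) > 0
  tab$valid <- ifelse(is.na(v1), v2, v1)
  ok <- stats::complete.cases(tab[need])
  tab <- tab[ok, , drop = FALSE]

  keys <- unique(tab[c("participant_id", "trial_id")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    pid <- keys$participant_id[i]; tid <- keys$trial_id[i]
    rows <- tab[tab$participant_id == pid & tab$trial_id == tid, , drop = FALSE]
    rows <- rows[order(rows$timestamp_us), , drop = FALSE]
    m <- man[man$participant_id == pid & man$trial_id == tid, , drop = FALSE]
    if (nrow(m) != 1L)
      stop_gpn("gpn_metadata_error",
               "manifest has no entry for participant %s trial %s", pid, tid)
    out[[i]] <- trial_recording(pid, tid, m$video_id, m$label,
                                rows[need])
  }
  out
}

#' Write trials back out in the package's gaze-table dialect
#'
#' Inverse of [read_trials()]; used by the fixture generator and for
#' round-trip testing.
#'
#' @param trials list of [trial_recording].
#' @param path output CSV path.
#' @param manifest_path optional path for the JSON manifest.
#' @export
write_trials <- function(trials, path, manifest_path = NULL) {
  rows <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id, trial_id = tr$trial_id,
               timestamp_us = format(tr$samples$timestamp_us, scientific = FALSE, trim = TRUE),
               u = tr$samples$u, v = tr$samples$v,
               valid = as.integer(tr$samples$valid))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest_path)) {
    man <- data.frame(participant_id = vapply(trials, `[[`, "", "participant_id"),
                      trial_id = vapply(trials, `[[`, 0L, "trial_id"),
                      video_id = vapply(trials, `[[`, 0L, "video_id"),
                      label = vapply(trials, `[[`, 0L, "label"))
    jsonlite::write_json(man, manifest_path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Fraction of validly tracked samples in a trial
#'
#' @param trial a [trial_recording].
#' @return fraction in \[0,1\]: valid samples / all samples.
#' @export
tracking_ratio <- function(trial) {
  n <- nrow(trial$samples)
  if (is.null(n) || n == 0L)
    stop_gpn("gpn_data_error", "empty trial has no tracking ratio")
  sum(trial$samples$valid) / n
}

#' Keep only trials whose tracking ratio exceeds a threshold
#'
#' A trial survives only when its tracking ratio is strictly greater than
#' `threshold` (a ratio exactly at the threshold is dropped). Order is
#' preserved; the result may be empty.
#'
#' @param trials list of [trial_recording].
#' @param threshold fraction in \[0,1\], default 0.75.
#' @return filtered list.
#' @export
filter_valid <- function(trials, threshold = 0.75) {
  stopifnot(threshold >= 0, threshold <= 1)
  trials[vapply(trials, tracking_ratio, 0) > threshold]
}
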