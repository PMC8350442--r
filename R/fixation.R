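# I-VT fixation detection on the sphere.
#
# Gaze velocity is the great-circle angular distance between consecutive
# valid samples divided by their time difference; invalid samples break the
# stream so no velocity is computed across a tracker dropout. A sample with
# speed below the velocity threshold (default 50 deg/s) is a fixation
# sample, otherwise a saccade sample; maximal runs of consecutive fixation
# samples form one fixation. No minimum-duration filter, no merging across
# short saccades, no smoothing: the plain I-VT reading.

#' Per-sample angular gaze velocity of a trial
#'
#' @param trial a [trial_recording()] with at least two valid samples.
#' @return data.frame with one row per consecutive pair of adjacent valid
#'   samples: `index` (row index of the second sample of the pair in the
#'   trial's sample table) and `speed_deg_s` (great-circle angular speed in
#'   degrees of visual angle per second).
#' @export
angular_velocity <- function(trial) {
  s <- trial$samples
  if (sum(s$valid) < 2L)
    stop_gpn("gpn_data_error", "trial %s/%s has fewer than 2 valid samples",
             trial$participant_id, trial$trial_id)
  n <- nrow(s)
  i2 <- which(s$valid[-1] & s$valid[-n]) + 1L  # second element of valid pairs
  if (!length(i2))
    return(data.frame(index = integer(0), speed_deg_s = numeric(0)))
  i1 <- i2 - 1L
  dt <- (s$timestamp_us[i2] - s$timestamp_us[i1]) / 1e6
  dist <- angular_distance_deg(s$u[i1], s$v[i1], s$u[i2], s$v[i2])
  data.frame(index = i2, speed_deg_s = dist / dt)
}

#' Detect fixations with the I-VT velocity-threshold filter
#'
#' Labels every valid sample fixation/saccade by its instantaneous angular
#' speed (strictly below `threshold_deg_s` is a fixation sample; the first
#' sample of each contiguous valid segment carries no velocity and inherits
#' the label of the transition into its successor, a singleton valid segment
#' counts as a one-sample fixation). Maximal runs of consecutive fixation
#' samples become one fixation each; saccade samples and tracker dropouts
#' terminate runs.
#'
#' @param trial a [trial_recording()].
#' @param threshold_deg_s velocity threshold in degrees per second
#'   (default 50).
#' @return data.frame of fixations: `onset_us`, `offset_us`, `center_u`,
#'   `center_v`, `center_us`, `n_samples`.
#' @export
ivt_detect <- function(trial, threshold_deg_s = 50) {
  if (threshold_deg_s <= 0)
    stop_gpn("gpn_parameter_error", "velocity threshold must be positive")
  s <- trial$samples
  lab <- ivt_labels(trial, threshold_deg_s)
  runs <- rle(ifelse(is.na(lab), "x", ifelse(lab, "f", "s")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values == "f"
  fx <- lapply(which(keep), function(k) {
    idx <- starts[k]:ends[k]
    ctr <- fixation_center(s[idx, , drop = FALSE])
    data.frame(onset_us = s$timestamp_us[idx[1]],
               offset_us = s$timestamp_us[idx[length(idx)]],
               center_u = ctr$center_u, center_v = ctr$center_v,
               center_us = ctr$center_us, n_samples = length(idx))
  })
  if (!length(fx))
    return(data.frame(onset_us = numeric(0), offset_us = numeric(0),
                      center_u = numeric(0), center_v = numeric(0),
                      center_us = numeric(0), n_samples = integer(0)))
  do.call(rbind, fx)
}

# Per-sample fixation labels: TRUE fixation, FALSE saccade, NA invalid.
# Exposed internally so the detector and test oracles share one label
# convention but independent grouping logic.
ivt_labels <- function(trial, threshold_deg_s) {
  s <- trial$samples
  n <- nrow(s)
  lab <- rep(NA, n)
  vel <- if (sum(s$valid) >= 2L) angular_velocity(trial) else
    data.frame(index = integer(0), speed_deg_s = numeric(0))
  lab[vel$index] <- vel$speed_deg_s < threshold_deg_s
  has_vel <- rep(FALSE, n + 1L)
  has_vel[vel$index] <- TRUE
  # segment-initial valid samples: inherit successor's label, or fixation
  # when the segment is a singleton
  for (i in which(s$valid)) {
    if (!is.na(lab[i])) next
    lab[i] <- if (has_vel[i + 1L]) lab[i + 1L] else TRUE
  }
  lab[!s$valid] <- NA
  lab
}

#' Spatial and temporal center of a set of fixation samples
#'
#' Arithmetic means of the member samples; the horizontal coordinate is
#' averaged circularly (unit-vector mean of longitudes) so fixations that
#' straddle the u = 0/1 seam of the equirectangular frame center correctly.
#'
#' @param samples data.frame with columns `timestamp_us`, `u`, `v` (at least
#'   one row).
#' @return list with `center_u`, `center_v`, `center_us`.
#' @export
fixation_center <- function(samples) {
  if (is.null(nrow(samples)) || nrow(samples) == 0L)
    stop_gpn("gpn_data_error", "fixation has no member samples")
  ang <- 2 * pi * samples$u
  cu <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
  if (cu >= 1) cu <- 0     # a tiny negative angle can round up to exactly 1
  list(center_u = cu,
       center_v = mean(samples$v),
       center_us = mean(samples$timestamp_us))
}

#' Export a fixation table for a set of trials
#'
#' @param trials list of [trial_recording()].
#' @param path output CSV path.
#' @param threshold_deg_s I-VT velocity threshold.
#' @return the path, invisibly.
#' @export
write_fixations <- function(trials, path, threshold_deg_s = 50) {
  rows <- do.call(rbind, lapply(trials, function(tr) {
    fx <- ivt_detect(tr, threshold_deg_s)
    if (nrow(fx) == 0L) return(NULL)
    cbind(data.frame(participant_id = tr$participant_id,
                     trial_id = tr$trial_id,
                     fix_index = seq_len(nrow(fx))), fx)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
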