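# Seeded synthetic cohort: procedural stimuli plus class-conditional gaze.
#
# The generator emulates the study design the pipeline targets: 250 Hz
# gaze over equirectangular video of a build-up scene (one ball-like disc,
# teammates, opponents), three expertise classes, several trials per
# participant over a shared set of videos. The class signal is placed in
# BOTH scanpath dynamics (fixation durations) and fixated appearance
# (which discs are looked at), so either the temporal or the spatial
# pathway can carry it. Gaze noise is modelled as a per-fixation angular
# offset (calibration error) plus tiny per-sample jitter -- at 250 Hz a
# large white per-sample noise would masquerade as saccadic velocity,
# which real tracker noise does not.

#' Per-class gaze behaviour profile
#'
#' @param fix_dur_mean_ms,fix_dur_sd_ms fixation dwell distribution
#'   (normal, truncated at 80 ms).
#' @param weight_ball,weight_team,weight_opp relative preference for
#'   fixating the ball disc, teammate discs and opponent discs.
#' @param noise_sigma_deg per-fixation angular offset SD in degrees.
#' @param jitter_sigma_deg per-sample angular jitter SD in degrees.
#' @param invalid_frac fraction of samples flagged invalid (in bursts).
#' @param saccade_ms saccade transition duration in milliseconds.
#' @return list profile.
#' @export
class_profile <- function(fix_dur_mean_ms = 300, fix_dur_sd_ms = 80,
                          weight_ball = 1, weight_team = 1, weight_opp = 1,
                          noise_sigma_deg = 0.8, jitter_sigma_deg = 0.02,
                          invalid_frac = 0.03, saccade_ms = 16) {
  as.list(environment())
}

# Widely separated class profiles: the acceptance condition for the
# synthetic cohort is that classes differ strongly in BOTH scanpath
# dynamics and fixated appearance. Novices scan all objects with short
# dwells and coarse calibration; experts hold long fixations almost
# exclusively on ball and teammates; the advanced class sits between but
# with clear margins in each channel.
default_class_profiles <- function() {
  list(
    novice = class_profile(180, 40, weight_ball = 1, weight_team = 1,
                           weight_opp = 1, noise_sigma_deg = 1.2),
    advanced = class_profile(320, 70, weight_ball = 2, weight_team = 3,
                             weight_opp = 1, noise_sigma_deg = 0.8),
    expert = class_profile(500, 110, weight_ball = 8, weight_team = 4,
                           weight_opp = 0.25, noise_sigma_deg = 0.5))
}

#' Synthetic cohort specification
#'
#' Defaults describe the desk-scale study: 4 participants per class, 8
#' trials each over 4 shared videos, 960 x 480 stimuli (same normalized
#' gaze coordinates as the 3,840 x 1,920 reference; patches then cover a
#' larger visual angle, acceptable for testing) at 30 FPS for 8 s, gaze at
#' 250 Hz.
#'
#' @param n_per_class participants per class, length 3.
#' @param n_trials trials per participant.
#' @param n_videos distinct stimulus videos shared by all participants.
#' @param video list with `width`, `height`, `fps`, `duration_s`.
#' @param class_profiles list of three [class_profile()]s named
#'   novice/advanced/expert.
#' @param identical_profiles if TRUE all classes use the advanced profile
#'   (no class signal; leakage control).
#' @param rate_hz gaze sampling rate.
#' @param seed integer master seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = c(4L, 4L, 4L), n_trials = 8L,
                         n_videos = 4L,
                         video = list(width = 960L, height = 480L, fps = 30,
                                      duration_s = 8),
                         class_profiles = default_class_profiles(),
                         identical_profiles = FALSE,
                         rate_hz = 250, seed = 42L) {
  stopifnot(length(n_per_class) == 3L, all(n_per_class >= 1L), n_trials >= 1L,
            video$duration_s > 0)
  if (identical_profiles)
    class_profiles <- stats::setNames(rep(class_profiles["advanced"], 3),
                                      EXPERTISE_LEVELS)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_trials = as.integer(n_trials),
                 n_videos = as.integer(n_videos), video = video,
                 class_profiles = class_profiles, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate one procedural stimulus video of a fixture cohort
#'
#' @param spec a [fixture_spec()].
#' @param video_id integer id.
#' @param seed seed (defaults to the spec seed).
#' @param dir if given, frames are also written there as PNGs.
#' @return a [video_stimulus()].
#' @export
generate_video <- function(spec, video_id, seed = spec$seed, dir = NULL) {
  v <- video_stimulus(video_id, spec$video$width, spec$video$height,
                      spec$video$fps, spec$video$duration_s, n_discs = 11,
                      seed = seed)
  if (!is.null(dir)) v <- write_video_frames(v, dir)
  v
}

# Disc preference weights of a profile for a given scene. Weights are
# per-disc multipliers: a profile of (1, 1, 1) scans every object
# uniformly, regardless of how many discs each role has.
disc_weights <- function(profile, scene) {
  w <- numeric(nrow(scene))
  w[scene$role == "ball"] <- profile$weight_ball
  w[scene$role == "team"] <- profile$weight_team
  w[scene$role == "opp"] <- profile$weight_opp
  w / sum(w)
}

#' Generate one class-conditional gaze trial over a video
#'
#' An alternating fixation/saccade process: fixation targets are drawn
#' from the class's disc preferences (never repeating the current target),
#' dwell times from the class's duration distribution; the gaze tracks the
#' moving target during a fixation and transitions along the great circle
#' during a saccade. The planned fixations are attached as attribute
#' `ground_truth` (never read by the pipeline).
#'
#' @param spec a [fixture_spec()].
#' @param participant_class 0, 1 or 2.
#' @param video a procedural [video_stimulus()].
#' @param seed integer seed.
#' @param participant_id,trial_id identity stamped on the recording.
#' @return a [trial_recording()] with a `ground_truth` attribute.
#' @export
generate_gaze <- function(spec, participant_class, video, seed,
                          participant_id = "p01", trial_id = 1L) {
  if (!participant_class %in% 0:2)
    stop_gpn("gpn_parameter_error", "unknown class %s", participant_class)
  prof <- spec$class_profiles[[participant_class + 1L]]
  period_us <- 1e6 / spec$rate_hz
  n <- floor(spec$video$duration_s * 1e6 / period_us)
  ts <- (seq_len(n) - 1L) * period_us
  ts_s <- ts / 1e6
  sacc_len <- max(2L, round(prof$saccade_ms / 1000 * spec$rate_hz))
  weights <- disc_weights(prof, video$scene)

  with_local_seed(seed, {
    lam <- numeric(n); phi <- numeric(n)
    plan <- list()
    i <- 1L
    target <- sample.int(nrow(video$scene), 1L, prob = weights)
    off <- stats::rnorm(2, 0, prof$noise_sigma_deg)
    while (i <= n) {
      dwell_ms <- max(80, stats::rnorm(1, prof$fix_dur_mean_ms, prof$fix_dur_sd_ms))
      n_fix <- max(2L, round(dwell_ms / 1000 * spec$rate_hz))
      last <- min(n, i + n_fix - 1L)
      # a trailing stub too short to host a new fixation+saccade is
      # absorbed into this fixation
      if (n - last - sacc_len < 2L) last <- n
      idx <- i:last
      trk <- disc_positions_at(video, target, ts_s[idx])
      lam[idx] <- trk$lambda + off[1]
      phi[idx] <- trk$phi + off[2]
      plan[[length(plan) + 1L]] <-
        data.frame(target = target, onset_us = ts[idx[1]],
                   offset_us = ts[idx[length(idx)]], n_samples = length(idx))
      i <- last + 1L
      if (i > n) break
      # saccade to a different disc
      new_target <- sample.int(nrow(video$scene), 1L,
                               prob = replace(weights, target, 0))
      new_off <- stats::rnorm(2, 0, prof$noise_sigma_deg)
      j <- i:min(n, i + sacc_len - 1L)
      from <- disc_positions_at(video, target, ts_s[j[1]])
      to <- disc_positions_at(video, new_target, ts_s[j[length(j)]])
      sl <- slerp_lambda_phi(from$lambda + off[1], from$phi + off[2],
                             to$lambda + new_off[1], to$phi + new_off[2],
                             seq_along(j) / (length(j) + 1))
      lam[j] <- sl$lambda; phi[j] <- sl$phi
      i <- j[length(j)] + 1L
      target <- new_target; off <- new_off
    }
    if (prof$jitter_sigma_deg > 0) {
      lam <- lam + stats::rnorm(n, 0, prof$jitter_sigma_deg)
      phi <- phi + stats::rnorm(n, 0, prof$jitter_sigma_deg)
    }
    phi <- pmin(pmax(phi, -89.9), 89.9)
    uv <- lambda_phi_to_uv(lam, phi)

    valid <- rep(TRUE, n)
    want_invalid <- round(prof$invalid_frac * n)
    while (sum(!valid) < want_invalid) {
      len <- min(want_invalid - sum(!valid), sample(15:35, 1L))
      start <- sample.int(n - len + 1L, 1L)
      valid[start:(start + len - 1L)] <- FALSE
    }

    tr <- trial_recording(participant_id, trial_id, video$video_id,
                          participant_class,
                          data.frame(timestamp_us = ts, u = uv$u, v = uv$v,
                                     valid = valid),
                          nominal_rate = spec$rate_hz)
    attr(tr, "ground_truth") <- do.call(rbind, plan)
    tr
  })
}

# Trajectory of one disc evaluated at many time points.
disc_positions_at <- function(video, disc, t_s) {
  sc <- video$scene[disc, ]
  lam <- sc$lam0 + sc$amp_lam * sin(2 * pi * sc$f_lam * t_s + sc$ph_lam)
  phi <- sc$phi0 + sc$amp_phi * sin(2 * pi * sc$f_phi * t_s + sc$ph_phi)
  list(lambda = lam, phi = phi)
}

#' Generate a full synthetic cohort
#'
#' Participants are named `nov01..`, `adv01..`, `exp01..`; each sees
#' `n_trials` trials over the shared videos (trial t uses video
#' `((t-1) mod n_videos) + 1`). Everything is deterministic under
#' `(spec, spec$seed)`.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory: gaze tables, trial manifest and the
#'   ground-truth log are written there (videos stay procedural).
#' @return list with `trials` (list of [trial_recording()]), `videos`
#'   (list of [video_stimulus()]), `manifest` (data.frame) and
#'   `ground_truth` (per-trial fixation plans).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  videos <- lapply(seq_len(spec$n_videos), function(vid)
    generate_video(spec, vid, seed = spec$seed))
  prefixes <- c("nov", "adv", "exp")
  trials <- list(); gt <- list()
  for (k in 0:2) {
    for (pi in seq_len(spec$n_per_class[k + 1L])) {
      pid <- sprintf("%s%02d", prefixes[k + 1L], pi)
      for (t in seq_len(spec$n_trials)) {
        vid <- ((t - 1L) %% spec$n_videos) + 1L
        tr <- generate_gaze(spec, k, videos[[vid]],
                            seed = derive_seed(spec$seed, paste(pid, t)),
                            participant_id = pid, trial_id = t)
        trials[[length(trials) + 1L]] <- tr
        gt[[paste(pid, t, sep = "/")]] <- attr(tr, "ground_truth")
      }
    }
  }
  manifest <- data.frame(
    participant_id = vapply(trials, `[[`, "", "participant_id"),
    trial_id = vapply(trials, `[[`, 0L, "trial_id"),
    video_id = vapply(trials, `[[`, 0L, "video_id"),
    label = vapply(trials, `[[`, 0L, "label"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(dir, "gaze.csv"),
                 file.path(dir, "manifest.json"))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(trials = trials, videos = videos, manifest = manifest,
       ground_truth = gt)
}
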