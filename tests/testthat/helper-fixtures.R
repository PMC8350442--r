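# Shared builders and independent oracles for the test suite.

# Quick trial from coordinate vectors; 250 Hz timestamps unless given.
make_trial <- function(u, v, valid = TRUE, ts = NULL, pid = "p01", tid = 1L,
                       vid = 1L, label = 0L) {
  n <- length(u)
  if (is.null(ts)) ts <- (seq_len(n) - 1) * 4000
  valid <- rep_len(valid, n)
  trial_recording(pid, tid, vid, label,
                  data.frame(timestamp_us = ts, u = u, v = rep_len(v, n),
                             valid = valid))
}

# Independent angular-speed oracle: dot-product/acos spherical distance
# (different formula from the haversine used by the package).
oracle_speeds <- function(trial) {
  s <- trial$samples
  lam <- (s$u - 0.5) * 2 * pi
  phi <- (0.5 - s$v) * pi
  x <- cos(phi) * cos(lam); y <- cos(phi) * sin(lam); z <- sin(phi)
  n <- nrow(s)
  idx <- integer(0); spd <- numeric(0)
  for (i in 2:n) {
    if (!s$valid[i] || !s$valid[i - 1]) next
    d <- x[i] * x[i - 1] + y[i] * y[i - 1] + z[i] * z[i - 1]
    cr <- c(y[i - 1] * z[i] - z[i - 1] * y[i],
            z[i - 1] * x[i] - x[i - 1] * z[i],
            x[i - 1] * y[i] - y[i - 1] * x[i])
    ang <- atan2(sqrt(sum(cr^2)), d) * 180 / pi
    dt <- (s$timestamp_us[i] - s$timestamp_us[i - 1]) / 1e6
    idx <- c(idx, i); spd <- c(spd, ang / dt)
  }
  data.frame(index = idx, speed_deg_s = spd)
}

# Naive two-pass I-VT oracle: label every sample, then group runs by an
# explicit scan (independent of the rle-based grouping in the package).
oracle_ivt <- function(trial, threshold = 50) {
  s <- trial$samples
  n <- nrow(s)
  vel <- oracle_speeds(trial)
  lab <- rep(NA, n)
  lab[vel$index] <- vel$speed_deg_s < threshold
  for (i in seq_len(n)) {
    if (!s$valid[i] || !is.na(lab[i])) next
    lab[i] <- if (i < n && (i + 1) %in% vel$index) lab[i + 1] else TRUE
  }
  lab[!s$valid] <- NA
  fix <- list(); cur <- integer(0)
  for (i in seq_len(n)) {
    if (isTRUE(lab[i])) cur <- c(cur, i)
    else if (length(cur)) { fix[[length(fix) + 1]] <- cur; cur <- integer(0) }
  }
  if (length(cur)) fix[[length(fix) + 1]] <- cur
  fix
}

# Random spherical-walk trial with occasional dropouts; exercises seam and
# threshold crossings.
random_walk_trial <- function(n = 120, seed = 1, p_invalid = 0.08) {
  set.seed(seed)
  u <- numeric(n); v <- numeric(n)
  u[1] <- runif(1); v[1] <- runif(1, 0.2, 0.8)
  step <- runif(n, 0, 0.004) * sample(c(0, 1), n, TRUE, c(0.6, 0.4))
  dirn <- runif(n, 0, 2 * pi)
  for (i in 2:n) {
    u[i] <- (u[i - 1] + step[i] * cos(dirn[i])) %% 1
    v[i] <- min(max(v[i - 1] + step[i] * sin(dirn[i]), 0), 1)
  }
  make_trial(u, v, valid = runif(n) > p_invalid)
}

# Synthetic linearly separable feature sequences (class mean shift).
sep_feature_seqs <- function(n_per_class, dim = 1024, pid_prefix = "p",
                             shift = 1, noise = 0.3, tmin = 6, tmax = 16,
                             per_participant = 1) {
  out <- list()
  pid_i <- 0
  for (k in 0:2) {
    for (i in seq_len(n_per_class)) {
      if ((i - 1) %% per_participant == 0) pid_i <- pid_i + 1
      T <- sample(tmin:tmax, 1)
      m <- matrix(rnorm(T * dim, 0, noise), T, dim)
      m[, k + 1] <- m[, k + 1] + shift
      out[[length(out) + 1]] <- feature_sequence(
        m, sprintf("%s%02d", pid_prefix, pid_i), ((i - 1) %% per_participant) + 1,
        k)
    }
  }
  out
}

# Desk-scale classifier settings used for cohort-level training in tests:
# a reduced network and schedule appropriate for 1,024-d toy features and
# ~100-sequence training sets (see the methods vignette).
desk_config <- function() gazenet_config(hidden = 16L, fc = 25L,
                                         dropout = 0.5)
desk_control <- function() gazenet_control(minibatch = 16L,
                                           validation_frequency = 20L,
                                           validation_patience = 10L,
                                           max_epochs = 400L,
                                           learning_rate = 1e-3, l2 = 1e-2,
                                           shuffle = TRUE,
                                           checkpoint = "final")

tiny_video <- function(video_id = 1, seed = 1, duration_s = 2)
  video_stimulus(video_id, width = 480, height = 240, fps = 30,
                 duration_s = duration_s, seed = seed)
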