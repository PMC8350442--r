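test_that("procedural videos are deterministic and geometrically consistent", {
  spec <- fixture_spec(video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 2), seed = 13)
  v <- generate_video(spec, 1)
  expect_equal(v$n_frames, 60)                       # duration * fps
  w1 <- render_window(v, 5, 10:40, 100:150)
  w2 <- render_window(v, 5, 10:40, 100:150)
  expect_identical(w1, w2)

  # disc pixels at t=0 match the analytic trajectory: the pixel at the
  # disc center carries the disc color
  pos <- disc_positions(v, 0)
  for (d in c(1, 5)) {
    uv <- lambda_phi_to_uv(pos$lambda[d], pos$phi[d])
    px <- round(uv$u * v$width) %% v$width
    py <- min(round(uv$v * v$height), v$height - 1)
    pix <- render_window(v, 0, py, px)
    expect_equal(as.vector(pix),
                 c(v$scene$r[d], v$scene$g[d], v$scene$b[d]),
                 tolerance = 1e-12)
  }

  # windows agree with the corresponding full-frame block
  full <- render_frame(v, 5)
  expect_equal(w1, full[10:40 + 1, 100:150 + 1, , drop = FALSE])
})

test_that("video frames written to disk reproduce the procedural render", {
  spec <- fixture_spec(video = list(width = 240, height = 120, fps = 10,
                                    duration_s = 0.4), seed = 2)
  v <- generate_video(spec, 1)
  dir <- withr::local_tempdir()
  vd <- generate_video(spec, 1, dir = dir)
  expect_equal(vd$source, "frames")
  back <- video_from_frames(dir)
  expect_equal(back$n_frames, v$n_frames)
  f <- render_frame(v, 2)
  g <- render_window(back, 2, 0:(v$height - 1), 0:(v$width - 1))
  expect_lt(max(abs(f - g)), 1 / 255)               # PNG quantization only
})

test_that("a noise-free single-target profile closes the loop through I-VT", {
  prof <- class_profile(fix_dur_mean_ms = 1e6, fix_dur_sd_ms = 0,
                        noise_sigma_deg = 0, jitter_sigma_deg = 0,
                        invalid_frac = 0)
  spec <- fixture_spec(video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 2),
                       class_profiles = list(novice = prof, advanced = prof,
                                             expert = prof), seed = 5)
  v <- generate_video(spec, 1)
  tr <- generate_gaze(spec, 0, v, seed = 9)
  fx <- ivt_detect(tr, 50)
  expect_equal(nrow(fx), 1)
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(gt), 1)
  # the fixation center sits on the tracked disc's mean position
  target_pos <- disc_positions_at(v, gt$target[1],
                                  mean(tr$samples$timestamp_us) / 1e6)
  uv <- lambda_phi_to_uv(target_pos$lambda, target_pos$phi)
  expect_lt(abs(fx$center_v - uv$v), 0.02)
})

test_that("planned fixation counts are recovered exactly on noise-free streams", {
  profs <- default_class_profiles()
  profs <- lapply(profs, function(p) {
    p$noise_sigma_deg <- 0; p$jitter_sigma_deg <- 0; p$invalid_frac <- 0; p
  })
  spec <- fixture_spec(video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 4),
                       class_profiles = profs, seed = 21)
  v <- generate_video(spec, 1)
  for (s in 1:8) {
    tr <- generate_gaze(spec, (s - 1) %% 3, v, seed = 100 + s)
    k_planned <- nrow(attr(tr, "ground_truth"))
    expect_equal(nrow(ivt_detect(tr, 50)), k_planned)
  }
})

test_that("generated gaze is deterministic and respects the invalid fraction", {
  spec <- fixture_spec(video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 2), seed = 3)
  v <- generate_video(spec, 2)
  t1 <- generate_gaze(spec, 1, v, seed = 44)
  t2 <- generate_gaze(spec, 1, v, seed = 44)
  expect_identical(t1$samples, t2$samples)

  prof_bad <- class_profile(invalid_frac = 0.3)
  spec_bad <- spec
  spec_bad$class_profiles$advanced <- prof_bad
  tb <- generate_gaze(spec_bad, 1, v, seed = 44)
  expect_lte(tracking_ratio(tb), 0.70)
  expect_length(filter_valid(list(tb), 0.75), 0)
})

test_that("cohorts have the configured size and class-ordered dwell times", {
  spec <- fixture_spec(n_per_class = c(4, 4, 4), n_trials = 8, n_videos = 2,
                       video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 2), seed = 6)
  cohort <- generate_cohort(spec)
  expect_length(cohort$trials, 96)
  expect_equal(nrow(cohort$manifest), 96)
  expect_equal(as.vector(table(cohort$manifest$label)), rep(32, 3))

  # mean planned dwell per class follows the configured ordering
  dwell <- vapply(0:2, function(k) {
    pids <- unique(cohort$manifest$participant_id[cohort$manifest$label == k])
    gts <- cohort$ground_truth[grepl(paste0("^(", paste(pids, collapse = "|"),
                                            ")/"),
                                     names(cohort$ground_truth))]
    mean(unlist(lapply(gts, function(g)
      g$offset_us - g$onset_us)))
  }, 0)
  expect_true(dwell[1] < dwell[2] && dwell[2] < dwell[3])

  # ground-truth log is written alongside the gaze tables
  dir <- withr::local_tempdir()
  spec_s <- fixture_spec(n_per_class = c(1, 1, 1), n_trials = 1, n_videos = 1,
                         video = list(width = 480, height = 240, fps = 30,
                                      duration_s = 2), seed = 6)
  generate_cohort(spec_s, dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "gaze.csv")))
})

test_that("identical class profiles remove the class signal from the spec", {
  spec <- fixture_spec(identical_profiles = TRUE)
  expect_identical(spec$class_profiles$novice, spec$class_profiles$expert)
  expect_error(generate_gaze(spec, 5, tiny_video(), 1),
               class = "gpn_parameter_error")
})
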