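test_that("frame lookup is floor(ts * fps / 1e6) clamped to the video", {
  v <- tiny_video(duration_s = 2)          # 60 frames at 30 FPS
  expect_equal(frame_for_timestamp(v, 0), 0)
  expect_equal(frame_for_timestamp(v, 1e6), 30)
  expect_equal(frame_for_timestamp(v, 1e9), v$n_frames - 1)  # clamped
  expect_error(frame_for_timestamp(v, -1), class = "gpn_parameter_error")

  set.seed(5)
  ts <- runif(10000, 0, 2.4e6)
  got <- frame_for_timestamp(v, ts)
  # linear scan over frame time spans
  spans <- (0:(v$n_frames - 1)) * 1e6 / v$fps
  oracle <- vapply(ts, function(t) max(which(spans <= t)) - 1L, 0L)
  oracle <- pmin(oracle, v$n_frames - 1L)
  expect_equal(got, oracle)
})

test_that("patches are exact crops away from borders and wrap at the seam", {
  v <- tiny_video(seed = 4)
  frame0 <- render_frame(v, 10)

  fx <- data.frame(center_u = 0.5, center_v = 0.5,
                   center_us = 10 / 30 * 1e6 + 1)
  p <- extract_patch(v, fx)
  expect_equal(dim(p), c(224, 224, 3))
  cx <- round(0.5 * v$width); cy <- round(0.5 * v$height)
  offs <- -112:111
  expect_equal(p[, , ], frame0[cy + offs + 1, cx + offs + 1, ],
               ignore_attr = TRUE)

  # u = 0: left half of the patch is the right edge of the frame
  fx0 <- data.frame(center_u = 0, center_v = 0.5, center_us = 10 / 30 * 1e6 + 1)
  p0 <- extract_patch(v, fx0)
  expect_equal(p0[, 1:112, ],
               frame0[cy + offs + 1, (v$width - 112 + 1):v$width, ],
               ignore_attr = TRUE)
  expect_equal(p0[, 113:224, ], frame0[cy + offs + 1, 1:112, ],
               ignore_attr = TRUE)

  # poles clamp with edge replication, shape always holds
  for (vv in c(0, 1)) {
    pp <- extract_patch(v, data.frame(center_u = 0.25, center_v = vv,
                                      center_us = 0))
    expect_equal(dim(pp), c(224, 224, 3))
  }

  # deterministic: bit-identical on repetition
  expect_identical(p, extract_patch(v, fx))
})

test_that("a uniform frames-backed video yields a uniform patch", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0.5, c(240, 480, 3)), file.path(dir, "frame_00000.png"))
  jsonlite::write_json(list(video_id = 9, width = 480, height = 240, fps = 30,
                            duration_s = 1 / 30, n_frames = 1),
                       file.path(dir, "video.json"), auto_unbox = TRUE)
  v <- video_from_frames(dir)
  p <- extract_patch(v, data.frame(center_u = 0.5, center_v = 0.5,
                                   center_us = 0))
  expect_equal(dim(p), c(224, 224, 3))
  expect_true(all(abs(p - 0.5) < 1 / 255))
})

test_that("build_sequences conserves fixation counts and trial identity", {
  spec <- fixture_spec(n_per_class = c(1, 1, 1), n_trials = 2, n_videos = 1,
                       video = list(width = 480, height = 240, fps = 30,
                                    duration_s = 2), seed = 3)
  cohort <- generate_cohort(spec)
  seqs <- build_sequences(cohort$trials, cohort$videos)
  expect_length(seqs, length(cohort$trials))
  for (i in seq_along(seqs)) {
    tr <- cohort$trials[[i]]
    expect_equal(length(seqs[[i]]$patches), nrow(ivt_detect(tr)))
    expect_equal(seqs[[i]]$label, tr$label)
    expect_false(seqs[[i]]$augmented)
    expect_true(!is.unsorted(seqs[[i]]$meta$center_us))
  }
  # two trials of one participant share participant_id
  pids <- vapply(seqs, `[[`, "", "participant_id")
  expect_equal(sum(pids == pids[1]), 2)

  # zero-fixation trial emits nothing, with a warning
  fast <- make_trial(seq(0.1, 0.9, length.out = 50), 0.5)  # constant sweep
  expect_true(nrow(ivt_detect(fast)) == 0)
  expect_warning(out <- build_sequences(list(fast), cohort$videos),
                 "no fixations")
  expect_length(out, 0)

  # unresolvable video id is a configuration error
  bad <- cohort$trials[[1]]; bad$video_id <- 99L
  expect_error(build_sequences(list(bad), cohort$videos),
               "99", class = "gpn_config_error")
})

test_that("patch sequences survive a store round trip", {
  v <- tiny_video(seed = 2)
  fx <- data.frame(center_u = c(0.3, 0.7), center_v = c(0.4, 0.5),
                   center_us = c(0, 5e5))
  patches <- lapply(1:2, function(i) extract_patch(v, fx[i, ]))
  s <- patch_sequence(patches, cbind(frame = c(0L, 15L), fx),
                      "p01", 1L, 2L)
  dir <- withr::local_tempdir()
  write_patch_sequences(list(s), dir)
  back <- read_patch_sequences(dir)
  expect_length(back, 1)
  expect_equal(back[[1]]$label, 2L)
  expect_equal(back[[1]]$augmented, FALSE)
  expect_length(back[[1]]$patches, 2)
  # PNG quantizes to 8 bits
  expect_lt(max(abs(back[[1]]$patches[[1]] - patches[[1]])), 1 / 255)
})
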