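# Fixation image-patch extraction.
#
# Each fixation is mapped to the stimulus frame showing at its temporal
# center and a 224 x 224 x 3 patch is cut around its spatial center.
# Horizontal indices wrap modulo the frame width (the equirectangular seam
# is a spherical continuation), vertical indices clamp with edge
# replication at the poles. Pixel (i, j) spans [i, i+1) x [j, j+1); the
# fixation pixel is (round(u*W) mod W, min(round(v*H), H-1)).

#' Cut an image patch around a fixation
#'
#' @param video a [video_stimulus()].
#' @param fixation one-row data.frame (or list) with `center_u`, `center_v`,
#'   `center_us` as produced by [ivt_detect()].
#' @param size patch side length in pixels (default 224).
#' @return numeric array `size x size x 3` in \[0,1\] with attribute
#'   `frame` (source 0-based frame index).
#' @export
extract_patch <- function(video, fixation, size = 224) {
  u <- fixation$center_u; v <- fixation$center_v
  stopifnot(u >= 0, u < 1, v >= 0, v <= 1)
  W <- video$width; H <- video$height
  frame <- frame_for_timestamp(video, fixation$center_us)
  cx <- round(u * W) %% W
  cy <- min(round(v * H), H - 1L)
  offs <- -(size %/% 2):(size - size %/% 2 - 1L)
  rows <- pmin(pmax(cy + offs, 0L), H - 1L)   # clamp: edge replication
  cols <- (cx + offs) %% W                    # wrap: spherical seam
  p <- render_window(video, frame, rows, cols)
  stopifnot(all(dim(p) == c(size, size, 3)))
  attr(p, "frame") <- frame
  p
}

#' Construct a patch sequence
#'
#' The ordered fixation patches of one trial: the classifier's unit sample.
#'
#' @param patches list of `size x size x 3` arrays in fixation order.
#' @param meta data.frame with per-patch `frame`, `center_u`, `center_v`,
#'   `center_us`.
#' @param participant_id,trial_id,label trial identity and expertise code.
#' @param augmented logical: whether the patches were augmented.
#' @return object of class `patch_sequence`.
#' @export
patch_sequence <- function(patches, meta, participant_id, trial_id, label,
                           augmented = FALSE) {
  stopifnot(length(patches) >= 1L, length(patches) == nrow(meta))
  structure(list(patches = patches, meta = meta,
                 participant_id = as.character(participant_id),
                 trial_id = as.integer(trial_id), label = as.integer(label),
                 augmented = isTRUE(augmented)),
            class = "patch_sequence")
}

#' @export
print.patch_sequence <- function(x, ...) {
  cat(sprintf("<patch_sequence> participant %s trial %d label %d: %d patches%s\n",
              x$participant_id, x$trial_id, x$label, length(x$patches),
              if (x$augmented) " (augmented)" else ""))
  invisible(x)
}

#' Build per-trial fixation patch sequences
#'
#' Runs I-VT fixation detection on every trial, maps each fixation to its
#' stimulus frame and cuts the patch around the fixation center. Trials
#' with zero detected fixations emit no sequence (with a warning).
#'
#' @param trials list of [trial_recording()].
#' @param videos named list of [video_stimulus()] keyed by `video_id`, or a
#'   function `function(video_id)` resolving one.
#' @param threshold_deg_s I-VT velocity threshold in degrees/second.
#' @param size patch side length in pixels.
#' @return list of [patch_sequence()] (augmented = FALSE).
#' @export
build_sequences <- function(trials, videos, threshold_deg_s = 50, size = 224) {
  lookup <- video_lookup(videos, trials)
  out <- list()
  for (tr in trials) {
    video <- lookup(tr$video_id)
    fx <- ivt_detect(tr, threshold_deg_s)
    if (nrow(fx) == 0L) {
      warning(sprintf("trial %s/%d: no fixations detected, no sequence emitted",
                      tr$participant_id, tr$trial_id))
      next
    }
    fx <- fx[order(fx$center_us), , drop = FALSE]
    patches <- vector("list", nrow(fx))
    frames <- integer(nrow(fx))
    for (i in seq_len(nrow(fx))) {
      patches[[i]] <- extract_patch(video, fx[i, ], size)
      frames[i] <- attr(patches[[i]], "frame")
    }
    meta <- data.frame(frame = frames, center_u = fx$center_u,
                       center_v = fx$center_v, center_us = fx$center_us)
    out[[length(out) + 1L]] <- patch_sequence(patches, meta,
                                              tr$participant_id, tr$trial_id,
                                              tr$label)
  }
  out
}

video_lookup <- function(videos, trials) {
  if (is.function(videos)) return(videos)
  ids <- vapply(trials, `[[`, 0L, "video_id")
  have <- vapply(videos, `[[`, 0L, "video_id")
  missing_ids <- setdiff(unique(ids), have)
  if (length(missing_ids))
    stop_gpn("gpn_config_error", "no video for video_id(s): %s",
             paste(missing_ids, collapse = ", "))
  function(id) videos[[match(id, have)]]
}

seq_tag <- function(s) sprintf("%s_t%03d_%s", s$participant_id, s$trial_id,
                               if (s$augmented) "aug" else "orig")

#' Persist patch sequences as PNGs plus JSON manifests
#'
#' One PNG per patch and one manifest per sequence
#' (`{participant_id, trial_id, label, augmented, patches: [...]}`).
#'
#' @param seqs list of [patch_sequence()].
#' @param dir output directory.
#' @return manifest paths, invisibly.
#' @export
write_patch_sequences <- function(seqs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seqs, function(s) {
    tag <- seq_tag(s)
    files <- character(length(s$patches))
    for (i in seq_along(s$patches)) {
      files[i] <- sprintf("%s_p%03d.png", tag, i)
      png::writePNG(s$patches[[i]], file.path(dir, files[i]))
    }
    man <- list(participant_id = s$participant_id, trial_id = s$trial_id,
                label = s$label, augmented = s$augmented,
                patches = cbind(data.frame(file = files), s$meta))
    mp <- file.path(dir, sprintf("%s.json", tag))
    jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
    mp
  }, "")
  invisible(paths)
}

#' Load patch sequences written by [write_patch_sequences()]
#'
#' @param dir directory of manifests and PNGs.
#' @return list of [patch_sequence()].
#' @export
read_patch_sequences <- function(dir) {
  mans <- sort(list.files(dir, pattern = "_(orig|aug)\\.json$",
                          full.names = TRUE))
  lapply(mans, function(mp) {
    man <- jsonlite::fromJSON(mp)
    patches <- lapply(man$patches$file, function(f) {
      img <- png::readPNG(file.path(dir, f))
      img[, , 1:3, drop = FALSE]
    })
    meta <- man$patches[c("frame", "center_u", "center_v", "center_us")]
    patch_sequence(patches, meta, man$participant_id, man$trial_id,
                   man$label, man$augmented)
  })
}
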