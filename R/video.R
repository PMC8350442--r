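# Equirectangular stimulus videos.
#
# A stimulus is a 2:1 equirectangular RGB video (reference resolution
# 3,840 x 1,920 at 30 FPS). Two backings are supported:
#   * "procedural": a deterministic scene description (textured background
#     plus moving high-contrast discs standing in for players and ball)
#     rendered on demand -- any pixel window of any frame can be evaluated
#     directly, so patch extraction never decodes full frames;
#   * "frames": a directory of numbered PNG frames (one file per frame),
#     the on-disk interchange format.

#' Construct a procedural equirectangular stimulus video
#'
#' Builds a deterministic scene: a smoothly varying textured background and
#' `n_discs` moving colored discs (one ball-like disc plus two teams) whose
#' positions follow slow sinusoidal trajectories on the sphere. Rendering is
#' fully determined by `(video_id, seed)`.
#'
#' @param video_id integer identifier.
#' @param width,height frame size in pixels (width must be 2 x height).
#' @param fps frames per second (default 30).
#' @param duration_s video length in seconds.
#' @param n_discs number of moving discs (>= 6).
#' @param seed integer seed for the scene layout.
#' @return object of class `video_stimulus`.
#' @export
video_stimulus <- function(video_id, width = 3840, height = 1920, fps = 30,
                           duration_s = 8, n_discs = 11, seed = 1) {
  stopifnot(width == 2 * height, fps > 0, duration_s > 0, n_discs >= 6)
  scene <- with_local_seed(derive_seed(seed, paste0("video", video_id)), {
    k <- n_discs
    base_lam <- ((seq_len(k) - 1) / k) * 360 - 180 + stats::runif(k, -5, 5)
    base_phi <- stats::runif(k, -38, 8)
    # disc 1 is the "ball": low, central, small, red; the rest split into
    # two teams with distinct palettes
    base_lam[1] <- stats::runif(1, -15, 15)
    base_phi[1] <- stats::runif(1, -35, -25)
    team <- c("ball", rep(c("team", "opp"), length.out = k - 1))
    col <- t(vapply(team, function(tm) switch(tm,
      ball = c(0.95, 0.15, 0.15),
      team = c(0.15, 0.25, 0.9) + stats::runif(3, -0.05, 0.05),
      opp  = c(0.95, 0.85, 0.1) + stats::runif(3, -0.05, 0.05)), numeric(3)))
    data.frame(
      id = seq_len(k), role = team,
      lam0 = base_lam, phi0 = base_phi,
      amp_lam = stats::runif(k, 3, 8), amp_phi = stats::runif(k, 1, 5),
      f_lam = stats::runif(k, 0.02, 0.08), f_phi = stats::runif(k, 0.02, 0.08),
      ph_lam = stats::runif(k, 0, 2 * pi), ph_phi = stats::runif(k, 0, 2 * pi),
      radius_deg = c(2.5, stats::runif(k - 1, 3.5, 5)),
      r = pmin(pmax(col[, 1], 0), 1), g = pmin(pmax(col[, 2], 0), 1),
      b = pmin(pmax(col[, 3], 0), 1))
  })
  structure(list(video_id = as.integer(video_id), width = as.integer(width),
                 height = as.integer(height), fps = fps,
                 duration_s = duration_s,
                 n_frames = as.integer(round(duration_s * fps)),
                 source = "procedural", seed = seed,
                 bg_phase = (derive_seed(seed, paste0("bg", video_id)) %% 1000) / 1000,
                 scene = scene),
            class = "video_stimulus")
}

#' @export
print.video_stimulus <- function(x, ...) {
  cat(sprintf("<video_stimulus %d> %dx%d @ %g FPS, %d frames (%s)\n",
              x$video_id, x$width, x$height, x$fps, x$n_frames, x$source))
  invisible(x)
}

#' Disc positions of a procedural video at a time point
#'
#' @param video a procedural [video_stimulus()].
#' @param t_s time in seconds.
#' @return data.frame with `lambda`, `phi` (degrees) per disc.
#' @export
disc_positions <- function(video, t_s) {
  sc <- video$scene
  lam <- sc$lam0 + sc$amp_lam * sin(2 * pi * sc$f_lam * t_s + sc$ph_lam)
  phi <- sc$phi0 + sc$amp_phi * sin(2 * pi * sc$f_phi * t_s + sc$ph_phi)
  lam <- ((lam + 180) %% 360) - 180
  data.frame(id = sc$id, role = sc$role, lambda = lam, phi = phi,
             radius_deg = sc$radius_deg)
}

# Deterministic per-pixel hash noise in [0,1); shader-style.
pixel_hash <- function(r, c, phase) {
  x <- sin((r + 1) * 12.9898 + (c + 1) * 78.233 + phase * 37.719) * 43758.5453
  x - floor(x)
}

#' Render a pixel window of one frame
#'
#' Evaluates the procedural scene over the requested pixel grid, or crops a
#' decoded PNG frame for a frames-backed video. `rows` must already be
#' clamped to `[0, height-1]` and `cols` wrapped modulo `width` (0-based).
#'
#' @param video a [video_stimulus()].
#' @param frame 0-based frame index.
#' @param rows,cols 0-based pixel indices of the window.
#' @return numeric array `length(rows) x length(cols) x 3` in \[0,1\].
#' @export
render_window <- function(video, frame, rows, cols) {
  if (frame < 0 || frame >= video$n_frames)
    stop_gpn("gpn_io_error", "frame %d outside video %d (0..%d)",
             frame, video$video_id, video$n_frames - 1L)
  if (video$source == "frames") {
    img <- read_frame_png(video, frame)
    return(img[rows + 1L, cols + 1L, , drop = FALSE])
  }
  W <- video$width; H <- video$height
  t_s <- frame / video$fps
  nr <- length(rows); nc <- length(cols)
  u <- (cols + 0.5) / W
  v <- (rows + 0.5) / H
  lam <- deg2rad(360 * (u - 0.5))
  phi <- deg2rad(180 * (0.5 - v))
  # pixel unit vectors: outer over rows(phi) x cols(lam)
  cp <- cos(phi); sp <- sin(phi)
  px <- outer(cp, cos(lam)); py <- outer(cp, sin(lam))
  pz <- matrix(sp, nr, nc)
  # background: slow large-scale waves plus static speckle
  gr <- matrix(rows, nr, nc); gc <- matrix(cols, nr, nc, byrow = TRUE)
  wave <- 0.35 + 0.18 * sin(2 * pi * (3 * gc / W + 0.03 * t_s + video$bg_phase)) *
    sin(2 * pi * (2 * gr / H))
  spk <- 0.12 * pixel_hash(gr, gc, video$bg_phase)
  out <- array(0, c(nr, nc, 3))
  out[, , 1] <- wave + spk
  out[, , 2] <- 0.45 + 0.20 * sin(2 * pi * (2 * gc / W - video$bg_phase)) + spk
  out[, , 3] <- wave * 0.6 + spk
  # discs: paint pixels within angular radius of each disc center; discs
  # provably outside the window are skipped
  pos <- disc_positions(video, t_s)
  sc <- video$scene
  ucols <- if (length(cols) > 1) cumsum(c(cols[1], diff(cols) %% W)) else cols
  ctr_lam <- 360 * (((mean(ucols) %% W) + 0.5) / W - 0.5)
  ctr_phi <- 180 * (0.5 - (mean(rows) + 0.5) / H)
  half_diag <- sqrt((nc / W * 180)^2 + (nr / H * 90)^2)
  cxyz <- lambda_phi_to_xyz(ctr_lam, ctr_phi)[1, ]
  for (d in seq_len(nrow(pos))) {
    cd <- lambda_phi_to_xyz(pos$lambda[d], pos$phi[d])[1, ]
    ctr_dist <- acos(min(max(sum(cd * cxyz), -1), 1)) * 180 / pi
    if (ctr_dist > half_diag + pos$radius_deg[d] + 1) next
    dot <- px * cd[1] + py * cd[2] + pz * cd[3]
    mask <- dot > cos(deg2rad(pos$radius_deg[d]))
    if (!any(mask)) next
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[mask] <- c(sc$r[d], sc$g[d], sc$b[d])[ch]
      out[, , ch] <- pl
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Render one full equirectangular frame
#'
#' @inheritParams render_window
#' @return numeric array `height x width x 3` in \[0,1\].
#' @export
render_frame <- function(video, frame) {
  render_window(video, frame, 0:(video$height - 1L), 0:(video$width - 1L))
}

frame_file <- function(dir, frame) file.path(dir, sprintf("frame_%05d.png", frame))

read_frame_png <- function(video, frame) {
  f <- frame_file(video$frame_dir, frame)
  if (!file.exists(f))
    stop_gpn("gpn_io_error", "cannot read frame %d of video %d (missing %s)",
             frame, video$video_id, f)
  img <- png::readPNG(f)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a procedural video to disk as numbered PNG frames
#'
#' @param video a procedural [video_stimulus()].
#' @param dir output directory (created if needed).
#' @return a frames-backed `video_stimulus` pointing at `dir`.
#' @export
write_video_frames <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop_gpn("gpn_io_error", "cannot create frame directory %s", dir)
  for (f in 0:(video$n_frames - 1L))
    png::writePNG(render_frame(video, f), frame_file(dir, f))
  meta <- list(video_id = video$video_id, width = video$width,
               height = video$height, fps = video$fps,
               duration_s = video$duration_s, n_frames = video$n_frames)
  jsonlite::write_json(meta, file.path(dir, "video.json"), auto_unbox = TRUE,
                       digits = NA)
  out <- video
  out$source <- "frames"
  out$frame_dir <- dir
  out
}

#' Open a frames-backed video written by [write_video_frames()]
#'
#' @param dir frame directory holding `video.json` and `frame_*.png`.
#' @return a `video_stimulus` of source "frames".
#' @export
video_from_frames <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "video.json"))
  structure(list(video_id = meta$video_id, width = meta$width,
                 height = meta$height, fps = meta$fps,
                 duration_s = meta$duration_s, n_frames = meta$n_frames,
                 source = "frames", frame_dir = dir),
            class = "video_stimulus")
}

#' Frame index showing at a timestamp
#'
#' The frame on screen at `ts_us` microseconds: `floor(ts * fps / 1e6)`,
#' clamped to the last frame of the video.
#'
#' @param video a [video_stimulus()].
#' @param ts_us timestamp in microseconds (>= 0).
#' @return 0-based frame index.
#' @export
frame_for_timestamp <- function(video, ts_us) {
  if (any(ts_us < 0))
    stop_gpn("gpn_parameter_error", "timestamps must be non-negative")
  pmin(floor(ts_us * video$fps / 1e6), video$n_frames - 1L)
}
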