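# Offline patch augmentation.
#
# Each patch first receives a random Gaussian blur and salt-and-pepper
# noise, then exactly ONE geometric action drawn uniformly from
# {rotate, shear, rotate+shear, flip-x, flip-y, translate-x, translate-y}.
# The output keeps the 224 x 224 x 3 shape; out-of-frame samples are filled
# by edge replication (clamped bilinear sampling) rather than a constant,
# so no artificial borders are introduced for the CNN. Augmentation doubles
# the dataset: every sequence gains exactly one augmented copy with the
# same label, order and identity.

#' Augmentation specification
#'
#' Ranges follow the published protocol where stated (rotation -180..180
#' degrees, shear -15..15 degrees); blur sigma, salt-and-pepper density and
#' the translation range (interpreted in pixels) are package defaults.
#'
#' @param blur_sigma_range Gaussian blur sigma range in pixels.
#' @param sp_density fraction of pixel locations corrupted to black/white.
#' @param rotation_range rotation range in degrees.
#' @param shear_range shear range in degrees.
#' @param translation_range translation range in pixels.
#' @param geometric_per_sequence if TRUE one geometric draw is shared by all
#'   patches of a sequence; default FALSE (independent draw per patch).
#' @param seed integer seed making [augment_dataset()] deterministic.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(blur_sigma_range = c(0.5, 2.0), sp_density = 0.02,
                         rotation_range = c(-180, 180),
                         shear_range = c(-15, 15),
                         translation_range = c(-80, 80),
                         geometric_per_sequence = FALSE, seed = 1L) {
  stopifnot(diff(blur_sigma_range) >= 0, sp_density >= 0, sp_density <= 1,
            diff(rotation_range) >= 0, diff(shear_range) >= 0,
            diff(translation_range) >= 0)
  structure(list(blur_sigma_range = blur_sigma_range, sp_density = sp_density,
                 rotation_range = rotation_range, shear_range = shear_range,
                 translation_range = translation_range,
                 geometric_per_sequence = isTRUE(geometric_per_sequence),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

GEOMETRIC_ACTIONS <- c("rotate", "shear", "rotate_shear", "flip_x", "flip_y",
                       "translate_x", "translate_y")

# Inverse-mapped affine warp about the patch center with clamped bilinear
# sampling (edge replication). m is the 2x2 forward matrix acting on
# (x = col, y = row) offsets from the center; shift is a forward (dx, dy).
affine_warp <- function(img, m, shift = c(0, 0)) {
  d <- dim(img); H <- d[1]; W <- d[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  minv <- solve(m)
  xo <- rep(seq_len(W), each = H) - cx - shift[1]
  yo <- rep(seq_len(H), times = W) - cy - shift[2]
  xs <- pmin(pmax(minv[1, 1] * xo + minv[1, 2] * yo + cx, 1), W)
  ys <- pmin(pmax(minv[2, 1] * xo + minv[2, 2] * yo + cy, 1), H)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, W); y1 <- pmin(y0 + 1, H)
  fx <- xs - x0; fy <- ys - y0
  i00 <- y0 + (x0 - 1) * H; i01 <- y0 + (x1 - 1) * H
  i10 <- y1 + (x0 - 1) * H; i11 <- y1 + (x1 - 1) * H
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  out <- img
  for (ch in seq_len(d[3])) {
    pl <- c(img[, , ch])
    out[, , ch] <- w00 * pl[i00] + w01 * pl[i01] + w10 * pl[i10] + w11 * pl[i11]
  }
  out
}

# Separable Gaussian blur as two band-matrix products per channel; rows of
# the kernel matrix are renormalized at the borders (no constant fill).
gaussian_blur <- function(img, sigma) {
  d <- dim(img); H <- d[1]; W <- d[2]
  Kh <- blur_matrix(H, sigma)
  Kw <- if (W == H) Kh else blur_matrix(W, sigma)
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- tcrossprod(Kh %*% img[, , ch], Kw)
  out
}

blur_matrix <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  idx <- seq_len(n)
  K <- exp(-(outer(idx, idx, "-")^2) / (2 * sigma^2))
  K[abs(outer(idx, idx, "-")) > r] <- 0
  sweep(K, 1, rowSums(K), "/")
}

rot_mat <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

shear_mat <- function(deg) matrix(c(1, 0, tan(deg2rad(deg)), 1), 2, 2)

apply_geometric <- function(img, action, spec) {
  switch(action$name,
    rotate = affine_warp(img, rot_mat(action$angle)),
    shear = affine_warp(img, shear_mat(action$shear)),
    rotate_shear = affine_warp(img, rot_mat(action$angle) %*% shear_mat(action$shear)),
    flip_x = img[dim(img)[1]:1, , , drop = FALSE],  # flip across the x-axis
    flip_y = img[, dim(img)[2]:1, , drop = FALSE],  # flip across the y-axis
    translate_x = affine_warp(img, diag(2), shift = c(action$dx, 0)),
    translate_y = affine_warp(img, diag(2), shift = c(0, action$dy)))
}

draw_geometric <- function(spec) {
  list(name = sample(GEOMETRIC_ACTIONS, 1L),
       angle = stats::runif(1, spec$rotation_range[1], spec$rotation_range[2]),
       shear = stats::runif(1, spec$shear_range[1], spec$shear_range[2]),
       dx = stats::runif(1, spec$translation_range[1], spec$translation_range[2]),
       dy = stats::runif(1, spec$translation_range[1], spec$translation_range[2]))
}

#' Augment one patch
#'
#' Applies, in order: Gaussian blur with sigma drawn uniformly from the
#' spec range, salt-and-pepper noise (a `sp_density` fraction of pixel
#' locations set to black or white with equal probability), then one random
#' geometric action. Draws come from the current RNG stream.
#'
#' @param p patch array (`size x size x 3`).
#' @param spec an [augment_spec()].
#' @param geometric optional pre-drawn geometric action (used when one draw
#'   is shared across a sequence).
#' @return augmented patch, same shape.
#' @export
augment_patch <- function(p, spec, geometric = NULL) {
  d <- dim(p)
  stopifnot(length(d) == 3L, d[3] == 3L)
  sigma <- stats::runif(1, spec$blur_sigma_range[1], spec$blur_sigma_range[2])
  if (sigma > 1e-3) p <- gaussian_blur(p, sigma)
  n_sp <- round(spec$sp_density * d[1] * d[2])
  if (n_sp > 0) {
    loc <- sample.int(d[1] * d[2], n_sp)
    val <- stats::rbinom(n_sp, 1, 0.5)
    hw <- d[1] * d[2]
    for (ch in 1:3) p[loc + (ch - 1L) * hw] <- val
  }
  if (is.null(geometric)) geometric <- draw_geometric(spec)
  p <- apply_geometric(p, geometric, spec)
  pmin(pmax(p, 0), 1)
}

#' Augment a whole patch sequence
#'
#' Same length, order, label and identity; each patch is augmented
#' (independently unless `geometric_per_sequence`); the result is flagged
#' `augmented = TRUE`. Augmenting an already-augmented sequence is an error.
#'
#' @param s a [patch_sequence()] with `augmented = FALSE`.
#' @param spec an [augment_spec()].
#' @return augmented [patch_sequence()].
#' @export
augment_sequence <- function(s, spec) {
  if (s$augmented)
    stop_gpn("gpn_usage_error", "sequence %s/%d is already augmented",
             s$participant_id, s$trial_id)
  run <- function() {
    shared <- if (spec$geometric_per_sequence) draw_geometric(spec) else NULL
    patches <- lapply(s$patches, augment_patch, spec = spec, geometric = shared)
    patch_sequence(patches, s$meta, s$participant_id, s$trial_id, s$label,
                   augmented = TRUE)
  }
  if (!is.null(spec$seed))
    with_local_seed(derive_seed(spec$seed, seq_tag(s)), run())
  else run()
}

#' Double a dataset by adding one augmented copy of every sequence
#'
#' @param seqs list of non-augmented [patch_sequence()].
#' @param spec an [augment_spec()]; `spec$seed` makes the result
#'   deterministic.
#' @return list of length `2 * length(seqs)`: the originals followed by
#'   their augmented copies in the same order.
#' @export
augment_dataset <- function(seqs, spec) {
  if (any(vapply(seqs, `[[`, FALSE, "augmented")))
    stop_gpn("gpn_usage_error", "input sequences must not be augmented already")
  c(seqs, lapply(seqs, augment_sequence, spec = spec))
}
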