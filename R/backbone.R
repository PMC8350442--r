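# Pluggable CNN feature backbones.
#
# A backbone maps one 224 x 224 x 3 patch to a length-1,024 feature vector
# and owns its own preprocessing contract. Two backbones are registered:
#   * "googlenet-pool5": the GoogLeNet architecture truncated at its last
#     (global average) pooling layer -- the fidelity default;
#   * "toy": a fixed, seeded deterministic map (pooled local image
#     statistics projected to 1,024 dimensions) that needs no network
#     weights and runs orders of magnitude faster; the test-suite default.

#' Backbone specification
#'
#' @param name registered backbone identifier: `"toy"` or
#'   `"googlenet-pool5"`.
#' @param output_dim expected feature dimension (default 1024); asserted at
#'   load time.
#' @param seed seed for weight initialization of the GoogLeNet-architecture
#'   backbone and for the toy projection.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "googlenet-pool5", output_dim = 1024L,
                          seed = 20210726L) {
  structure(list(name = name, output_dim = as.integer(output_dim),
                 seed = as.integer(seed)),
            class = "backbone_spec")
}

#' Load a feature-extraction backbone
#'
#' @param spec a [backbone_spec()] or a backbone name string.
#' @return object of class `gpn_backbone` with elements `name`,
#'   `output_dim` and `forward(patch)`.
#' @export
load_backbone <- function(spec = backbone_spec()) {
  if (is.character(spec)) spec <- backbone_spec(name = spec)
  bb <- switch(spec$name,
    "toy" = toy_backbone(spec$seed),
    "googlenet-pool5" = googlenet_backbone(spec$seed),
    stop_gpn("gpn_config_error", "unknown backbone '%s' (registered: %s)",
             spec$name, "toy, googlenet-pool5"))
  if (bb$output_dim != spec$output_dim)
    stop_gpn("gpn_config_error",
             "backbone '%s' emits %d dimensions, spec expects %d",
             spec$name, bb$output_dim, spec$output_dim)
  bb
}

#' @export
print.gpn_backbone <- function(x, ...) {
  cat(sprintf("<gpn_backbone '%s'> 224x224x3 -> %d\n", x$name, x$output_dim))
  invisible(x)
}

# Foveated pooled statistics: per-channel cell means and standard
# deviations over concentric grids -- the full patch (7 x 7 cells), the
# central half (5 x 5), the central quarter (3 x 3) and the innermost
# sixteenth (1 cell) -- projected to 1,024 dimensions by a fixed sparse
# sign projection (every output dimension is a signed copy of one pooled
# statistic; with ~3x oversampling each statistic survives with high
# probability). The fixated object sits at the patch center by
# construction, so center-weighted pooling preserves its signature instead
# of diluting it across the wide equirectangular crop; the sparse
# projection keeps the statistics axis-aligned, which downstream models
# can exploit at small sample sizes. Deterministic per seed.
toy_backbone <- function(seed = 20210726L) {
  scales <- list(list(frac = 1, grid = 7L), list(frac = 0.5, grid = 5L),
                 list(frac = 0.25, grid = 3L), list(frac = 0.125, grid = 1L))
  dim_out <- 1024L
  n_stats <- sum(vapply(scales, function(s) 2 * 3 * s$grid^2, 0))
  proj <- with_local_seed(derive_seed(seed, "toy-proj"), {
    P <- matrix(0, dim_out, n_stats)
    pick <- c(seq_len(n_stats),                       # every stat at least once
              sample.int(n_stats, dim_out - n_stats, replace = TRUE))
    P[cbind(seq_len(dim_out), pick)] <- sample(c(-1, 1), dim_out, replace = TRUE)
    P
  })
  agg <- function(n, grid) {
    if (grid == 1L) return(matrix(1 / n, n, 1))
    cell <- as.integer(cut(seq_len(n), grid, labels = FALSE))
    A <- matrix(0, n, grid)
    A[cbind(seq_len(n), cell)] <- 1
    sweep(A, 2, colSums(A), "/")
  }
  forward <- function(patch) {
    d <- dim(patch)
    if (length(d) != 3L || d[3] != 3L)
      stop_gpn("gpn_data_error", "backbone input must be H x W x 3")
    stats_v <- numeric(n_stats)
    k <- 0L
    for (sc in scales) {
      rr <- center_span(d[1], sc$frac); cc <- center_span(d[2], sc$frac)
      Ar <- agg(length(rr), sc$grid); Ac <- agg(length(cc), sc$grid)
      for (ch in 1:3) {
        pl <- patch[rr, cc, ch]
        mu <- crossprod(Ar, pl) %*% Ac
        m2 <- crossprod(Ar, pl^2) %*% Ac
        g2 <- sc$grid^2
        stats_v[k + seq_len(g2)] <- as.vector(mu) - 0.5
        stats_v[k + g2 + seq_len(g2)] <- sqrt(pmax(as.vector(m2 - mu^2), 0))
        k <- k + 2L * g2
      }
    }
    as.vector(proj %*% stats_v)
  }
  structure(list(name = "toy", output_dim = dim_out, forward = forward),
            class = "gpn_backbone")
}

center_span <- function(n, frac) {
  m <- max(1L, round(n * frac))
  start <- (n - m) %/% 2L + 1L
  start:(start + m - 1L)
}

googlenet_backbone <- function(seed = 20210726L) {
  params <- googlenet_init(seed)
  structure(list(name = "googlenet-pool5",
                 output_dim = attr(params, "output_dim"),
                 forward = function(patch) googlenet_forward(params, patch)),
            class = "gpn_backbone")
}

#' Construct a feature sequence
#'
#' @param features `T x D` numeric matrix of per-patch feature vectors.
#' @param participant_id,trial_id,label sequence identity and class code.
#' @param augmented logical augmentation flag.
#' @return object of class `feature_sequence`.
#' @export
feature_sequence <- function(features, participant_id, trial_id, label,
                             augmented = FALSE) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop_gpn("gpn_data_error", "non-finite feature values in %s/%s",
             participant_id, trial_id)
  structure(list(features = features,
                 participant_id = as.character(participant_id),
                 trial_id = as.integer(trial_id), label = as.integer(label),
                 augmented = isTRUE(augmented)),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> participant %s trial %d label %d: %d x %d%s\n",
              x$participant_id, x$trial_id, x$label, nrow(x$features),
              ncol(x$features), if (x$augmented) " (augmented)" else ""))
  invisible(x)
}

#' Convert patch sequences to feature sequences
#'
#' Feeds every patch through the backbone; order, labels, lengths and
#' augmentation flags are preserved.
#'
#' @param seqs list of [patch_sequence()].
#' @param backbone a loaded [load_backbone()] handle.
#' @return list of [feature_sequence()] (`T x output_dim` each).
#' @export
featurize <- function(seqs, backbone) {
  lapply(seqs, function(s) {
    mat <- matrix(0, length(s$patches), backbone$output_dim)
    for (i in seq_along(s$patches)) {
      p <- s$patches[[i]]
      if (length(dim(p)) != 3L || dim(p)[3] != 3L)
        stop_gpn("gpn_data_error",
                 "malformed patch %d in sequence %s/%d", i,
                 s$participant_id, s$trial_id)
      mat[i, ] <- backbone$forward(p)
    }
    feature_sequence(mat, s$participant_id, s$trial_id, s$label, s$augmented)
  })
}

#' Persist feature sequences as TSV matrices plus JSON manifests
#'
#' @param fseqs list of [feature_sequence()].
#' @param dir output directory.
#' @param backbone_name recorded in each manifest.
#' @return manifest paths, invisibly.
#' @export
write_feature_sequences <- function(fseqs, dir, backbone_name = "unknown") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(fseqs, function(s) {
    tag <- seq_tag(s)
    df <- sprintf("%s_features.tsv", tag)
    utils::write.table(s$features, file.path(dir, df), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    mp <- file.path(dir, sprintf("%s.json", tag))
    jsonlite::write_json(list(participant_id = s$participant_id,
                              trial_id = s$trial_id, label = s$label,
                              augmented = s$augmented, file = df,
                              backbone = backbone_name),
                         mp, auto_unbox = TRUE, digits = NA)
    mp
  }, "")
  invisible(paths)
}

#' Load feature sequences written by [write_feature_sequences()]
#'
#' @param dir directory of manifests and TSV matrices.
#' @return list of [feature_sequence()].
#' @export
read_feature_sequences <- function(dir) {
  mans <- sort(list.files(dir, pattern = "_(orig|aug)\\.json$",
                          full.names = TRUE))
  lapply(mans, function(mp) {
    man <- jsonlite::fromJSON(mp)
    mat <- as.matrix(utils::read.table(file.path(dir, man$file), sep = "\t"))
    dimnames(mat) <- NULL
    feature_sequence(mat, man$participant_id, man$trial_id, man$label,
                     man$augmented)
  })
}
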