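# Pipeline orchestration: staged, manifest-driven processing.
#
# Stages (simulate -> extract -> augment -> featurize -> evaluate) hand
# off through on-disk artifacts plus a JSON stage manifest embedding the
# configuration fingerprint; a stage refuses to consume manifests written
# under a different configuration. `run_cohort_evaluation()` is the
# in-memory fast path over the same functions: it streams each trial
# through extraction, augmentation and featurization, keeping only the
# feature sequences, and then runs the leave-one-participant-out protocol.

#' Pipeline configuration
#'
#' Collects every stage's parameters; defaults reproduce the published
#' protocol constants (50 deg/s I-VT threshold, 75% tracking-ratio cutoff,
#' 224 px patches, augmentation ranges, architecture and training
#' options).
#'
#' @param workdir working directory for stage artifacts.
#' @param ivt_threshold I-VT velocity threshold in degrees/second.
#' @param validity_threshold minimum (strict) tracking ratio.
#' @param patch_size patch side length in pixels.
#' @param augment an [augment_spec()].
#' @param backbone a [backbone_spec()] or backbone name.
#' @param model a [gazenet_config()].
#' @param train a [gazenet_control()].
#' @param fixture a [fixture_spec()] for the simulate stage.
#' @param val_frac validation fraction of the inner split.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(workdir = tempfile("gpn_work"),
                            ivt_threshold = 50, validity_threshold = 0.75,
                            patch_size = 224L, augment = augment_spec(),
                            backbone = backbone_spec(),
                            model = gazenet_config(),
                            train = gazenet_control(),
                            fixture = fixture_spec(), val_frac = 0.3,
                            seed = 42L) {
  if (ivt_threshold <= 0)
    stop_gpn("gpn_config_error", "ivt_threshold must be positive (got %g)",
             ivt_threshold)
  if (validity_threshold < 0 || validity_threshold > 1)
    stop_gpn("gpn_config_error", "validity_threshold must lie in [0,1]")
  if (is.character(backbone)) backbone <- backbone_spec(name = backbone)
  cfg <- structure(list(workdir = workdir, ivt_threshold = ivt_threshold,
                        validity_threshold = validity_threshold,
                        patch_size = as.integer(patch_size), augment = augment,
                        backbone = backbone, model = model, train = train,
                        fixture = fixture, val_frac = val_frac,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), c("workdir", "hash"))])
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    workdir = raw$workdir %||% tempfile("gpn_work"),
    ivt_threshold = raw$ivt_threshold, validity_threshold = raw$validity_threshold,
    patch_size = raw$patch_size,
    augment = do.call(augment_spec, raw$augment[setdiff(names(raw$augment), "geometric_per_sequence")]),
    backbone = do.call(backbone_spec, raw$backbone),
    model = do.call(gazenet_config, raw$model),
    train = do.call(gazenet_control, raw$train[setdiff(names(raw$train), c("val_loss_fn", "optimizer"))]),
    fixture = do.call(fixture_spec, raw$fixture[setdiff(names(raw$fixture), "class_profiles")]),
    val_frac = raw$val_frac, seed = raw$seed)
}

stage_manifest_path <- function(config, stage)
  file.path(config$workdir, sprintf("%s_manifest.json", stage))

write_stage_manifest <- function(config, stage, info) {
  jsonlite::write_json(c(list(stage = stage, config_hash = config$hash), info),
                       stage_manifest_path(config, stage), auto_unbox = TRUE,
                       digits = NA)
}

require_stage <- function(config, stage) {
  mp <- stage_manifest_path(config, stage)
  if (!file.exists(mp))
    stop_gpn("gpn_config_error",
             "stage '%s' has not run (expected manifest %s)", stage, mp)
  man <- jsonlite::fromJSON(mp)
  if (!identical(man$config_hash, config$hash))
    stop_gpn("gpn_config_error",
             "stage '%s' artifacts were written under config %s, current is %s",
             stage, man$config_hash, config$hash)
  man
}

#' Run pipeline stages
#'
#' @param config a [pipeline_config()].
#' @param stages subset of simulate, extract, augment, featurize, evaluate
#'   (in order).
#' @return for runs ending in "evaluate", the [eval_report()]; otherwise
#'   the last stage's manifest info, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "augment",
                                    "featurize", "evaluate")) {
  stages <- match.arg(stages, c("simulate", "extract", "augment", "featurize",
                                "evaluate"), several.ok = TRUE)
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  out <- NULL
  for (stage in stages) {
    message(sprintf("[gazepatchnet] stage %s", stage))
    out <- switch(stage,
      simulate = stage_simulate(config),
      extract = stage_extract(config),
      augment = stage_augment(config),
      featurize = stage_featurize(config),
      evaluate = stage_evaluate(config))
  }
  if (identical(stages[length(stages)], "evaluate")) out else invisible(out)
}

stage_simulate <- function(config) {
  gdir <- file.path(config$workdir, "gaze")
  cohort <- generate_cohort(config$fixture, dir = gdir)
  write_stage_manifest(config, "simulate",
                       list(n_trials = length(cohort$trials),
                            gaze = file.path(gdir, "gaze.csv"),
                            manifest = file.path(gdir, "manifest.json")))
  invisible(cohort)
}

stage_extract <- function(config) {
  man <- require_stage(config, "simulate")
  trials <- read_trials(man$gaze, man$manifest)
  n_read <- length(trials)
  trials <- filter_valid(trials, config$validity_threshold)
  videos <- lapply(seq_len(config$fixture$n_videos), function(vid)
    generate_video(config$fixture, vid))
  seqs <- build_sequences(trials, videos, config$ivt_threshold,
                          config$patch_size)
  pdir <- file.path(config$workdir, "patches")
  write_patch_sequences(seqs, pdir)
  write_stage_manifest(config, "extract",
                       list(n_read = n_read, n_valid = length(trials),
                            n_sequences = length(seqs), dir = pdir))
  invisible(seqs)
}

stage_augment <- function(config) {
  man <- require_stage(config, "extract")
  seqs <- read_patch_sequences(man$dir)
  seqs <- seqs[!vapply(seqs, `[[`, FALSE, "augmented")]
  aug <- lapply(seqs, augment_sequence, spec = config$augment)
  write_patch_sequences(aug, man$dir)
  write_stage_manifest(config, "augment",
                       list(n_augmented = length(aug), dir = man$dir,
                            seed = config$augment$seed))
  invisible(aug)
}

stage_featurize <- function(config) {
  man <- require_stage(config, "augment")
  seqs <- read_patch_sequences(man$dir)
  backbone <- load_backbone(config$backbone)
  fseqs <- featurize(seqs, backbone)
  fdir <- file.path(config$workdir, "features")
  write_feature_sequences(fseqs, fdir, backbone$name)
  write_stage_manifest(config, "featurize",
                       list(n_sequences = length(fseqs), dir = fdir,
                            backbone = backbone$name))
  invisible(fseqs)
}

stage_evaluate <- function(config) {
  man <- require_stage(config, "featurize")
  fseqs <- read_feature_sequences(man$dir)
  is_aug <- vapply(fseqs, `[[`, FALSE, "augmented")
  results <- lopo_runs(fseqs[!is_aug], fseqs[is_aug], config$model,
                       config$train, config$val_frac, seed = config$seed)
  report <- eval_report(results)
  rdir <- file.path(config$workdir, "report")
  dir.create(rdir, showWarnings = FALSE)
  write_eval_report(report, file.path(rdir, "report.json"), results)
  write_stage_manifest(config, "evaluate",
                       list(report = file.path(rdir, "report.json"),
                            mean_accuracy = report$mean_accuracy))
  report
}

#' In-memory cohort evaluation (streaming fast path)
#'
#' Generates the synthetic cohort, streams every trial through fixation
#' detection, patch extraction, augmentation and featurization (patches
#' are discarded as soon as their features exist), then runs the
#' leave-one-participant-out protocol.
#'
#' @param spec a [fixture_spec()].
#' @param backbone a [backbone_spec()], name string or loaded backbone.
#' @param config a [gazenet_config()].
#' @param control a [gazenet_control()].
#' @param augment an [augment_spec()]; NULL disables augmentation.
#' @param ivt_threshold,validity_threshold,patch_size,val_frac protocol
#'   constants.
#' @param seed global seed for the split/training protocol.
#' @return an [eval_report()].
#' @export
run_cohort_evaluation <- function(spec, backbone = "toy",
                                  config = gazenet_config(),
                                  control = gazenet_control(),
                                  augment = augment_spec(seed = spec$seed),
                                  ivt_threshold = 50,
                                  validity_threshold = 0.75,
                                  patch_size = 224L, val_frac = 0.3,
                                  seed = spec$seed) {
  fs <- cohort_feature_sequences(spec, backbone, augment, ivt_threshold,
                                 validity_threshold, patch_size)
  results <- lopo_runs(fs$orig, fs$aug, config, control, val_frac, seed = seed)
  eval_report(results)
}

#' Featurize a synthetic cohort trial-by-trial
#'
#' @inheritParams run_cohort_evaluation
#' @return list with `orig` and `aug` feature-sequence lists.
#' @export
cohort_feature_sequences <- function(spec, backbone = "toy",
                                     augment = augment_spec(seed = spec$seed),
                                     ivt_threshold = 50,
                                     validity_threshold = 0.75,
                                     patch_size = 224L) {
  cohort <- generate_cohort(spec)
  if (inherits(backbone, "gpn_backbone")) bb <- backbone
  else bb <- load_backbone(backbone)
  trials <- filter_valid(cohort$trials, validity_threshold)
  lookup <- video_lookup(cohort$videos, trials)
  orig <- list(); aug <- list()
  for (tr in trials) {
    seqs <- suppressWarnings(
      build_sequences(list(tr), lookup, ivt_threshold, patch_size))
    if (!length(seqs)) next
    orig[[length(orig) + 1L]] <- featurize(seqs, bb)[[1L]]
    if (!is.null(augment)) {
      aseq <- augment_sequence(seqs[[1L]], augment)
      aug[[length(aug) + 1L]] <- featurize(list(aseq), bb)[[1L]]
    }
  }
  list(orig = orig, aug = if (is.null(augment)) NULL else aug)
}
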