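# Leave-one-participant-out evaluation and pooled metrics.
#
# One run per participant: that participant's original sequences are held
# out entirely; the remaining participants' originals are split 70:30
# (stratified by class) into training and validation; augmented copies
# join ONLY the training side; training classes are balanced by
# undersampling; the fitted model predicts the held-out originals.
# Metrics pool all held-out predictions across runs: 3x3 confusion
# (rows = true), per-class recall, one-vs-rest ROC/AUC, plus the
# unweighted mean of per-run accuracies (reported separately from the
# pooled confusion-matrix accuracy; the two need not agree).

#' Run the leave-one-participant-out protocol
#'
#' @param fseqs list of original (non-augmented) [feature_sequence()].
#' @param augmented optional list of augmented copies, matched to originals
#'   by (participant, trial); they are used only inside training sets.
#' @param config a [gazenet_config()].
#' @param control a [gazenet_control()].
#' @param val_frac fraction of the remaining data assigned to validation
#'   (default 0.3).
#' @param stratify stratify the split by class (default TRUE; prevents
#'   degenerate single-class validation sets at small cohort sizes).
#' @param drop_frac longest-sequence removal fraction applied once, before
#'   any split.
#' @param seed global seed; per-run seeds derive deterministically from
#'   (seed, participant ID).
#' @return list of run results, each with `participant`, `truth`, `pred`,
#'   `scores`, `accuracy`.
#' @export
lopo_runs <- function(fseqs, augmented = NULL, config = gazenet_config(),
                      control = gazenet_control(), val_frac = 0.3,
                      stratify = TRUE, drop_frac = 0.02, seed = 1L) {
  if (any(vapply(fseqs, `[[`, FALSE, "augmented")))
    stop_gpn("gpn_usage_error", "fseqs must be the original sequences")
  participants <- unique(vapply(fseqs, `[[`, "", "participant_id"))
  if (length(participants) < 2L)
    stop_gpn("gpn_data_error", "leave-one-participant-out needs >= 2 participants")

  prep <- prepare_sequences(fseqs, drop_frac)
  pool <- prep$sequences
  aug_key <- function(s) paste(s$participant_id, s$trial_id, sep = "\r")
  aug_map <- if (!is.null(augmented))
    stats::setNames(augmented, vapply(augmented, aug_key, "")) else NULL

  pids <- vapply(pool, `[[`, "", "participant_id")
  labs <- vapply(pool, `[[`, 0L, "label")
  results <- list()
  for (p in participants) {
    test <- pool[pids == p]
    if (!length(test)) {
      warning(sprintf("participant %s has no valid sequences; skipped", p))
      next
    }
    rest_idx <- which(pids != p)
    run_seed <- derive_seed(seed, paste0("run-", p))
    val_idx <- with_local_seed(run_seed, {
      if (stratify) {
        unlist(lapply(unique(labs[rest_idx]), function(k) {
          idx <- rest_idx[labs[rest_idx] == k]
          sample(idx, max(1L, round(val_frac * length(idx))))
        }))
      } else sample(rest_idx, max(1L, round(val_frac * length(rest_idx))))
    })
    train_idx <- setdiff(rest_idx, val_idx)
    train <- pool[train_idx]
    if (!is.null(aug_map)) {
      copies <- aug_map[vapply(train, aug_key, "")]
      train <- c(train, copies[!vapply(copies, is.null, FALSE)])
    }
    train <- balance_classes(train, seed = run_seed)
    train <- train[order(vapply(train, function(s) nrow(s$features), 0L))]
    model <- gazenet(train, validation = pool[val_idx], config = config,
                     control = control, seed = run_seed)
    scores <- predict(model, test, type = "prob")
    pred <- max.col(scores, ties.method = "first") - 1L
    truth <- vapply(test, `[[`, 0L, "label")
    seq_id <- function(s) sprintf("%s/%d/%s", s$participant_id, s$trial_id,
                                  if (s$augmented) "aug" else "orig")
    results[[length(results) + 1L]] <-
      structure(list(participant = p, truth = truth, pred = pred,
                     scores = scores,
                     trial_ids = vapply(test, `[[`, 0L, "trial_id"),
                     test_ids = vapply(test, seq_id, ""),
                     train_ids = vapply(train, seq_id, ""),
                     val_ids = vapply(pool[val_idx], seq_id, ""),
                     accuracy = mean(pred == truth)),
                class = "gpn_run_result")
  }
  results
}

#' Pooled confusion matrix, per-class recall and accuracies
#'
#' Accepts either a list of run results from [lopo_runs()] (predictions are
#' pooled across runs) or a ready 3x3 count matrix (rows = true class,
#' columns = predicted class, order novice/advanced/expert).
#'
#' @param results run-result list or 3x3 matrix.
#' @return list with `confusion`, `per_class_recall` (fractions),
#'   `mean_accuracy` (unweighted mean of run accuracies; equals the pooled
#'   accuracy for matrix input) and `pooled_accuracy` (trace / total).
#' @export
confusion_and_recall <- function(results) {
  if (is.matrix(results)) {
    conf <- results
    stopifnot(all(dim(conf) == c(3, 3)))
    run_acc <- sum(diag(conf)) / sum(conf)
  } else {
    if (!length(results))
      stop_gpn("gpn_data_error", "no run results")
    truth <- unlist(lapply(results, `[[`, "truth"))
    pred <- unlist(lapply(results, `[[`, "pred"))
    conf <- table(factor(truth, 0:2), factor(pred, 0:2))
    conf <- matrix(as.integer(conf), 3, 3)
    run_acc <- mean(vapply(results, `[[`, 0, "accuracy"))
  }
  dimnames(conf) <- list(true = EXPERTISE_LEVELS, predicted = EXPERTISE_LEVELS)
  rs <- rowSums(conf)
  recall <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  names(recall) <- EXPERTISE_LEVELS
  list(confusion = conf, per_class_recall = recall,
       mean_accuracy = run_acc, pooled_accuracy = sum(diag(conf)) / sum(conf))
}

# Binary ROC by threshold sweep with tie grouping; trapezoidal AUC.
binary_roc <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- positive[ord]
  grp_last <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(!y)[grp_last]
  P <- sum(positive); N <- sum(!positive)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and AUC over pooled predictions
#'
#' For each class, labels are binarized (class vs rest) and the ROC curve
#' swept over that class's score column, grouping tied scores; AUC by
#' trapezoidal integration. A class absent from the pooled truth gets
#' `NA` AUC.
#'
#' @param results run-result list from [lopo_runs()], or a list with
#'   elements `truth` (codes 0..2) and `scores` (n x 3 matrix).
#' @return list per class: `fpr`, `tpr`, `auc`.
#' @export
roc_auc_ovr <- function(results) {
  if (!is.null(results$truth)) {
    truth <- results$truth; scores <- results$scores
  } else {
    truth <- unlist(lapply(results, `[[`, "truth"))
    scores <- do.call(rbind, lapply(results, `[[`, "scores"))
  }
  out <- lapply(0:2, function(k) {
    pos <- truth == k
    if (!any(pos) || all(pos))
      return(list(fpr = NULL, tpr = NULL, auc = NA_real_))
    binary_roc(scores[, k + 1L], pos)
  })
  names(out) <- EXPERTISE_LEVELS
  out
}

#' Assemble the full evaluation report
#'
#' @param results run-result list from [lopo_runs()].
#' @return object of class `gpn_eval_report` with the pooled confusion,
#'   per-class recalls, ROC/AUC, per-run accuracies and both accuracy
#'   summaries.
#' @export
eval_report <- function(results) {
  cr <- confusion_and_recall(results)
  roc <- roc_auc_ovr(results)
  structure(list(confusion = cr$confusion,
                 per_class_recall = cr$per_class_recall,
                 roc = roc,
                 auc = vapply(roc, `[[`, 0, "auc"),
                 mean_accuracy = cr$mean_accuracy,
                 pooled_accuracy = cr$pooled_accuracy,
                 run_accuracies = vapply(results, `[[`, 0, "accuracy"),
                 participants = vapply(results, `[[`, "", "participant")),
            class = "gpn_eval_report")
}

#' @export
print.gpn_eval_report <- function(x, ...) {
  cat(sprintf("Leave-one-participant-out evaluation: %d runs, %d pooled samples\n",
              length(x$run_accuracies), sum(x$confusion)))
  cat(sprintf("  mean run accuracy:   %.2f%%\n", 100 * x$mean_accuracy))
  cat(sprintf("  pooled accuracy:     %.2f%%\n", 100 * x$pooled_accuracy))
  cat("  per-class recall:    ",
      paste(sprintf("%s %.1f%%", names(x$per_class_recall),
                    100 * x$per_class_recall), collapse = ", "), "\n")
  cat("  one-vs-rest AUC:     ",
      paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report (and pooled predictions) to disk
#'
#' @param report a `gpn_eval_report`.
#' @param results the run-result list it came from (for the prediction CSV);
#'   optional.
#' @param path output JSON path; the CSV lands next to it.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, results = NULL) {
  payload <- list(confusion = unclass(report$confusion),
                  per_class_recall = report$per_class_recall,
                  auc = report$auc,
                  mean_accuracy = report$mean_accuracy,
                  pooled_accuracy = report$pooled_accuracy,
                  run_accuracies = report$run_accuracies,
                  participants = report$participants)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(results)) {
    df <- do.call(rbind, lapply(results, function(r)
      data.frame(participant = r$participant, trial_id = r$trial_ids,
                 truth = r$truth, pred = r$pred,
                 p_novice = r$scores[, 1], p_advanced = r$scores[, 2],
                 p_expert = r$scores[, 3])))
    utils::write.csv(df, sub("\\.json$", "_predictions.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
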