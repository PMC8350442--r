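make_run <- function(participant, truth, pred, scores = NULL) {
  if (is.null(scores)) {
    scores <- matrix(0, length(truth), 3)
    scores[cbind(seq_along(pred), pred + 1)] <- 1
  }
  structure(list(participant = participant, truth = truth, pred = pred,
                 scores = scores, trial_ids = seq_along(truth),
                 accuracy = mean(truth == pred)),
            class = "gpn_run_result")
}

test_that("a perfect predictor yields an identity-structured confusion", {
  runs <- lapply(1:3, function(i) make_run(paste0("p", i), 0:2, 0:2))
  cr <- confusion_and_recall(runs)
  expect_equal(unname(diag(cr$confusion)), c(3, 3, 3))
  expect_equal(sum(cr$confusion) - sum(diag(cr$confusion)), 0)
  expect_equal(unname(cr$per_class_recall), c(1, 1, 1))
  expect_equal(cr$mean_accuracy, 1)
  expect_equal(cr$pooled_accuracy, 1)
})

test_that("matrix input and expanded run results agree", {
  conf <- matrix(c(50, 10, 5,
                   8, 60, 7,
                   2, 4, 70), 3, 3, byrow = TRUE)
  truth <- integer(0); pred <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    truth <- c(truth, rep(i - 1, conf[i, j]))
    pred <- c(pred, rep(j - 1, conf[i, j]))
  }
  from_runs <- confusion_and_recall(list(make_run("p1", truth, pred)))
  from_mat <- confusion_and_recall(conf)
  expect_equal(unclass(from_runs$confusion), unclass(from_mat$confusion),
               ignore_attr = TRUE)
  expect_equal(from_runs$per_class_recall, from_mat$per_class_recall)
  expect_equal(from_mat$pooled_accuracy, sum(diag(conf)) / sum(conf))
})

test_that("one-hot scores give AUC 1 and label-free scores give AUC ~0.5", {
  truth <- rep(0:2, each = 20)
  one_hot <- matrix(0, 60, 3); one_hot[cbind(1:60, truth + 1)] <- 1
  roc <- roc_auc_ovr(list(truth = truth, scores = one_hot))
  expect_equal(vapply(roc, `[[`, 0, "auc"), c(novice = 1, advanced = 1,
                                              expert = 1))

  set.seed(8)
  n <- 10000
  truth_r <- sample(0:2, n, replace = TRUE)
  scores_r <- matrix(runif(3 * n), n, 3)
  roc_r <- roc_auc_ovr(list(truth = truth_r, scores = scores_r))
  for (k in 1:3) {
    n1 <- sum(truth_r == k - 1); n2 <- n - n1
    se <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
    expect_lt(abs(roc_r[[k]]$auc - 0.5), 1.96 * se)
  }
})

test_that("AUC equals Mann-Whitney pair counting and is rank-invariant", {
  set.seed(12)
  n <- 200
  truth <- rbinom(n, 1, 0.4)
  score <- round(rnorm(n, truth, 1), 1)          # rounding forces ties
  got <- binary_roc(score, truth == 1)$auc
  pos <- score[truth == 1]; neg <- score[truth == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got, mean(pairs), tolerance = 1e-12)
  # strictly monotone transform leaves the AUC untouched
  expect_equal(binary_roc(exp(2 * score), truth == 1)$auc, got,
               tolerance = 1e-12)
  # independent implementation agrees
  skip_if_not_installed("pROC")
  proc_auc <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                             direction = "<")))
  expect_equal(got, proc_auc, tolerance = 1e-12)
})

test_that("an absent class reports a missing AUC", {
  truth <- rep(c(0, 1), 10)
  scores <- matrix(runif(60), 20, 3)
  roc <- roc_auc_ovr(list(truth = truth, scores = scores))
  expect_true(is.na(roc$expert$auc))
  expect_false(is.na(roc$novice$auc))
})

test_that("LOPO runs once per participant with no identity leakage", {
  set.seed(21)
  # 6 participants x 6 original sequences, synthetic separable features
  fs <- sep_feature_seqs(12, dim = 16, per_participant = 6)
  aug <- lapply(fs, function(s) feature_sequence(
    s$features + matrix(rnorm(length(s$features), 0, 0.01), nrow(s$features)),
    s$participant_id, s$trial_id, s$label, augmented = TRUE))
  cfg <- gazenet_config(input_dim = 16, hidden = 4, fc = 3)
  ctl <- gazenet_control(max_epochs = 1, validation_frequency = 52)
  res <- lopo_runs(fs, aug, cfg, ctl, seed = 2)
  expect_length(res, 6)
  held <- vapply(res, `[[`, "", "participant")
  expect_setequal(held, unique(vapply(fs, `[[`, "", "participant_id")))
  for (r in res) {
    expect_length(intersect(r$test_ids, c(r$train_ids, r$val_ids)), 0)
    expect_false(any(grepl(paste0("^", r$participant, "/"),
                           c(r$train_ids, r$val_ids))))
    expect_false(any(grepl("/aug$", r$val_ids)))     # augmented never validate
    expect_false(any(grepl("/aug$", r$test_ids)))    # held-out are originals
    expect_true(all(r$scores >= 0) && all(abs(rowSums(r$scores) - 1) < 1e-6))
  }
})

test_that("a 33-participant cohort yields 33 runs", {
  set.seed(33)
  fs <- sep_feature_seqs(33, dim = 8, per_participant = 3)  # 11 participants/class
  expect_length(unique(vapply(fs, `[[`, "", "participant_id")), 33)
  cfg <- gazenet_config(input_dim = 8, hidden = 2, fc = 2)
  ctl <- gazenet_control(max_epochs = 1, validation_frequency = 52)
  res <- lopo_runs(fs, NULL, cfg, ctl, seed = 1)
  expect_length(res, 33)
})

test_that("eval_report pools counts conservatively and prints", {
  runs <- list(make_run("a", c(0, 1, 2, 2), c(0, 1, 1, 2)),
               make_run("b", c(0, 0, 1), c(2, 0, 1)))
  rep <- eval_report(runs)
  expect_equal(sum(rep$confusion), 7)
  expect_equal(unname(rowSums(rep$confusion)), c(3, 2, 2))
  expect_equal(rep$mean_accuracy, mean(c(3 / 4, 2 / 3)))
  expect_equal(rep$pooled_accuracy, 5 / 7)
  expect_output(print(rep), "pooled accuracy")
  dir <- withr::local_tempdir()
  write_eval_report(rep, file.path(dir, "report.json"), runs)
  back <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(back$pooled_accuracy, 5 / 7, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "report_predictions.csv")))
})
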