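test_that("softmax output is normalized and untrained zeroed head is uniform", {
  cfg <- gazenet_config(input_dim = 12, hidden = 5, fc = 4)
  m <- gazenet_build(cfg, seed = 1)
  xs <- list(matrix(rnorm(36), 3, 12), matrix(rnorm(12), 1, 12))
  pr <- predict(m, xs)
  expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-6)
  expect_true(all(pr >= 0))

  m$params$W2[] <- 0; m$params$b2[] <- 0
  pr0 <- predict(m, xs)
  expect_equal(as.vector(pr0), rep(1 / 3, 6), tolerance = 1e-12)
  # argmax ties resolve to the lowest class index
  expect_equal(predict(m, xs, type = "class"), c(0L, 0L))
})

test_that("prediction is deterministic (dropout off) and padding-invariant", {
  cfg <- gazenet_config(input_dim = 8, hidden = 6, fc = 5, dropout = 0.5)
  m <- gazenet_build(cfg, seed = 2)
  set.seed(9)
  xs <- lapply(c(2, 9, 5), function(T) matrix(rnorm(T * 8), T, 8))
  expect_identical(predict(m, xs), predict(m, xs))
  # batching with different padding lengths changes nothing
  joint <- predict(m, xs)
  solo <- do.call(rbind, lapply(xs, function(x) predict(m, list(x))))
  expect_equal(joint, solo, tolerance = 1e-12)
})

test_that("cross-entropy of a perfect one-hot prediction is ~0", {
  probs <- diag(3)[c(1, 2, 3, 2), ]
  expect_lte(gazenet_loss(probs, c(0, 1, 2, 1)), 1e-6)
})

test_that("prepare_sequences drops the strictly-longest tail and sorts ascending", {
  mk <- function(T, i) feature_sequence(matrix(0, T, 4), "p", i, 0)
  lens <- c(sample(5:20, 98, replace = TRUE), 40, 45)
  seqs <- Map(mk, lens, seq_along(lens))
  prep <- prepare_sequences(seqs, 0.02)
  expect_length(prep$sequences, 98)               # ceil(2% of 100) = 2 removed
  expect_equal(sort(vapply(prep$dropped, function(s) nrow(s$features), 0L)),
               c(40, 45))
  expect_true(!is.unsorted(prep$lengths))
  expect_equal(prep$max_len, max(prep$lengths))

  # all-equal lengths: nothing is dropped, padding would be a no-op
  eq <- Map(mk, rep(7, 50), 1:50)
  prep_eq <- prepare_sequences(eq, 0.02)
  expect_length(prep_eq$sequences, 50)
  expect_length(prep_eq$dropped, 0)
})

test_that("class balancing undersamples to the minority count, reproducibly", {
  mk <- function(label, i) feature_sequence(matrix(0, 3, 4),
                                            sprintf("p%02d", i), i, label)
  seqs <- c(Map(mk, rep(0, 30), 1:30), Map(mk, rep(1, 20), 31:50),
            Map(mk, rep(2, 10), 51:60))
  bal <- balance_classes(seqs, seed = 4)
  tab <- table(vapply(bal, `[[`, 0L, "label"))
  expect_equal(as.vector(tab), c(10, 10, 10))
  ids <- function(x) vapply(x, `[[`, 0L, "trial_id")
  expect_identical(ids(bal), ids(balance_classes(seqs, seed = 4)))
  expect_false(identical(ids(bal), ids(balance_classes(seqs, seed = 5))))

  already <- seqs[41:60]  # 10 + 10 of classes 1, 2 ... class 0 absent
  expect_error(balance_classes(already, 1), "0", class = "gpn_data_error")
  balanced_in <- c(seqs[1:10], seqs[31:40], seqs[51:60])
  expect_equal(sort(ids(balance_classes(balanced_in, 1))), sort(ids(balanced_in)))
})

test_that("the patience rule halts at exactly the configured check", {
  es <- early_stop_state(6)
  stream <- c(0.9, rep(1.0, 7))
  stopped_at <- NA
  for (i in seq_along(stream)) {
    es <- early_stop_update(es, stream[i])
    if (es$stop) { stopped_at <- i; break }
  }
  expect_equal(stopped_at, 7)   # the 6th consecutive non-improving check
  expect_equal(es$best, 0.9)

  # an improvement resets the strike counter; equality does not
  es2 <- early_stop_state(3)
  for (l in c(1.0, 1.1, 1.1, 0.5, 0.5, 0.6, 0.7)) es2 <- early_stop_update(es2, l)
  expect_true(es2$stop)  # 0.5(tie), 0.6, 0.7 after best 0.5
})

test_that("train executes ceil(N/minibatch) iterations per epoch and is reproducible", {
  set.seed(3)
  mkxy <- function(n) {
    xs <- lapply(seq_len(n), function(i) {
      k <- (i - 1) %% 3
      m <- matrix(rnorm(4 * 6, 0, 0.1), 4, 6); m[, k + 1] <- m[, k + 1] + 1; m
    })
    list(xs = xs, y = (seq_len(n) - 1) %% 3)
  }
  tr <- mkxy(100); va <- mkxy(9)
  cfg <- gazenet_config(input_dim = 6, hidden = 4, fc = 3)
  ctl <- gazenet_control(minibatch = 42, max_epochs = 1,
                         validation_frequency = 52)
  m <- gazenet(tr$xs, tr$y, validation = list(x = va$xs, y = va$y),
               config = cfg, control = ctl, seed = 11)
  expect_equal(m$n_iterations, ceiling(100 / 42))

  ctl2 <- gazenet_control(minibatch = 20, max_epochs = 3,
                          validation_frequency = 5)
  m1 <- gazenet(tr$xs, tr$y, validation = list(x = va$xs, y = va$y),
                config = cfg, control = ctl2, seed = 7)
  m2 <- gazenet(tr$xs, tr$y, validation = list(x = va$xs, y = va$y),
                config = cfg, control = ctl2, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  expect_error(gazenet(tr$xs, tr$y, validation = NULL, config = cfg,
                       control = ctl), class = "gpn_config_error")
})

test_that("training separates a linearly separable cohort", {
  set.seed(31)
  dim <- 64
  mkxy <- function(n_per_class, shift) {
    xs <- list(); y <- integer(0)
    for (k in 0:2) for (i in seq_len(n_per_class)) {
      T <- sample(5:12, 1)
      m <- matrix(rnorm(T * dim, 0, 0.4), T, dim)
      m[, k + 1] <- m[, k + 1] + shift
      xs[[length(xs) + 1]] <- m; y <- c(y, k)
    }
    list(xs = xs, y = y)
  }
  tr <- mkxy(30, 1); va <- mkxy(6, 1)
  # independent linear probe on per-sequence mean features confirms the
  # classes are separable before the network sees them
  probe_x <- t(vapply(tr$xs, colMeans, numeric(dim)))
  probe <- MASS::lda(probe_x, grouping = factor(tr$y))
  expect_gte(mean(predict(probe)$class == factor(tr$y)), 0.95)

  m <- gazenet(tr$xs, tr$y, validation = list(x = va$xs, y = va$y),
               config = gazenet_config(input_dim = dim, hidden = 16, fc = 8),
               control = gazenet_control(validation_frequency = 10,
                                         max_epochs = 25,
                                         learning_rate = 2e-3),
               seed = 3)
  expect_gte(mean(predict(m, tr$xs, type = "class") == tr$y), 0.95)
})

test_that("the scripted-validation hook drives real training shutdown", {
  set.seed(5)
  xs <- lapply(1:10, function(i) matrix(rnorm(12), 3, 4))
  y <- rep(0:1, 5)
  stream <- c(0.9, rep(1.0, 10))
  ctl <- gazenet_control(minibatch = 2, max_epochs = 50,
                         validation_frequency = 1, validation_patience = 6,
                         val_loss_fn = function(params, check) stream[check])
  m <- gazenet(xs, y, validation = NULL,
               config = gazenet_config(input_dim = 4, hidden = 3, fc = 2),
               control = ctl, seed = 1)
  expect_equal(m$stop_reason, "patience")
  expect_equal(nrow(m$history), 7)    # best + 6 non-improving checks
  expect_equal(m$n_iterations, 7)
})
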