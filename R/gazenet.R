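# The sequence classifier: a bidirectional LSTM over per-fixation feature
# vectors.
#
# Layer stack: sequence input (1,024) -> BiLSTM (500 units per direction,
# final step of each direction concatenated to 1,000) -> fully connected
# (100, linear) -> dropout (0.5, training only) -> fully connected (3) ->
# softmax, with multi-class cross-entropy loss. Per direction the LSTM
# holds a 2,000 x 1,024 input-weight block, a 2,000 x 500 recurrent block
# and 2,000 biases; stacking both directions gives the 4,000 x 1,024 /
# 4,000 x 500 / 4,000 x 1 blocks of the combined layer.

#' Model architecture configuration
#'
#' @param input_dim per-step feature dimension (default 1024, the backbone
#'   output).
#' @param hidden LSTM units per direction (default 500; BiLSTM output is
#'   `2 * hidden`).
#' @param fc units of the first fully connected layer (default 100).
#' @param dropout dropout probability after fc-1 (default 0.5, training
#'   time only).
#' @param n_classes number of expertise classes (fixed at 3).
#' @return object of class `gazenet_config`.
#' @export
gazenet_config <- function(input_dim = 1024L, hidden = 500L, fc = 100L,
                           dropout = 0.5, n_classes = 3L) {
  stopifnot(input_dim >= 1, hidden >= 1, fc >= 1, dropout >= 0, dropout < 1)
  if (n_classes != 3L)
    stop_gpn("gpn_config_error", "the expertise problem has exactly 3 classes")
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 fc = as.integer(fc), dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "gazenet_config")
}

#' Training configuration
#'
#' Defaults are the published training options: minibatch 42, constant
#' learning rate 4.4e-4, L2 regularization 8.2e-4 (weight matrices only),
#' validation every 52 iterations, patience 6, at most 100 epochs, no
#' reshuffling between epochs. The optimizer itself is not stated in the
#' protocol; Adam with the constant learning rate is the package default
#' ("sgd" is available).
#'
#' @param minibatch minibatch size.
#' @param learning_rate constant learning rate.
#' @param l2 L2 regularization factor applied to weight matrices.
#' @param validation_frequency iterations between validation-loss checks.
#' @param validation_patience consecutive non-improving checks before
#'   training halts.
#' @param max_epochs maximum number of passes over the training set.
#' @param shuffle reshuffle minibatch order each epoch (default FALSE).
#' @param drop_longest_frac fraction of longest sequences removed by
#'   [prepare_sequences()] (default 0.02).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param checkpoint which parameters the fit returns: `"best"` (the
#'   best-validation-loss checkpoint, the default) or `"final"` (the last
#'   iterate, as MATLAB-style trainers return unless told otherwise).
#'   With few, small validation sets the cross-entropy can rise through
#'   overconfidence while accuracy still improves, making the best-loss
#'   checkpoint an early, undertrained iterate; `"final"` avoids that.
#' @param val_loss_fn optional `function(model_params, check)` overriding
#'   the validation-loss computation (diagnostics and testing).
#' @return object of class `gazenet_control`.
#' @export
gazenet_control <- function(minibatch = 42L, learning_rate = 4.4e-4,
                            l2 = 8.2e-4, validation_frequency = 52L,
                            validation_patience = 6L, max_epochs = 100L,
                            shuffle = FALSE, drop_longest_frac = 0.02,
                            optimizer = c("adam", "sgd"),
                            checkpoint = c("best", "final"),
                            val_loss_fn = NULL) {
  stopifnot(minibatch >= 1, learning_rate > 0, l2 >= 0,
            validation_frequency >= 1, validation_patience >= 1,
            max_epochs >= 1)
  structure(list(minibatch = as.integer(minibatch),
                 learning_rate = learning_rate, l2 = l2,
                 validation_frequency = as.integer(validation_frequency),
                 validation_patience = as.integer(validation_patience),
                 max_epochs = as.integer(max_epochs), shuffle = isTRUE(shuffle),
                 drop_longest_frac = drop_longest_frac,
                 optimizer = match.arg(optimizer),
                 checkpoint = match.arg(checkpoint),
                 val_loss_fn = val_loss_fn),
            class = "gazenet_control")
}

#' Build an untrained model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases with
#' open forget gates) under `seed`.
#'
#' @param config a [gazenet_config()].
#' @param seed integer seed.
#' @return an untrained object of class `gazenet`.
#' @export
gazenet_build <- function(config = gazenet_config(), seed = 1L) {
  if (!inherits(config, "gazenet_config"))
    stop_gpn("gpn_config_error", "config must be a gazenet_config")
  D <- config$input_dim; H <- config$hidden; Fc <- config$fc
  params <- with_local_seed(derive_seed(seed, "init"), {
    fw <- lstm_init(D, H); bw <- lstm_init(D, H)
    r1 <- sqrt(6 / (2 * H + Fc)); r2 <- sqrt(6 / (Fc + config$n_classes))
    list(Wf = fw$W, Uf = fw$U, bf = fw$b,
         Wb = bw$W, Ub = bw$U, bb = bw$b,
         W1 = matrix(stats::runif(Fc * 2 * H, -r1, r1), Fc, 2 * H),
         b1 = rep(0, Fc),
         W2 = matrix(stats::runif(config$n_classes * Fc, -r2, r2),
                     config$n_classes, Fc),
         b2 = rep(0, config$n_classes))
  })
  structure(list(params = params, config = config, seed = as.integer(seed),
                 fitted = FALSE, history = NULL),
            class = "gazenet")
}

# Full forward pass over a list of T_i x D matrices (or a pre-packed
# batch from pack_batch(), so fixed validation sets pack only once).
gazenet_forward <- function(params, xs, dropout = 0, training = FALSE,
                            want_cache = FALSE) {
  pb <- if (is.list(xs) && !is.null(xs$Xm)) xs else pack_batch(xs)
  fw <- lstm_forward_dir(pb$Xm, pb$M, params$Wf, params$Uf, params$bf, want_cache)
  bw <- lstm_forward_dir(pb$Xrm, pb$M, params$Wb, params$Ub, params$bb, want_cache)
  H2 <- cbind(fw$h, bw$h)
  a1 <- H2 %*% t(params$W1) + matrix(params$b1, nrow(H2), length(params$b1),
                                     byrow = TRUE)
  dmask <- NULL
  a1d <- a1
  if (training && dropout > 0) {
    dmask <- matrix(stats::rbinom(length(a1), 1, 1 - dropout), nrow(a1)) /
      (1 - dropout)
    a1d <- a1 * dmask
  }
  logits <- a1d %*% t(params$W2) + matrix(params$b2, nrow(a1d),
                                          length(params$b2), byrow = TRUE)
  out <- list(probs = row_softmax(logits), logits = logits)
  if (want_cache)
    out$cache <- list(fw = fw$cache, bw = bw$cache, H2 = H2, a1d = a1d,
                      dmask = dmask, H = ncol(fw$h))
  out
}

gazenet_loss <- function(probs, y) {
  p <- pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)
  -mean(log(p))
}

# Backward pass; returns gradients named like the parameters.
gazenet_backward <- function(params, fwd, y) {
  cache <- fwd$cache
  B <- nrow(fwd$probs)
  K <- ncol(fwd$probs)
  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (fwd$probs - Y) / B
  dW2 <- crossprod(dlogits, cache$a1d)
  db2 <- colSums(dlogits)
  da1 <- dlogits %*% params$W2
  if (!is.null(cache$dmask)) da1 <- da1 * cache$dmask
  dW1 <- crossprod(da1, cache$H2)
  db1 <- colSums(da1)
  dH2 <- da1 %*% params$W1
  H <- cache$H
  gf <- lstm_backward_dir(cache$fw, dH2[, seq_len(H), drop = FALSE])
  gb <- lstm_backward_dir(cache$bw, dH2[, H + seq_len(H), drop = FALSE])
  list(Wf = gf$dW, Uf = gf$dU, bf = gf$db,
       Wb = gb$dW, Ub = gb$dU, bb = gb$db,
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

L2_PARAMS <- c("Wf", "Uf", "Wb", "Ub", "W1", "W2")

#' Early-stopping monitor
#'
#' Implements the patience rule: training halts when the validation loss is
#' greater than or equal to the previous smallest validation loss at
#' `patience` consecutive checks. `early_stop_update()` consumes one check
#' and returns the updated state with elements `best`, `strikes`, `stop`
#' and `improved`.
#'
#' @param patience consecutive non-improving checks tolerated (default 6).
#' @return for `early_stop_state`, a fresh monitor state.
#' @export
early_stop_state <- function(patience = 6L) {
  list(best = Inf, strikes = 0L, stop = FALSE, improved = FALSE,
       patience = as.integer(patience))
}

#' @rdname early_stop_state
#' @param state a monitor state.
#' @param val_loss validation loss of the current check.
#' @export
early_stop_update <- function(state, val_loss) {
  if (val_loss >= state$best) {
    state$strikes <- state$strikes + 1L
    state$improved <- FALSE
  } else {
    state$strikes <- 0L
    state$improved <- TRUE
  }
  state$best <- min(state$best, val_loss)
  state$stop <- state$strikes >= state$patience
  state
}

#' Fit the BiLSTM expertise classifier
#'
#' Minibatch gradient training with a constant learning rate, L2 penalty on
#' weight matrices, validation-loss checks every
#' `control$validation_frequency` iterations and patience-based early
#' stopping; the parameters of the best-validation-loss checkpoint are
#' returned. Minibatches are consumed in fixed order unless
#' `control$shuffle`.
#'
#' @param x training sequences: a list of [feature_sequence()] objects or
#'   of plain `T x input_dim` matrices.
#' @param y integer class codes (0, 1, 2) when `x` holds plain matrices;
#'   ignored otherwise.
#' @param validation held-out sequences for the validation loss: a list of
#'   [feature_sequence()], or `list(x = , y = )` with plain matrices.
#' @param config a [gazenet_config()].
#' @param control a [gazenet_control()].
#' @param seed integer seed controlling initialization, dropout and any
#'   shuffling; fits are bit-for-bit reproducible given (seed,
#'   single-threaded BLAS).
#' @return a fitted object of class `gazenet` with `params`, `history`
#'   (one row per validation check), `n_iterations` and `stop_reason`.
#' @seealso [predict.gazenet()], [prepare_sequences()], [balance_classes()]
#' @export
gazenet <- function(x, y = NULL, validation = NULL,
                    config = gazenet_config(), control = gazenet_control(),
                    seed = 1L) {
  train <- as_xy(x, y)
  if (is.null(validation) && is.null(control$val_loss_fn))
    stop_gpn("gpn_config_error", "a validation set is required")
  val <- if (!is.null(validation)) as_xy(validation, NULL) else NULL
  if (!is.null(val) && length(val$xs) == 0L)
    stop_gpn("gpn_config_error", "validation set is empty")
  if (any(vapply(train$xs, ncol, 0L) != config$input_dim))
    stop_gpn("gpn_data_error", "training feature dimension != input_dim")

  model <- gazenet_build(config, seed)
  params <- model$params
  n <- length(train$xs)
  mb <- control$minibatch
  n_batches <- ceiling(n / mb)
  opt <- adam_state(params)
  es <- early_stop_state(control$validation_patience)
  best_params <- params
  hist <- list()
  iter <- 0L; check <- 0L; stop_reason <- "max_epochs"
  last_train_loss <- NA_real_

  val_packed <- if (!is.null(val)) pack_batch(val$xs)
  run_check <- function() {
    check <<- check + 1L
    vacc <- NA_real_
    if (is.null(control$val_loss_fn)) {
      f <- gazenet_forward(params, val_packed)
      vl <- gazenet_loss(f$probs, val$y)
      vacc <- mean(max.col(f$probs, ties.method = "first") - 1L == val$y)
    } else vl <- control$val_loss_fn(params, check)
    es <<- early_stop_update(es, vl)
    if (es$improved) best_params <<- params
    hist[[check]] <<- data.frame(check = check, iteration = iter,
                                 train_loss = last_train_loss, val_loss = vl,
                                 val_acc = vacc)
    es$stop
  }

  with_local_seed(derive_seed(seed, "train"), {
    done <- FALSE
    for (epoch in seq_len(control$max_epochs)) {
      ord <- if (control$shuffle) sample.int(n) else seq_len(n)
      for (bi in seq_len(n_batches)) {
        idx <- ord[((bi - 1L) * mb + 1L):min(bi * mb, n)]
        fwd <- gazenet_forward(params, train$xs[idx],
                               dropout = config$dropout, training = TRUE,
                               want_cache = TRUE)
        last_train_loss <- gazenet_loss(fwd$probs, train$y[idx])
        if (!is.finite(last_train_loss))
          stop_gpn("gpn_training_error", "non-finite loss at iteration %d",
                   iter + 1L)
        grads <- gazenet_backward(params, fwd, train$y[idx])
        for (nm in L2_PARAMS) grads[[nm]] <- grads[[nm]] + control$l2 * params[[nm]]
        iter <- iter + 1L
        upd <- opt_step(opt, params, grads, control, iter)
        opt <- upd$opt; params <- upd$params
        if (iter %% control$validation_frequency == 0L) {
          if (run_check()) { stop_reason <- "patience"; done <- TRUE; break }
        }
      }
      if (done) break
    }
    # terminal check so short fits still pick a checkpoint
    if (!done && (check == 0L || iter %% control$validation_frequency != 0L))
      if (run_check()) stop_reason <- "patience"
  })

  model$params <- if (identical(control$checkpoint %||% "best", "final"))
    params else best_params
  model$fitted <- TRUE
  model$control <- control
  model$history <- do.call(rbind, hist)
  model$n_iterations <- iter
  model$n_train <- n
  model$stop_reason <- stop_reason
  model$best_val_loss <- es$best
  model
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

opt_step <- function(opt, params, grads, control, iter) {
  lr <- control$learning_rate
  if (control$optimizer == "sgd") {
    for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(opt = opt, params = params))
  }
  for (nm in names(params)) {
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * grads[[nm]]
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - opt$b1^iter)
    vhat <- opt$v[[nm]] / (1 - opt$b2^iter)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Coerce sequences + labels to list(xs = list of matrices, y = int codes).
as_xy <- function(x, y) {
  if (length(x) && inherits(x[[1]], "feature_sequence")) {
    list(xs = lapply(x, `[[`, "features"),
         y = vapply(x, `[[`, 0L, "label"))
  } else if (is.list(x) && !is.null(x$x)) {
    list(xs = x$x, y = as.integer(x$y))
  } else {
    if (is.null(y)) stop_gpn("gpn_data_error", "labels y are required")
    list(xs = x, y = as.integer(y))
  }
}

#' Predict expertise classes for new sequences
#'
#' Dropout is disabled: prediction is deterministic. The class label is the
#' argmax of the softmax probabilities; exact ties resolve to the
#' lowest-index class.
#'
#' @param object a `gazenet` model.
#' @param newdata list of [feature_sequence()] or of `T x input_dim`
#'   matrices.
#' @param type `"prob"` for the B x 3 probability matrix, `"class"` for
#'   integer codes 0/1/2.
#' @param ... unused.
#' @return probabilities or class codes.
#' @export
predict.gazenet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  nd <- as_xy(newdata, rep(0L, length(newdata)))
  if (any(vapply(nd$xs, ncol, 0L) != object$config$input_dim))
    stop_gpn("gpn_data_error", "feature dimension does not match input_dim")
  probs <- gazenet_forward(object$params, nd$xs)$probs
  colnames(probs) <- EXPERTISE_LEVELS
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.gazenet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("gazenet BiLSTM classifier: %d -> BiLSTM(%d/dir -> %d) -> fc(%d) -> dropout(%.2f) -> fc(%d) -> softmax\n",
              cfg$input_dim, cfg$hidden, 2 * cfg$hidden, cfg$fc, cfg$dropout,
              cfg$n_classes))
  if (x$fitted)
    cat(sprintf("  fitted: %d iterations, stop: %s, best val loss %.4f\n",
                x$n_iterations, x$stop_reason, x$best_val_loss))
  else cat("  untrained\n")
  invisible(x)
}

#' Parameter-shape audit of the model
#'
#' Reports the combined bidirectional blocks (both directions stacked), the
#' per-direction shapes and the fully connected layers.
#'
#' @param model a `gazenet` object.
#' @return named list of dimension vectors.
#' @export
model_shape_audit <- function(model) {
  p <- model$params
  list(bilstm_input_weights = c(nrow(p$Wf) + nrow(p$Wb), ncol(p$Wf)),
       bilstm_recurrent_weights = c(nrow(p$Uf) + nrow(p$Ub), ncol(p$Uf)),
       bilstm_bias = c(length(p$bf) + length(p$bb), 1L),
       bilstm_output_dim = 2L * model$config$hidden,
       fc1_weights = dim(p$W1), fc1_bias = length(p$b1),
       fc2_weights = dim(p$W2), fc2_bias = length(p$b2))
}

#' @export
summary.gazenet <- function(object, ...) {
  a <- model_shape_audit(object)
  n_par <- sum(vapply(object$params, length, 0))
  out <- list(audit = a, n_parameters = n_par, config = object$config,
              fitted = object$fitted, history = object$history)
  class(out) <- "summary.gazenet"
  out
}

#' @export
print.summary.gazenet <- function(x, ...) {
  cat("gazenet parameter audit\n")
  cat(sprintf("  BiLSTM input weights:     %d x %d\n", x$audit$bilstm_input_weights[1],
              x$audit$bilstm_input_weights[2]))
  cat(sprintf("  BiLSTM recurrent weights: %d x %d\n", x$audit$bilstm_recurrent_weights[1],
              x$audit$bilstm_recurrent_weights[2]))
  cat(sprintf("  BiLSTM biases:            %d x 1\n", x$audit$bilstm_bias[1]))
  cat(sprintf("  BiLSTM output dimension:  %d\n", x$audit$bilstm_output_dim))
  cat(sprintf("  fc-1 weights: %d x %d, fc-2 weights: %d x %d\n",
              x$audit$fc1_weights[1], x$audit$fc1_weights[2],
              x$audit$fc2_weights[1], x$audit$fc2_weights[2]))
  cat(sprintf("  total parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

#' @export
coef.gazenet <- function(object, ...) object$params

#' @export
plot.gazenet <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::plot(h$iteration, h$val_loss, type = "b", pch = 16,
                 xlab = "iteration", ylab = "loss",
                 ylim = range(c(h$val_loss, h$train_loss), na.rm = TRUE), ...)
  graphics::lines(h$iteration, h$train_loss, lty = 2, col = "grey40")
  graphics::legend("topright", c("validation", "train (batch)"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
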