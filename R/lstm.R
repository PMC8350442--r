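# Bidirectional LSTM internals: batched masked forward pass and
# backpropagation through time, written against plain BLAS matrix products.
#
# Conventions: a batch is an array X[B, T, D] with mask M[B, T] (1 = real
# step, 0 = zero padding). Gate pre-activations for one direction are
#   z_t = x_t W' + h_{t-1} U' + b,    W: 4H x D, U: 4H x H, b: 4H
# with gate column blocks [input | forget | cell | output]. State updates
# are masked so h and c freeze after a sequence's true length: the "final
# step" read out downstream is therefore the last TRUE step, never a padded
# one. The backward direction runs the same machinery on sequences reversed
# within their true lengths.

lstm_init <- function(D, H) {
  r <- sqrt(6 / (D + H))
  W <- matrix(stats::runif(4 * H * D, -r, r), 4 * H, D)
  U <- matrix(stats::runif(4 * H * H, -r, r), 4 * H, H)
  b <- rep(0, 4 * H)
  b[H + seq_len(H)] <- 1          # forget-gate bias starts open
  list(W = W, U = U, b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward one direction over a flattened batch (Xm: (B*T) x D with row
# blocks per time step). Returns the final hidden state (B x H) and, when
# want_cache, everything BPTT needs.
lstm_forward_dir <- function(Xm, M, W, U, b, want_cache = FALSE) {
  B <- nrow(M); Tn <- ncol(M); D <- ncol(Xm)
  H <- nrow(U) %/% 4L
  XW <- Xm %*% t(W)                              # (B*T) x 4H
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  cache <- if (want_cache)
    list(gates = vector("list", Tn), c = vector("list", Tn),
         h_prev = vector("list", Tn), c_prev = vector("list", Tn)) else NULL
  iH <- seq_len(H)
  bmat <- matrix(b, B, 4L * H, byrow = TRUE)
  Ut <- t(U)
  for (t in seq_len(Tn)) {
    m <- M[, t]
    z <- XW[(t - 1L) * B + seq_len(B), , drop = FALSE] + h %*% Ut + bmat
    ig <- sigmoid(z[, iH, drop = FALSE])
    fg <- sigmoid(z[, H + iH, drop = FALSE])
    gg <- tanh(z[, 2L * H + iH, drop = FALSE])
    og <- sigmoid(z[, 3L * H + iH, drop = FALSE])
    c_new <- fg * c + ig * gg
    h_new <- og * tanh(c_new)
    if (want_cache) {
      cache$gates[[t]] <- cbind(ig, fg, gg, og)
      cache$c[[t]] <- c_new
      cache$h_prev[[t]] <- h
      cache$c_prev[[t]] <- c
    }
    c <- c + m * (c_new - c)
    h <- h + m * (h_new - h)
  }
  if (want_cache) {
    cache$Xm <- Xm; cache$M <- M; cache$U <- U; cache$W <- W
    cache$B <- B; cache$Tn <- Tn; cache$D <- D; cache$H <- H
  }
  list(h = h, cache = cache)
}

# BPTT for one direction given the gradient on the emitted final state.
lstm_backward_dir <- function(cache, dH_final) {
  B <- cache$B; Tn <- cache$Tn; D <- cache$D; H <- cache$H
  U <- cache$U
  iH <- seq_len(H)
  dh <- dH_final
  dc <- matrix(0, B, H)
  dZ <- matrix(0, B * Tn, 4L * H)
  dU <- matrix(0, 4L * H, H)
  db <- numeric(4L * H)
  for (t in rev(seq_len(Tn))) {
    m <- cache$M[, t]
    g <- cache$gates[[t]]
    ig <- g[, iH, drop = FALSE]; fg <- g[, H + iH, drop = FALSE]
    gg <- g[, 2L * H + iH, drop = FALSE]; og <- g[, 3L * H + iH, drop = FALSE]
    tc <- tanh(cache$c[[t]])
    do_ <- dh * tc
    dct <- dc + dh * og * (1 - tc^2)
    di <- dct * gg
    df <- dct * cache$c_prev[[t]]
    dg <- dct * ig
    dz <- cbind(di * ig * (1 - ig), df * fg * (1 - fg),
                dg * (1 - gg^2), do_ * og * (1 - og)) * m
    dZ[(t - 1L) * B + seq_len(B), ] <- dz
    dU <- dU + crossprod(dz, cache$h_prev[[t]])
    db <- db + colSums(dz)
    dh <- m * (dz %*% U) + (1 - m) * dh
    dc <- m * (dct * fg) + (1 - m) * dc
  }
  dW <- crossprod(dZ, cache$Xm)
  list(dW = dW, dU = dU, db = db)
}

# Pad a list of T_i x D matrices into a flattened batch: Xm is
# (B*Tmax) x D with row block t holding all sequences' step t (zero rows
# beyond a sequence's true length); Xrm holds the sequences reversed
# within their true lengths (for the backward direction); M is the
# B x Tmax validity mask. Packing happens once per batch so forward
# passes never reshape or re-reverse.
pack_batch <- function(xs, Tmax = NULL) {
  B <- length(xs)
  D <- ncol(xs[[1]])
  lengths <- vapply(xs, nrow, 0L)
  if (is.null(Tmax)) Tmax <- max(lengths)
  X <- array(0, c(B, Tmax, D))
  Xr <- array(0, c(B, Tmax, D))
  M <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    L <- lengths[b]
    X[b, seq_len(L), ] <- xs[[b]]
    Xr[b, seq_len(L), ] <- xs[[b]][L:1, , drop = FALSE]
    M[b, seq_len(L)] <- 1
  }
  dim(X) <- c(B * Tmax, D)
  dim(Xr) <- c(B * Tmax, D)
  list(Xm = X, Xrm = Xr, M = M, lengths = lengths)
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
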