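# Minimal CNN forward primitives and the truncated GoogLeNet-architecture
# feature extractor.
#
# Only inference is needed: the backbone is used as a fixed feature map,
# truncated after the last (global average) pooling layer, so a patch of
# 224 x 224 x 3 is reduced to a 1,024-vector. Convolution is evaluated as
# k^2 shifted matrix products (BLAS-friendly, no im2col allocation).

conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  if (pad > 0) {
    xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
    x <- xp; H <- H + 2 * pad; W <- W + 2 * pad
  }
  Hout <- (H - k) %/% stride + 1L
  Wout <- (W - k) %/% stride + 1L
  acc <- matrix(rep(b, each = Hout * Wout), Hout * Wout, Cout)
  for (i in seq_len(k)) {
    rows <- seq(i, by = stride, length.out = Hout)
    for (j in seq_len(k)) {
      cols <- seq(j, by = stride, length.out = Wout)
      sl <- x[rows, cols, , drop = FALSE]
      dim(sl) <- c(Hout * Wout, Cin)
      acc <- acc + sl %*% matrix(w[i, j, , ], Cin, Cout)
    }
  }
  array(acc, c(Hout, Wout, Cout))
}

relu <- function(x) { x[x < 0] <- 0; x }

max_pool <- function(x, k = 3L, stride = 2L, pad = 0L, ceil_mode = TRUE) {
  d <- dim(x); H <- d[1] + 2L * pad; W <- d[2] + 2L * pad; C <- d[3]
  Hout <- if (ceil_mode) as.integer(ceiling((H - k) / stride)) + 1L
          else (H - k) %/% stride + 1L
  Wout <- if (ceil_mode) as.integer(ceiling((W - k) / stride)) + 1L
          else (W - k) %/% stride + 1L
  Hn <- (Hout - 1L) * stride + k; Wn <- (Wout - 1L) * stride + k
  xp <- array(-Inf, c(Hn, Wn, C))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out <- array(-Inf, c(Hout, Wout, C))
  for (i in seq_len(k)) {
    rows <- seq(i, by = stride, length.out = Hout)
    for (j in seq_len(k)) {
      cols <- seq(j, by = stride, length.out = Wout)
      out <- pmax(out, xp[rows, cols, , drop = FALSE])
    }
  }
  out
}

# He-normal initialized conv weights; deterministic under the caller's RNG.
conv_init <- function(k, cin, cout) {
  list(w = array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = rep(0, cout))
}

# Standard GoogLeNet inception channel plan: (1x1, 3x3 reduce, 3x3,
# 5x5 reduce, 5x5, pool proj) per module.
GOOGLENET_INCEPTION <- list(
  i3a = c(64, 96, 128, 16, 32, 32),
  i3b = c(128, 128, 192, 32, 96, 64),
  i4a = c(192, 96, 208, 16, 48, 64),
  i4b = c(160, 112, 224, 24, 64, 64),
  i4c = c(128, 128, 256, 24, 64, 64),
  i4d = c(112, 144, 288, 32, 64, 64),
  i4e = c(256, 160, 320, 32, 128, 128),
  i5a = c(256, 160, 320, 32, 128, 128),
  i5b = c(384, 192, 384, 48, 128, 128))

inception_init <- function(cin, plan) {
  list(b1 = conv_init(1, cin, plan[1]),
       b2r = conv_init(1, cin, plan[2]), b2 = conv_init(3, plan[2], plan[3]),
       b3r = conv_init(1, cin, plan[4]), b3 = conv_init(5, plan[4], plan[5]),
       b4 = conv_init(1, cin, plan[6]))
}

inception_forward <- function(x, m) {
  o1 <- relu(conv2d(x, m$b1$w, m$b1$b))
  o2 <- relu(conv2d(relu(conv2d(x, m$b2r$w, m$b2r$b)), m$b2$w, m$b2$b, pad = 1L))
  o3 <- relu(conv2d(relu(conv2d(x, m$b3r$w, m$b3r$b)), m$b3$w, m$b3$b, pad = 2L))
  o4 <- relu(conv2d(max_pool(x, 3L, 1L, pad = 1L, ceil_mode = FALSE),
                    m$b4$w, m$b4$b))
  d <- dim(o1)
  out <- array(0, c(d[1], d[2], dim(o1)[3] + dim(o2)[3] + dim(o3)[3] + dim(o4)[3]))
  ch <- 0L
  for (o in list(o1, o2, o3, o4)) {
    out[, , ch + seq_len(dim(o)[3])] <- o
    ch <- ch + dim(o)[3]
  }
  out
}

# Builds the truncated network (stem + 9 inception modules + global average
# pool). Weights are randomly initialized (He) under `seed`: the extractor
# is used architecture-faithfully; pretrained ImageNet weights can be
# loaded into the same structure when available.
googlenet_init <- function(seed = 20210726L) {
  with_local_seed(seed, {
    p <- list(conv1 = conv_init(7, 3, 64),
              conv2r = conv_init(1, 64, 64),
              conv2 = conv_init(3, 64, 192))
    cin <- 192L
    for (nm in names(GOOGLENET_INCEPTION)) {
      plan <- GOOGLENET_INCEPTION[[nm]]
      p[[nm]] <- inception_init(cin, plan)
      cin <- plan[1] + plan[3] + plan[5] + plan[6]
    }
    attr(p, "output_dim") <- as.integer(cin)
    p
  })
}

googlenet_forward <- function(params, patch) {
  stopifnot(all(dim(patch) == c(224, 224, 3)))
  x <- patch * 2 - 1                      # [0,1] -> [-1,1]
  x <- relu(conv2d(x, params$conv1$w, params$conv1$b, stride = 2L, pad = 3L))
  x <- max_pool(x, 3L, 2L)                              # 56
  x <- relu(conv2d(x, params$conv2r$w, params$conv2r$b))
  x <- relu(conv2d(x, params$conv2$w, params$conv2$b, pad = 1L))
  x <- max_pool(x, 3L, 2L)                              # 28
  x <- inception_forward(x, params$i3a)
  x <- inception_forward(x, params$i3b)
  x <- max_pool(x, 3L, 2L)                              # 14
  for (nm in c("i4a", "i4b", "i4c", "i4d", "i4e")) {
    x <- inception_forward(x, params[[nm]])
  }
  x <- max_pool(x, 3L, 2L)                              # 7
  x <- inception_forward(x, params$i5a)
  x <- inception_forward(x, params$i5b)
  apply(x, 3, mean)                                     # global 7x7 avg pool
}
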