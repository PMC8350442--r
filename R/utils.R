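#' @keywords internal
"_PACKAGE"

# --- spherical geometry on the equirectangular frame -------------------------
#
# Normalized frame coordinates map to the sphere as
#   longitude lambda = 360 * (u - 0.5)   degrees, u in [0, 1)
#   latitude  phi    = 180 * (0.5 - v)   degrees, v in [0, 1]
# so u wraps (the frame is a full horizontal turn) and v clamps at the poles.

deg2rad <- function(x) x * pi / 180

uv_to_lambda_phi <- function(u, v) {
  list(lambda = 360 * (u - 0.5), phi = 180 * (0.5 - v))
}

lambda_phi_to_uv <- function(lambda, phi) {
  u <- (lambda / 360 + 0.5) %% 1
  v <- pmin(pmax(0.5 - phi / 180, 0), 1)
  list(u = u, v = v)
}

# Great-circle angular distance in degrees between gaze directions given in
# normalized frame coordinates. Haversine form: stable near 0.
angular_distance_deg <- function(u1, v1, u2, v2) {
  a1 <- uv_to_lambda_phi(u1, v1)
  a2 <- uv_to_lambda_phi(u2, v2)
  lam1 <- deg2rad(a1$lambda); phi1 <- deg2rad(a1$phi)
  lam2 <- deg2rad(a2$lambda); phi2 <- deg2rad(a2$phi)
  dphi <- phi2 - phi1
  dlam <- lam2 - lam1
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  h <- pmin(pmax(h, 0), 1)
  2 * asin(sqrt(h)) * 180 / pi
}

# Unit vectors for spherical interpolation.
lambda_phi_to_xyz <- function(lambda, phi) {
  lam <- deg2rad(lambda); ph <- deg2rad(phi)
  cbind(cos(ph) * cos(lam), cos(ph) * sin(lam), sin(ph))
}

xyz_to_lambda_phi <- function(p) {
  n <- sqrt(rowSums(p^2))
  p <- p / n
  list(lambda = atan2(p[, 2], p[, 1]) * 180 / pi,
       phi = asin(pmin(pmax(p[, 3], -1), 1)) * 180 / pi)
}

# Spherical linear interpolation between two directions, t in [0,1].
slerp_lambda_phi <- function(l1, p1, l2, p2, t) {
  a <- lambda_phi_to_xyz(l1, p1)[1, ]
  b <- lambda_phi_to_xyz(l2, p2)[1, ]
  dotab <- sum(a * b)
  dotab <- min(max(dotab, -1), 1)
  omega <- acos(dotab)
  if (omega < 1e-9) {
    out <- matrix(rep(a, length(t)), ncol = 3, byrow = TRUE)
  } else {
    s <- sin(omega)
    out <- outer(sin((1 - t) * omega) / s, a) + outer(sin(t * omega) / s, b)
  }
  xyz_to_lambda_phi(out)
}

# --- RNG helpers -------------------------------------------------------------

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from a base seed and a string tag (FNV-1a).
derive_seed <- function(seed, tag) {
  h <- fnv1a(paste0(seed, "/", tag))
  as.integer(h %% 2147483647)
}

# FNV-1a hash over a character scalar or raw vector; returns a double in
# [0, 2^32). Used for sub-seed derivation and config fingerprints (the
# environment provides no general-purpose digest facility).
fnv1a <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = "\x01"))
  h <- 2166136261
  m <- 4294967296
  for (b in as.integer(x)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% m
  }
  h
}

# xor for doubles holding 32-bit values (bitwXor needs integers < 2^31)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

config_hash <- function(cfg) {
  h <- fnv1a(serialize(cfg, NULL, version = 2))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gpn <- function(kind, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(kind, "gpn_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}
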