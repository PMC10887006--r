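# Independent brute-force oracles used to pin down the vectorized
# implementations. Deliberately written as naive loops so they share no code
# with the package internals.

# L1-norm fusion, Eqs.-style: per-pixel L1 activity over channels, zero-padded
# (2r+1)^2 box average with fixed divisor, normalized weights, convex blend.
naive_fuse <- function(phis, r, eps = 1e-8) {
  K <- length(phis)
  d <- dim(phis[[1]])
  act <- lapply(phis, function(p) {
    m <- matrix(0, d[1], d[2])
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2])) m[x, y] <- sum(abs(p[x, y, ]))
    }
    m
  })
  sm <- lapply(act, function(cm) {
    m <- matrix(0, d[1], d[2])
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2])) {
        s <- 0
        for (a in -r:r) {
          for (b in -r:r) {
            xa <- x + a
            yb <- y + b
            if (xa >= 1 && xa <= d[1] && yb >= 1 && yb <= d[2]) {
              s <- s + cm[xa, yb]
            }
          }
        }
        m[x, y] <- s / (2 * r + 1)^2
      }
    }
    m
  })
  out <- array(0, dim = d)
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      S <- sum(vapply(sm, function(m) m[x, y], 0))
      w <- if (S < eps) rep(1 / K, K) else vapply(sm, function(m) m[x, y], 0) / S
      for (ch in seq_len(d[3])) {
        out[x, y, ch] <- sum(w * vapply(phis, function(p) p[x, y, ch], 0))
      }
    }
  }
  out
}

# Per-pixel bilinear resize with half-pixel-centre alignment.
naive_bilinear <- function(x, h, w) {
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      si <- min(max((i - 0.5) * nrow(x) / h - 0.5, 0), nrow(x) - 1)
      sj <- min(max((j - 0.5) * ncol(x) / w - 0.5, 0), ncol(x) - 1)
      i0 <- floor(si); j0 <- floor(sj)
      i1 <- min(i0 + 1, nrow(x) - 1); j1 <- min(j0 + 1, ncol(x) - 1)
      wi <- si - i0; wj <- sj - j0
      out[i, j] <- (1 - wi) * (1 - wj) * x[i0 + 1, j0 + 1] +
        wi * (1 - wj) * x[i1 + 1, j0 + 1] +
        (1 - wi) * wj * x[i0 + 1, j1 + 1] +
        wi * wj * x[i1 + 1, j1 + 1]
    }
  }
  out
}

# Tiny architecture used wherever a full forward/backward pass is needed but
# the geometry is irrelevant.
tiny_config <- function(seed = 3, input_size = 8, ...) {
  model_config(input_size = input_size, stem_channels = 2, growth_rate = 2,
               block_layers = 2, trans_channels = c(2, 3, 4), fc_hidden = 5,
               seed = seed, ...)
}

# Small-but-real architecture for training runs in tests.
small_config <- function(seed = 101, input_size = 64, ...) {
  model_config(input_size = input_size, stem_channels = 4, growth_rate = 4,
               trans_channels = c(8, 12, 16), fc_hidden = 32, seed = seed, ...)
}

random_slice <- function(n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n, 0, 255), n, n)
}

one_hot_test <- function(labels) {
  classes <- c("GBM", "SBM", "PCNSL")
  y <- matrix(0, length(labels), 3)
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}
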