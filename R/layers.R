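# Low-level differentiable layers. Feature maps are H x W x C arrays.
# Every *_forward returns list(out, ...cache...); the matching *_backward
# takes the cache and the upstream gradient and returns gradients for the
# input and the parameters. Convolutions are evaluated as im2col + one BLAS
# matrix product; the gather indices that build the patch matrix are cached
# per feature-map shape, and the input gradient is computed as a second
# convolution with tap-reversed, channel-transposed kernels rather than a
# scatter, which keeps the whole pass inside vectorized gathers and GEMMs.

# --- 3x3 convolution, stride 1, zero padding 1 ------------------------------
# Weight layout: (9*Cin) x Cout with rows ordered channel-fast within tap
# (tap k = dy + 3*dx). Evaluated in compiled code as im2col + GEMM; the
# backward pass recomputes the patch matrix rather than caching it.

conv3_forward <- function(x, W, b) {
  list(out = .conv3_fwd_cpp(x, W, b), x = x)
}

conv3_backward <- function(cache, W, dout) {
  .conv3_bwd_cpp(cache$x, W, dout)
}

# --- 1x1 convolution (channel projection) -----------------------------------

conv1_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  y <- xm %*% W
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(d[1], d[2], length(b))
  list(out = y, x = x)
}

conv1_backward <- function(cache, W, dout) {
  d <- dim(cache$x)
  HW <- d[1] * d[2]
  xm <- matrix(cache$x, HW, d[3])
  dmat <- matrix(dout, HW, ncol(W))
  dx <- dmat %*% t(W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(xm, dmat), db = colSums(dmat))
}

# --- per-feature-map normalization ------------------------------------------
# Each channel is standardized over its spatial extent (batch-independent,
# so train and eval behave identically), then scaled/shifted by gamma/beta.

norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  nf <- .norm_fwd_cpp(x, gamma, beta, eps)
  list(out = nf$out, x = x, mu = nf$mu, sd = nf$sd)
}

norm_backward <- function(cache, gamma, dout) {
  .norm_bwd_cpp(cache$x, dout, gamma, cache$mu, cache$sd)
}

# --- pointwise nonlinearities ------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0))
relu_backward <- function(cache, dout) dout * (cache$out > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# --- 2x2 average pooling, stride 2 ------------------------------------------

pool2_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop_mffc("pooling needs even spatial dimensions")
  }
  i1 <- seq(1L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L)
  y <- (x[i1, j1, , drop = FALSE] + x[i1 + 1L, j1, , drop = FALSE] +
          x[i1, j1 + 1L, , drop = FALSE] + x[i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
  list(out = y, d = d)
}

pool2_backward <- function(cache, dout) {
  d <- cache$d
  dx <- array(0, dim = d)
  i1 <- seq(1L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L)
  g <- dout / 4
  dx[i1, j1, ] <- g
  dx[i1 + 1L, j1, ] <- g
  dx[i1, j1 + 1L, ] <- g
  dx[i1 + 1L, j1 + 1L, ] <- g
  dx
}

# --- fully connected ----------------------------------------------------------

linear_forward <- function(x, W, b) {
  list(out = as.numeric(crossprod(W, x)) + b, x = x)
}

linear_backward <- function(cache, W, dout) {
  list(dx = as.numeric(W %*% dout),
       dW = outer(cache$x, dout),
       db = dout)
}
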