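# Forward model: two parallel DenseBlock encoders (one per MRI
# modality), L1-norm activity fusion of the per-scale features, spatial-
# channel attention on the three deep branches, and a two-layer softmax
# decoder over their concatenation. The backward pass is written by hand and
# checked against finite differences in the test suite.

#' Model configuration
#'
#' Architecture hyper-parameters. The defaults reproduce the reference
#' geometry: 240 x 240 inputs, three DenseBlocks of 5 layers per encoder,
#' transition widths 32/64/128 so the deepest features are 30 x 30 x 128,
#' fusion window half-width 2, and a 256-unit hidden FC layer. Smaller
#' values of `input_size` (any multiple of 8) and of the width parameters
#' give proportionally cheaper models with the same architecture.
#'
#' @param input_size input side length in pixels; must be divisible by 8.
#' @param num_classes number of tumor classes (3: GBM, SBM, PCNSL).
#' @param stem_channels channels of the initial 3x3 convolution.
#' @param growth_rate channels added by each DenseBlock layer.
#' @param block_layers convolutional layers per DenseBlock (default 5).
#' @param trans_channels length-3 integer: channels after each block's 1x1
#'   transition (the third is the deep-feature width used for fusion).
#' @param fusion_radius box half-width r of the activity smoothing.
#' @param fusion_eps degenerate-denominator threshold in the fusion weights.
#' @param fusion_scales which encoder scales (1, 2, 3) enter the fusion.
#' @param fusion_combine `"average"` of per-scale fused maps or `"last"`.
#' @param fc_hidden width of the hidden fully connected layer.
#' @param attention apply the spatial-channel attention gates.
#' @param seed seed for parameter initialization.
#' @return An object of class `mffc_config`.
#' @export
model_config <- function(input_size = 240, num_classes = 3,
                         stem_channels = 16, growth_rate = 16,
                         block_layers = 5, trans_channels = c(32, 64, 128),
                         fusion_radius = 2, fusion_eps = 1e-8,
                         fusion_scales = 1:3,
                         fusion_combine = c("average", "last"),
                         fc_hidden = 256, attention = TRUE, seed = 1) {
  if (!is_count(input_size, 8L) || input_size %% 8L != 0L) {
    stop_mffc("`input_size` must be a positive multiple of 8")
  }
  if (num_classes != 3) stop_mffc("this task has exactly 3 classes")
  stopifnot(is_count(stem_channels), is_count(growth_rate),
            is_count(block_layers), length(trans_channels) == 3,
            is_count(fc_hidden), is_count(fusion_radius, 0L))
  if (!all(fusion_scales %in% 1:3) || length(fusion_scales) < 1) {
    stop_mffc("`fusion_scales` must be a non-empty subset of 1:3")
  }
  structure(list(
    input_size = as.integer(input_size), num_classes = 3L,
    stem_channels = as.integer(stem_channels),
    growth_rate = as.integer(growth_rate),
    block_layers = as.integer(block_layers),
    trans_channels = as.integer(trans_channels),
    fusion_radius = as.integer(fusion_radius), fusion_eps = fusion_eps,
    fusion_scales = sort(as.integer(fusion_scales)),
    fusion_combine = match.arg(fusion_combine),
    fc_hidden = as.integer(fc_hidden), attention = isTRUE(attention),
    seed = as.integer(seed)
  ), class = "mffc_config")
}

#' @export
print.mffc_config <- function(x, ...) {
  s3 <- x$input_size %/% 8L
  cat(sprintf(
    "<mffc_config> input %dx%d | stem %d, growth %d, %d layers/block, widths %s\n",
    x$input_size, x$input_size, x$stem_channels, x$growth_rate,
    x$block_layers, paste(x$trans_channels, collapse = "/")))
  cat(sprintf("  deep features %dx%dx%d; fusion r=%d scales %s (%s); fc %d; attention %s\n",
              s3, s3, x$trans_channels[3], x$fusion_radius,
              paste(x$fusion_scales, collapse = ","), x$fusion_combine,
              x$fc_hidden, if (x$attention) "on" else "off"))
  invisible(x)
}

he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

init_dense_block <- function(in_channels, cfg) {
  layers <- vector("list", cfg$block_layers)
  for (l in seq_len(cfg$block_layers)) {
    cin <- in_channels + (l - 1L) * cfg$growth_rate
    layers[[l]] <- list(
      gamma = rep(1, cin), beta = rep(0, cin),
      W = he_mat(9L * cin, cfg$growth_rate, 9L * cin),
      b = rep(0, cfg$growth_rate)
    )
  }
  layers
}

init_encoder <- function(cfg) {
  enc <- list(stem = list(W = he_mat(9L, cfg$stem_channels, 9L),
                          b = rep(0, cfg$stem_channels)))
  cin <- cfg$stem_channels
  enc$blocks <- vector("list", 3L)
  for (n in 1:3) {
    ct <- cin + cfg$block_layers * cfg$growth_rate
    enc$blocks[[n]] <- list(
      layers = init_dense_block(cin, cfg),
      trans = list(gamma = rep(1, ct), beta = rep(0, ct),
                   W = he_mat(ct, cfg$trans_channels[n], ct),
                   b = rep(0, cfg$trans_channels[n]))
    )
    cin <- cfg$trans_channels[n]
  }
  enc
}

init_attention <- function(C) {
  red <- max(1L, C %/% 8L)
  list(W1 = he_mat(C, red, C), b1 = rep(0, red),
       W2 = he_mat(red, C, red), b2 = rep(0, C),
       Wsp = he_mat(18L, 1L, 18L), bsp = 0)
}

#' Initialize model parameters
#'
#' Seeded He-normal initialization of every weight in the network; the same
#' configuration seed always yields bitwise-identical parameters.
#'
#' @param cfg an [model_config()] object.
#' @return Nested list of parameter arrays.
#' @export
init_params <- function(cfg) {
  C3 <- cfg$trans_channels[3]
  s3 <- cfg$input_size %/% 8L
  with_seed(cfg$seed, {
    params <- list(enc1 = init_encoder(cfg), enc2 = init_encoder(cfg))
    # 1x1 projections to the deep width for shallower fusion scales
    params$proj <- list(enc1 = list(), enc2 = list())
    for (n in cfg$fusion_scales) {
      cn <- cfg$trans_channels[n]
      if (cn != C3) {
        for (m in c("enc1", "enc2")) {
          params$proj[[m]][[as.character(n)]] <-
            list(W = he_mat(cn, C3, cn), b = rep(0, C3))
        }
      }
    }
    if (cfg$attention) {
      params$att <- list(t1ce = init_attention(C3),
                         flair = init_attention(C3),
                         fusion = init_attention(C3))
    }
    D <- s3 * s3 * 3L * C3
    params$fc <- list(W1 = he_mat(D, cfg$fc_hidden, D),
                      b1 = rep(0, cfg$fc_hidden),
                      W2 = he_mat(cfg$fc_hidden, 3L, cfg$fc_hidden),
                      b2 = rep(0, 3L))
    params
  })
}

# --- DenseBlock ---------------------------------------------------------------

#' DenseBlock forward pass
#'
#' Each layer applies per-map normalization, ReLU and a 3x3 convolution to
#' the channel concatenation of the block input and all previous layer
#' outputs; the block output concatenates the input with every layer's
#' output, so channels grow from `C` to `C + block_layers * growth_rate`
#' while the spatial size is preserved.
#'
#' @param x H x W x C input feature map.
#' @param block_params list of per-layer parameter lists (`gamma`, `beta`,
#'   `W`, `b`), e.g. `init_params(cfg)$enc1$blocks[[1]]$layers`.
#' @return H x W x (C + L*growth) feature map.
#' @export
dense_block_forward <- function(x, block_params) {
  dense_block_fwd(x, block_params)$out
}

dense_block_fwd <- function(x, layers) {
  feats <- list(x)
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    lp <- layers[[l]]
    xcat <- if (l == 1L) x else cat_channels(feats)
    if (dim(xcat)[3] != length(lp$gamma)) {
      stop_mffc("channel mismatch entering DenseBlock layer ", l)
    }
    nf <- norm_forward(xcat, lp$gamma, lp$beta)
    rf <- relu_forward(nf$out)
    cf <- conv3_forward(rf$out, lp$W, lp$b)
    feats[[l + 1L]] <- cf$out
    caches[[l]] <- list(norm = nf, relu = rf, conv = cf)
  }
  list(out = cat_channels(feats), feats_channels = vapply(feats, function(f) dim(f)[3], 0L),
       caches = caches)
}

dense_block_bwd <- function(cache, layers, dout) {
  ch <- cache$feats_channels
  L <- length(layers)
  d <- dim(dout)
  # split the gradient of the concatenated output into per-feature pieces
  dfeats <- vector("list", L + 1L)
  ofs <- 0L
  for (i in seq_len(L + 1L)) {
    dfeats[[i]] <- dout[, , ofs + seq_len(ch[i]), drop = FALSE]
    ofs <- ofs + ch[i]
  }
  grads <- vector("list", L)
  for (l in L:1) {
    lp <- layers[[l]]
    cb <- conv3_backward(cache$caches[[l]]$conv, lp$W, dfeats[[l + 1L]])
    drelu <- relu_backward(cache$caches[[l]]$relu, cb$dx)
    nb <- norm_backward(cache$caches[[l]]$norm, lp$gamma, drelu)
    grads[[l]] <- list(gamma = nb$dgamma, beta = nb$dbeta,
                       W = cb$dW, b = cb$db)
    # dxcat feeds back into the block input and all earlier layer outputs
    ofs <- 0L
    for (i in seq_len(l)) {
      dfeats[[i]] <- dfeats[[i]] + nb$dx[, , ofs + seq_len(ch[i]), drop = FALSE]
      ofs <- ofs + ch[i]
    }
  }
  list(dx = dfeats[[1L]], grads = grads)
}

# --- encoder ------------------------------------------------------------------

#' Encoder forward pass
#'
#' A 3x3 stem convolution produces the low-level feature `f0` at full
#' resolution; three DenseBlocks, each followed by a 1x1 transition and 2x2
#' average pooling, produce `f1`, `f2`, `f3` at 1/2, 1/4 and 1/8 resolution.
#'
#' @param x input slice: a matrix with side `cfg$input_size`, values in
#'   `[0, 255]`.
#' @param enc_params one encoder's parameters, e.g. `init_params(cfg)$enc1`.
#' @param cfg the [model_config()].
#' @return List of feature maps `f0`, `f1`, `f2`, `f3`.
#' @export
encoder_forward <- function(x, enc_params, cfg) {
  enc <- encoder_fwd(prep_input(x, cfg), enc_params)
  enc$f
}

prep_input <- function(x, cfg) {
  if (!is.matrix(x) || !all(dim(x) == cfg$input_size)) {
    stop_mffc("input slice must be ", cfg$input_size, "x", cfg$input_size)
  }
  array(x / 255, dim = c(dim(x), 1L))  # [0,255] inputs scaled to [0,1]
}

encoder_fwd <- function(x, enc) {
  stem <- conv3_forward(x, enc$stem$W, enc$stem$b)
  f <- list(stem$out)
  caches <- list(stem = stem, blocks = vector("list", 3L))
  cur <- stem$out
  for (n in 1:3) {
    bp <- enc$blocks[[n]]
    bf <- dense_block_fwd(cur, bp$layers)
    tn <- norm_forward(bf$out, bp$trans$gamma, bp$trans$beta)
    tr <- relu_forward(tn$out)
    tc <- conv1_forward(tr$out, bp$trans$W, bp$trans$b)
    pl <- pool2_forward(tc$out)
    caches$blocks[[n]] <- list(block = bf, tnorm = tn, trelu = tr, tconv = tc,
                               pool = pl)
    cur <- pl$out
    f[[n + 1L]] <- cur
  }
  names(f) <- c("f0", "f1", "f2", "f3")
  list(f = f, caches = caches)
}

# dfs: list of gradients w.r.t. f1, f2, f3 (post-pool); df0 optional.
encoder_bwd <- function(cache, enc, dfs, df0 = NULL) {
  grads <- list(stem = NULL, blocks = vector("list", 3L))
  dcur <- NULL
  for (n in 3:1) {
    d_fn <- dfs[[n]]
    if (!is.null(dcur)) d_fn <- if (is.null(d_fn)) dcur else d_fn + dcur
    cb <- cache$blocks[[n]]
    bp <- enc$blocks[[n]]
    dpool <- pool2_backward(cb$pool, d_fn)
    tcb <- conv1_backward(cb$tconv, bp$trans$W, dpool)
    trb <- relu_backward(cb$trelu, tcb$dx)
    tnb <- norm_backward(cb$tnorm, bp$trans$gamma, trb)
    bb <- dense_block_bwd(cb$block, bp$layers, tnb$dx)
    grads$blocks[[n]] <- list(layers = bb$grads,
                              trans = list(gamma = tnb$dgamma, beta = tnb$dbeta,
                                           W = tcb$dW, b = tcb$db))
    dcur <- bb$dx
  }
  if (!is.null(df0)) dcur <- dcur + df0
  sb <- conv3_backward(cache$stem, enc$stem$W, dcur)
  grads$stem <- list(W = sb$dW, b = sb$db)
  grads
}

# --- spatial-channel attention -------------------------------------------------

#' Spatial-channel attention gate
#'
#' Applies a channel gate (sigmoid MLP over the spatially averaged channel
#' descriptor) followed by a spatial gate (sigmoid of a 3x3 convolution over
#' the channel-mean and channel-max maps); the input is multiplied by both
#' gates, so shape is preserved and magnitudes can only shrink.
#'
#' @param f H x W x C feature map.
#' @param att_params attention parameters (`W1`, `b1`, `W2`, `b2`, `Wsp`,
#'   `bsp`), e.g. `init_params(cfg)$att$fusion`.
#' @return Gated feature map, same shape as `f`.
#' @export
attention_forward <- function(f, att_params) {
  att_fwd(f, att_params)$out
}

att_fwd <- function(f, ap) {
  d <- dim(f)
  HW <- d[1] * d[2]
  xm <- matrix(f, HW, d[3])
  s <- colMeans(xm)
  z1 <- as.numeric(crossprod(ap$W1, s)) + ap$b1
  h <- pmax(z1, 0)
  z2 <- as.numeric(crossprod(ap$W2, h)) + ap$b2
  gc <- sigmoid(z2)
  x1 <- xm * rep(gc, each = HW)
  mavg <- rowMeans(x1)
  imax <- max.col(x1, ties.method = "first")
  mmax <- x1[cbind(seq_len(HW), imax)]
  sp_in <- array(c(mavg, mmax), dim = c(d[1], d[2], 2L))
  cv <- conv3_forward(sp_in, ap$Wsp, ap$bsp)
  gs <- sigmoid(as.vector(cv$out))
  y <- x1 * gs
  dim(y) <- d
  list(out = y,
       cache = list(d = d, xm = xm, s = s, z1 = z1, h = h, gc = gc, x1 = x1,
                    imax = imax, conv = cv, gs = gs))
}

att_bwd <- function(cache, ap, dout) {
  d <- cache$d
  HW <- d[1] * d[2]
  dy <- matrix(dout, HW, d[3])
  dx1 <- dy * cache$gs
  dgs <- rowSums(dy * cache$x1)
  du <- dgs * cache$gs * (1 - cache$gs)
  cb <- conv3_backward(cache$conv, ap$Wsp, array(du, dim = c(d[1], d[2], 1L)))
  dmavg <- as.vector(cb$dx[, , 1L])
  dmmax <- as.vector(cb$dx[, , 2L])
  dx1 <- dx1 + dmavg / d[3]
  dx1[cbind(seq_len(HW), cache$imax)] <-
    dx1[cbind(seq_len(HW), cache$imax)] + dmmax
  # channel gate
  dgc <- colSums(dx1 * cache$xm)
  dxm <- dx1 * rep(cache$gc, each = HW)
  dz2 <- dgc * cache$gc * (1 - cache$gc)
  dW2 <- outer(cache$h, dz2)
  dh <- as.numeric(ap$W2 %*% dz2)
  dz1 <- dh * (cache$z1 > 0)
  dW1 <- outer(cache$s, dz1)
  ds <- as.numeric(ap$W1 %*% dz1)
  dxm <- dxm + matrix(ds, HW, d[3], byrow = TRUE) / HW
  dx <- dxm
  dim(dx) <- d
  list(dx = dx,
       grads = list(W1 = dW1, b1 = dz1, W2 = dW2, b2 = dz2,
                    Wsp = cb$dW, bsp = cb$db))
}

# --- full model ----------------------------------------------------------------

#' Full model forward pass
#'
#' Runs both modality encoders, the multi-scale L1-norm fusion, attention on
#' the two deep modality features and the fused feature, and the softmax
#' decoder over their concatenation.
#'
#' @param x_t1ce,x_flair co-registered slices (matrices with side
#'   `cfg$input_size`, values in `[0, 255]`).
#' @param params parameters from [init_params()] or a fitted model.
#' @param cfg the [model_config()].
#' @return List with `probs` (named length-3 probability vector), `logits`,
#'   and `branches` (the three gated deep feature maps).
#' @export
model_forward <- function(x_t1ce, x_flair, params, cfg) {
  fw <- net_forward(x_t1ce, x_flair, params, cfg)
  list(probs = fw$probs, logits = fw$logits,
       branches = fw$branches)
}

net_forward <- function(x_t1ce, x_flair, params, cfg) {
  if (!all(dim(x_t1ce) == dim(x_flair))) {
    stop_mffc("modality slices must share a shape")
  }
  s3 <- cfg$input_size %/% 8L
  C3 <- cfg$trans_channels[3]
  e1 <- encoder_fwd(prep_input(x_t1ce, cfg), params$enc1)
  e2 <- encoder_fwd(prep_input(x_flair, cfg), params$enc2)

  # per-scale projection + fusion + resize to the deep geometry
  scales <- cfg$fusion_scales
  fcaches <- vector("list", length(scales))
  fused_acc <- NULL
  for (si in seq_along(scales)) {
    n <- scales[si]
    pcs <- list()
    phi <- list(e1$f[[n + 1L]], e2$f[[n + 1L]])
    for (mi in 1:2) {
      pp <- params$proj[[c("enc1", "enc2")[mi]]][[as.character(n)]]
      if (!is.null(pp)) {
        pc <- conv1_forward(phi[[mi]], pp$W, pp$b)
        pcs[[mi]] <- pc
        phi[[mi]] <- pc$out
      }
    }
    ff <- fusion_forward(phi, r = cfg$fusion_radius, eps = cfg$fusion_eps)
    hin <- dim(ff$out)[1]
    A <- interp_matrix(hin, s3)
    rz <- array(0, dim = c(s3, s3, C3))
    for (ch in seq_len(C3)) rz[, , ch] <- A %*% ff$out[, , ch] %*% t(A)
    fcaches[[si]] <- list(n = n, proj = pcs, fusion = ff$cache, A = A,
                          hin = hin)
    fused_acc <- if (is.null(fused_acc)) rz else fused_acc + rz
    if (cfg$fusion_combine == "last" && si < length(scales)) fused_acc <- NULL
  }
  nsc <- if (cfg$fusion_combine == "average") length(scales) else 1L
  f_fusion <- fused_acc / nsc

  branches_in <- list(t1ce = e1$f$f3, flair = e2$f$f3, fusion = f_fusion)
  acaches <- NULL
  branches <- branches_in
  if (cfg$attention) {
    acaches <- list()
    for (b in names(branches)) {
      af <- att_fwd(branches_in[[b]], params$att[[b]])
      acaches[[b]] <- af$cache
      branches[[b]] <- af$out
    }
  }
  fall <- cat_channels(branches$t1ce, branches$flair, branches$fusion)
  flat <- as.numeric(fall)
  l1 <- linear_forward(flat, params$fc$W1, params$fc$b1)
  r1 <- relu_forward(l1$out)
  l2 <- linear_forward(r1$out, params$fc$W2, params$fc$b2)
  probs <- softmax(l2$out)
  names(probs) <- tumor_classes()
  list(probs = probs, logits = l2$out, branches = branches,
       cache = list(e1 = e1, e2 = e2, fcaches = fcaches, acaches = acaches,
                    l1 = l1, r1 = r1, l2 = l2, s3 = s3, C3 = C3,
                    branches = branches))
}

# Backward from d(loss)/d(logits). Returns parameter gradients and, for
# Grad-CAM, the gradient w.r.t. the three concatenated branch feature maps.
net_backward <- function(fw, params, cfg, dlogits, branches_only = FALSE) {
  ca <- fw$cache
  s3 <- ca$s3
  C3 <- ca$C3
  l2b <- linear_backward(ca$l2, params$fc$W2, dlogits)
  dr1 <- relu_backward(ca$r1, l2b$dx)
  l1b <- linear_backward(ca$l1, params$fc$W1, dr1)
  dfall <- array(l1b$dx, dim = c(s3, s3, 3L * C3))
  dbr <- list(t1ce = dfall[, , seq_len(C3), drop = FALSE],
              flair = dfall[, , C3 + seq_len(C3), drop = FALSE],
              fusion = dfall[, , 2L * C3 + seq_len(C3), drop = FALSE])
  if (branches_only) return(list(dbranches = dbr))

  grads <- list(fc = list(W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db))
  if (cfg$attention) {
    grads$att <- list()
    for (b in names(dbr)) {
      ab <- att_bwd(ca$acaches[[b]], params$att[[b]], dbr[[b]])
      grads$att[[b]] <- ab$grads
      dbr[[b]] <- ab$dx
    }
  }

  # fusion path: split the fused-branch gradient across scales
  scales <- cfg$fusion_scales
  nsc <- if (cfg$fusion_combine == "average") length(scales) else 1L
  dfs1 <- vector("list", 3L)  # grads w.r.t. f1..f3 per encoder
  dfs2 <- vector("list", 3L)
  grads$proj <- list(enc1 = list(), enc2 = list())
  active <- if (cfg$fusion_combine == "average") seq_along(scales) else length(scales)
  for (si in active) {
    fc <- ca$fcaches[[si]]
    n <- fc$n
    dscale <- dbr$fusion / nsc
    # resize adjoint
    drz <- array(0, dim = c(fc$hin, fc$hin, C3))
    for (ch in seq_len(C3)) {
      drz[, , ch] <- t(fc$A) %*% dscale[, , ch] %*% fc$A
    }
    dphi <- fusion_backward(fc$fusion, drz)
    for (mi in 1:2) {
      mname <- c("enc1", "enc2")[mi]
      pp <- params$proj[[mname]][[as.character(n)]]
      dfn <- if (!is.null(pp)) {
        pb <- conv1_backward(fc$proj[[mi]], pp$W, dphi[[mi]])
        g <- grads$proj[[mname]][[as.character(n)]]
        grads$proj[[mname]][[as.character(n)]] <- if (is.null(g)) {
          list(W = pb$dW, b = pb$db)
        } else {
          list(W = g$W + pb$dW, b = g$b + pb$db)
        }
        pb$dx
      } else {
        dphi[[mi]]
      }
      tgt <- if (mi == 1L) dfs1 else dfs2
      tgt[[n]] <- if (is.null(tgt[[n]])) dfn else tgt[[n]] + dfn
      if (mi == 1L) dfs1 <- tgt else dfs2 <- tgt
    }
  }
  # deep-branch gradients reach f3 directly
  dfs1[[3L]] <- if (is.null(dfs1[[3L]])) dbr$t1ce else dfs1[[3L]] + dbr$t1ce
  dfs2[[3L]] <- if (is.null(dfs2[[3L]])) dbr$flair else dfs2[[3L]] + dbr$flair
  for (n in 1:3) {
    z1 <- dim(ca$e1$f[[n + 1L]])
    if (is.null(dfs1[[n]])) dfs1[[n]] <- array(0, dim = z1)
    z2 <- dim(ca$e2$f[[n + 1L]])
    if (is.null(dfs2[[n]])) dfs2[[n]] <- array(0, dim = z2)
  }
  grads$enc1 <- encoder_bwd(ca$e1$caches, params$enc1, dfs1)
  grads$enc2 <- encoder_bwd(ca$e2$caches, params$enc2, dfs2)
  grads
}

# --- loss ----------------------------------------------------------------------

#' Cross-entropy classification loss
#'
#' `L = -(1/N) sum_i sum_l y_il log p_il` over slices, with probabilities
#' clamped below at 1e-12 so the loss stays finite.
#'
#' @param probs N x 3 matrix (or list of length-3 vectors) of predicted
#'   class probabilities.
#' @param labels N x 3 one-hot matrix (or list of one-hot vectors, or a
#'   factor/character vector of class names).
#' @return Nonnegative scalar; 0 iff every slice puts probability 1 on its
#'   true class.
#' @export
cross_entropy_loss <- function(probs, labels) {
  if (is.list(probs)) probs <- do.call(rbind, probs)
  if (is.list(labels)) labels <- do.call(rbind, labels)
  if (is.character(labels) || is.factor(labels)) labels <- one_hot(labels)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1)
  if (nrow(probs) != nrow(labels) || nrow(probs) < 1) {
    stop_mffc("probs and labels must have the same positive length")
  }
  -mean(rowSums(labels * log(pmax(probs, 1e-12))))
}

one_hot <- function(labels, classes = tumor_classes()) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop_mffc("unknown class label")
  y <- matrix(0, length(idx), length(classes))
  y[cbind(seq_along(idx), idx)] <- 1
  colnames(y) <- classes
  y
}

# --- parameter flattening (optimizer plumbing) ----------------------------------

# Depth-first list of paths to every numeric leaf in a nested parameter list.
leaf_paths <- function(x, prefix = list()) {
  if (is.numeric(x)) return(list(prefix))
  out <- list()
  for (nm in seq_along(x)) {
    key <- if (!is.null(names(x)) && nzchar(names(x)[nm])) names(x)[nm] else nm
    out <- c(out, leaf_paths(x[[nm]], c(prefix, list(key))))
  }
  out
}

get_leaf <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

set_leaf <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- set_leaf(x[[path[[1L]]]], path[-1L], value)
  x
}

n_parameters <- function(params) {
  sum(vapply(leaf_paths(params), function(p) length(get_leaf(params, p)), 0))
}
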