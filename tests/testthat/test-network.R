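test_that("model configuration validates its geometry", {
  expect_error(model_config(input_size = 100), "multiple of 8")
  expect_error(model_config(num_classes = 2), "3 classes")
  cfg <- model_config()
  expect_equal(cfg$input_size, 240L)
  expect_equal(cfg$trans_channels, c(32L, 64L, 128L))
  expect_equal(cfg$block_layers, 5L)
})

test_that("dense block grows channels by layers x growth and keeps H x W", {
  cfg <- model_config(input_size = 16, stem_channels = 8, growth_rate = 8,
                      block_layers = 5, trans_channels = c(8, 8, 8),
                      fc_hidden = 4, seed = 1)
  params <- init_params(cfg)
  set.seed(2)
  x <- array(rnorm(12 * 10 * 8), dim = c(12, 10, 8))
  out <- dense_block_forward(x, params$enc1$blocks[[1]]$layers)
  expect_equal(dim(out), c(12, 10, 8 + 5 * 8))

  # zero conv weights: appended channels are zero, input passes through
  zp <- params$enc1$blocks[[1]]$layers
  for (l in seq_along(zp)) {
    zp[[l]]$W[] <- 0
    zp[[l]]$b[] <- 0
  }
  out0 <- dense_block_forward(x, zp)
  expect_identical(out0[, , 1:8], x)
  expect_true(all(out0[, , 9:48] == 0))

  expect_error(dense_block_forward(array(0, c(4, 4, 3)),
                                   params$enc1$blocks[[1]]$layers),
               "channel mismatch")
})

test_that("encoder halves spatial size per stage down to 1/8 resolution", {
  cfg <- small_config(seed = 5)
  params <- init_params(cfg)
  f <- encoder_forward(random_slice(64, 3), params$enc1, cfg)
  expect_equal(dim(f$f0), c(64, 64, 4))
  expect_equal(dim(f$f1), c(32, 32, 8))
  expect_equal(dim(f$f2), c(16, 16, 12))
  expect_equal(dim(f$f3), c(8, 8, 16))
  expect_error(encoder_forward(matrix(0, 32, 32), params$enc1, cfg), "64")

  # determinism: same input, same parameters, identical features
  f2 <- encoder_forward(random_slice(64, 3), params$enc1, cfg)
  expect_identical(f, f2)
})

test_that("attention gates preserve shape and damp magnitudes", {
  cfg <- tiny_config()
  params <- init_params(cfg)
  set.seed(6)
  f <- array(rnorm(5 * 5 * 4), dim = c(5, 5, 4))
  ap <- params$att$fusion
  out <- attention_forward(f, ap)
  expect_equal(dim(out), dim(f))
  expect_true(all(abs(out) <= abs(f) + 1e-12))

  # biases driven to saturation force both gates to 1: identity mapping
  ap1 <- ap
  ap1$W2[] <- 0
  ap1$b2[] <- 40
  ap1$Wsp[] <- 0
  ap1$bsp <- 40
  expect_equal(attention_forward(f, ap1), f, tolerance = 1e-9)
})

test_that("forward pass returns a probability simplex with 384-channel concat", {
  cfg <- small_config(seed = 7)
  params <- init_params(cfg)
  out <- model_forward(random_slice(64, 10), random_slice(64, 11), params, cfg)
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_gte(min(out$probs), 0)
  expect_named(out$probs, c("GBM", "SBM", "PCNSL"))
  # three branches on the deep grid; concatenation is 3 x deep width
  for (b in out$branches) expect_equal(dim(b), c(8, 8, 16))
  expect_error(model_forward(matrix(0, 64, 64), matrix(0, 32, 32), params, cfg),
               "share a shape")
})

test_that("seeded initialization is bitwise reproducible", {
  cfg <- tiny_config(seed = 99)
  expect_identical(init_params(cfg), init_params(cfg))
  p1 <- init_params(tiny_config(seed = 1))
  p2 <- init_params(tiny_config(seed = 2))
  expect_false(identical(p1$fc$W1, p2$fc$W1))
})

test_that("permuting decoder class weights permutes the probabilities", {
  cfg <- tiny_config(seed = 13)
  params <- init_params(cfg)
  x1 <- random_slice(8, 1)
  x2 <- random_slice(8, 2)
  p <- model_forward(x1, x2, params, cfg)$probs
  perm <- c(3, 1, 2)
  params2 <- params
  params2$fc$W2 <- params$fc$W2[, perm]
  params2$fc$b2 <- params$fc$b2[perm]
  p2 <- model_forward(x1, x2, params2, cfg)$probs
  expect_equal(unname(p2), unname(p[perm]), tolerance = 1e-12)
})

test_that("cross-entropy loss matches its closed forms", {
  u <- matrix(1 / 3, 4, 3)
  y <- one_hot_test(c("GBM", "SBM", "PCNSL", "GBM"))
  expect_equal(cross_entropy_loss(u, y), log(3), tolerance = 1e-12)

  perfect <- y
  expect_equal(cross_entropy_loss(perfect, y), 0)

  # two slices with true-class probabilities 0.5 and 0.25
  p <- rbind(c(0.5, 0.3, 0.2), c(0.25, 0.5, 0.25))
  yy <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_equal(cross_entropy_loss(p, yy), 1.5 * log(2), tolerance = 1e-12)

  expect_error(cross_entropy_loss(u, yy), "same positive length")
  expect_gte(cross_entropy_loss(matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1)), 0)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_config(seed = 3)
  params <- init_params(cfg)
  ns <- asNamespace("mffcnet")
  set.seed(42)
  x1 <- random_slice(8, 42)
  x2 <- random_slice(8, 43)
  y <- c(0, 1, 0)
  fw <- ns$net_forward(x1, x2, params, cfg)
  grads <- ns$net_backward(fw, params, cfg, fw$probs - y)
  loss_fn <- function(p) {
    -sum(y * log(pmax(ns$net_forward(x1, x2, p, cfg)$probs, 1e-12)))
  }
  paths <- ns$leaf_paths(params)
  set.seed(7)
  checked <- 0
  for (pth in paths) {
    w <- ns$get_leaf(params, pth)
    for (i in sample(length(w), min(2, length(w)))) {
      h <- 1e-5
      wp <- w; wp[i] <- wp[i] + h
      wm <- w; wm[i] <- wm[i] - h
      fd <- (loss_fn(ns$set_leaf(params, pth, wp)) -
               loss_fn(ns$set_leaf(params, pth, wm))) / (2 * h)
      an <- ns$get_leaf(grads, pth)[i]
      if (max(abs(fd), abs(an)) < 1e-7) next
      expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)  # every parameter group gets sampled
})
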