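test_that("activity map is the per-pixel L1 norm over channels", {
  expect_equal(activity_map(array(c(3, -4), dim = c(1, 1, 2)))[1, 1], 7)
  expect_identical(activity_map(array(0, dim = c(3, 4, 5))), matrix(0, 3, 4))

  set.seed(11)
  phi <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  want <- matrix(0, 4, 4)
  for (x in 1:4) for (y in 1:4) for (m in 1:3) {
    want[x, y] <- want[x, y] + abs(phi[x, y, m])
  }
  expect_equal(activity_map(phi), want, tolerance = 1e-12)
})

test_that("box smoothing is zero padded with a fixed divisor", {
  cm <- matrix(runif(20), 4, 5)
  expect_identical(smooth_activity(cm, 0), cm)

  ones <- matrix(1, 5, 5)
  sm <- smooth_activity(ones, 2)
  expect_equal(sm[3, 3], 1)
  expect_equal(sm[1, 1], 9 / 25)

  # zero padding with fixed divisor never increases total mass
  for (s in 1:5) {
    set.seed(s)
    cm <- matrix(rexp(48), 6, 8)
    expect_lte(sum(smooth_activity(cm, sample(1:3, 1))), sum(cm))
  }
  expect_error(smooth_activity(cm, -1), "nonnegative")
})

test_that("fusion weights normalize activities with a uniform fallback", {
  a <- matrix(2, 3, 3)
  w <- fusion_weights(list(a, a))
  expect_true(all(abs(w - 0.5) < 1e-12))

  w2 <- fusion_weights(list(matrix(3, 1, 1), matrix(1, 1, 1)))
  expect_equal(as.numeric(w2), c(0.75, 0.25))

  w0 <- fusion_weights(list(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_true(all(w0 == 0.5))

  expect_error(fusion_weights(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "mismatch")
  expect_error(fusion_weights(list(matrix(1, 2, 2))), "at least two")
})

test_that("fusing identical maps returns them unchanged; hand case checks out", {
  set.seed(3)
  phi <- array(rnorm(5 * 6 * 3), dim = c(5, 6, 3))
  expect_equal(fuse_features(list(phi, phi), r = 2), phi, tolerance = 1e-9)

  f <- fuse_features(list(array(3, c(1, 1, 1)), array(-1, c(1, 1, 1))), r = 2)
  expect_equal(f[1, 1, 1], 0.75 * 3 + 0.25 * (-1), tolerance = 1e-12)
})

test_that("vectorized fusion equals the nested-loop oracle on random instances", {
  set.seed(2024)
  for (i in 1:22) {
    K <- sample(2:3, 1)
    h <- sample(2:8, 1)
    w <- sample(2:8, 1)
    m <- sample(1:4, 1)
    r <- sample(0:2, 1)
    phis <- lapply(seq_len(K), function(k) array(rnorm(h * w * m), c(h, w, m)))
    expect_lt(max(abs(fuse_features(phis, r = r) - naive_fuse(phis, r))), 1e-6)
  }
})

test_that("fusion weights are convex and symmetric; fusion is 1-homogeneous", {
  set.seed(5)
  for (i in 1:10) {
    K <- sample(2:3, 1)
    h <- sample(2:6, 1)
    w <- sample(2:6, 1)
    m <- sample(1:4, 1)
    phis <- lapply(seq_len(K), function(k) array(rnorm(h * w * m), c(h, w, m)))
    cs <- lapply(phis, function(p) smooth_activity(activity_map(p), 2))
    wt <- fusion_weights(cs)
    # weights sum to one at every pixel (including any fallback pixels)
    expect_lt(max(abs(apply(wt, c(1, 2), sum) - 1)), 1e-6)
    expect_gte(min(wt), 0)

    fused <- fuse_features(phis, r = 2)
    lo <- Reduce(pmin, phis)
    hi <- Reduce(pmax, phis)
    expect_true(all(fused >= lo - 1e-6 & fused <= hi + 1e-6))

    # permuting the modalities leaves the fusion unchanged
    perm <- sample(K)
    expect_equal(fuse_features(phis[perm], r = 2), fused, tolerance = 1e-9)
    wt_perm <- fusion_weights(cs[perm])
    expect_equal(wt_perm, wt[, , perm, drop = FALSE], tolerance = 1e-12)

    # positive homogeneity: scaling both inputs scales the output
    lam <- runif(1, 0.2, 5)
    scaled <- fuse_features(lapply(phis, function(p) lam * p), r = 2)
    expect_equal(scaled, lam * fused, tolerance = 1e-9)
  }

  # degenerate zero-activity pixels fall back to the uniform convex blend
  z <- array(0, c(2, 2, 2))
  fused0 <- fuse_features(list(z, z), r = 1)
  expect_true(all(fused0 == 0))
})

test_that("feature resize is per-channel bilinear with identity fixed point", {
  set.seed(8)
  phi <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3))
  expect_equal(resize_feature(phi, 4, 5), phi, tolerance = 1e-12)

  const <- array(2.5, dim = c(3, 3, 2))
  up <- resize_feature(const, 7, 9)
  expect_equal(dim(up), c(7, 9, 2))
  expect_true(all(abs(up - 2.5) < 1e-12))

  x <- matrix(c(0, 2, 1, 3), 2, 2)
  got <- resize_feature(array(x, c(2, 2, 1)), 4, 4)
  expect_equal(got[, , 1], naive_bilinear(x, 4, 4), tolerance = 1e-12)
})

test_that("multi-scale fusion averages per-scale fused maps on the deep grid", {
  # identical constant maps at every scale: fixed point
  mk <- function(val, h) array(val, c(h, h, 2))
  t1 <- list(mk(1, 8), mk(1, 4), mk(1, 2))
  fl <- list(mk(1, 8), mk(1, 4), mk(1, 2))
  out <- multi_scale_fuse(t1, fl, r = 2, target_h = 2, target_w = 2)
  expect_equal(out, mk(1, 2), tolerance = 1e-12)

  # single-scale call reduces to fuse + resize
  set.seed(12)
  a <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  b <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  one <- multi_scale_fuse(list(a), list(b), r = 2, target_h = 2, target_w = 2)
  expect_equal(one, resize_feature(fuse_features(list(a, b), r = 2), 2, 2),
               tolerance = 1e-12)

  # distinct constant pairs: the output is the mean of per-scale fusions
  t1c <- list(mk(1, 8), mk(2, 4), mk(6, 2))
  flc <- list(mk(3, 8), mk(2, 4), mk(0, 2))
  got <- multi_scale_fuse(t1c, flc, r = 2, target_h = 2, target_w = 2)
  per_scale <- c(
    fuse_features(list(mk(1, 8), mk(3, 8)), r = 2)[1, 1, 1],
    2,
    fuse_features(list(mk(6, 2), mk(0, 2)), r = 2)[1, 1, 1]
  )
  expect_equal(got[1, 1, 1], mean(per_scale), tolerance = 1e-9)

  # last-scale-only alternative
  last <- multi_scale_fuse(t1c, flc, r = 2, target_h = 2, target_w = 2,
                           combine = "last")
  expect_equal(last[1, 1, 1], per_scale[3], tolerance = 1e-9)

  expect_error(multi_scale_fuse(list(), list(), target_h = 2, target_w = 2),
               "non-empty")
})
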