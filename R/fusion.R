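# L1-norm activity-level feature fusion.
#
# Feature maps from the two modality encoders are combined pixelwise as a
# convex combination f(x,y,m) = sum_i w_i(x,y) phi_i(x,y,m). The weight of
# modality i at a pixel is its smoothed "activity level" -- the L1 norm of
# the feature vector across channels, box-averaged over a (2r+1)^2 window --
# normalized over modalities. The box average uses zero padding with the
# fixed divisor (2r+1)^2, so border activities are shrunk toward zero.

#' Activity-level map of a feature map
#'
#' The activity level at a pixel is the L1 norm of the channel vector:
#' `C(x,y) = sum_m |phi(x,y,m)|`.
#'
#' @param phi H x W x M numeric array (a feature map).
#' @return H x W nonnegative matrix.
#' @export
activity_map <- function(phi) {
  stopifnot(is.array(phi), length(dim(phi)) == 3L)
  d <- dim(phi)
  matrix(rowSums(matrix(abs(phi), d[1] * d[2], d[3])), d[1], d[2])
}

# Banded 0/1 matrix implementing a zero-padded moving window sum of
# half-width r along one axis; symmetric, hence self-adjoint.
box_matrix <- function(n, r) {
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    B[i, j] <- 1
  }
  B
}

#' Smooth an activity map with a zero-padded box average
#'
#' `Chat(x,y) = sum_{|a|<=r, |b|<=r} C(x+a, y+b) / (2r+1)^2`, where terms
#' outside the map are 0 and the divisor is fixed at `(2r+1)^2` regardless of
#' how much of the window falls inside (so the total mass never increases).
#' `r = 0` is the identity.
#'
#' @param c_map H x W nonnegative matrix.
#' @param r window half-width (the field's default fusion setting is 2).
#' @return Smoothed H x W matrix.
#' @export
smooth_activity <- function(c_map, r = 2) {
  if (!is_count(r, min = 0L)) stop_mffc("`r` must be a nonnegative integer")
  if (r == 0) return(c_map)
  Br <- box_matrix(nrow(c_map), r)
  Bc <- box_matrix(ncol(c_map), r)
  (Br %*% c_map %*% Bc) / (2 * r + 1)^2
}

#' Per-pixel fusion weights from smoothed activity maps
#'
#' `w_i(x,y) = Chat_i(x,y) / sum_n Chat_n(x,y)`. Where the denominator is
#' below `eps` all modalities receive the uniform weight `1/K`.
#'
#' @param cs list of K >= 2 smoothed activity maps of identical shape.
#' @param eps degenerate-denominator threshold (default 1e-8).
#' @return H x W x K array of weights; at every pixel the K weights are
#'   nonnegative and sum to 1.
#' @export
fusion_weights <- function(cs, eps = 1e-8) {
  K <- length(cs)
  if (K < 2) stop_mffc("need at least two activity maps")
  d <- dim(cs[[1]])
  for (c_map in cs) {
    if (!all(dim(c_map) == d)) stop_mffc("activity map shape mismatch")
  }
  S <- Reduce(`+`, cs)
  degen <- S < eps
  S[degen] <- 1
  w <- array(0, dim = c(d[1], d[2], K))
  for (i in seq_len(K)) {
    wi <- cs[[i]] / S
    wi[degen] <- 1 / K
    w[, , i] <- wi
  }
  w
}

#' Fuse feature maps by L1-norm activity weighting
#'
#' Computes the activity map of each input, smooths it with the box window of
#' half-width `r`, normalizes across inputs into per-pixel weights, and
#' returns the weighted pixelwise combination of the feature maps.
#'
#' @param phis list of K >= 2 feature maps (H x W x M arrays, same shape).
#' @param r box window half-width (default 2).
#' @param eps degenerate-denominator threshold for the weights.
#' @return H x W x M fused feature map.
#' @export
fuse_features <- function(phis, r = 2, eps = 1e-8) {
  fusion_forward(phis, r = r, eps = eps)$out
}

# Forward pass retaining what the backward pass needs.
fusion_forward <- function(phis, r = 2, eps = 1e-8) {
  K <- length(phis)
  if (K < 2) stop_mffc("need at least two feature maps")
  d <- dim(phis[[1]])
  for (phi in phis) {
    if (!is.array(phi) || length(dim(phi)) != 3L || !all(dim(phi) == d)) {
      stop_mffc("feature map shape mismatch")
    }
  }
  cs <- lapply(phis, function(p) smooth_activity(activity_map(p), r))
  w <- fusion_weights(cs, eps = eps)
  out <- array(0, dim = d)
  for (i in seq_len(K)) {
    out <- out + phis[[i]] * as.vector(w[, , i])  # broadcast over channels
  }
  S <- Reduce(`+`, cs)
  list(out = out,
       cache = list(phis = phis, w = w, S = S, degen = S < eps, r = r, d = d))
}

# Gradient of the fused output w.r.t. every input feature map, through both
# the convex combination and the activity-derived weights:
#   t_i = sum_m dout_m phi_i_m            (per pixel)
#   dChat_j = (t_j - sum_i t_i w_i) / S   (0 at degenerate pixels)
#   dC_j = box(dChat_j) / (2r+1)^2        (box filter is self-adjoint)
#   dphi_j_m = w_j dout_m + sign(phi_j_m) dC_j
fusion_backward <- function(cache, dout) {
  K <- length(cache$phis)
  d <- cache$d
  HW <- d[1] * d[2]
  dmat <- matrix(dout, HW, d[3])
  t_i <- vector("list", K)
  for (i in seq_len(K)) {
    t_i[[i]] <- matrix(rowSums(dmat * matrix(cache$phis[[i]], HW, d[3])),
                       d[1], d[2])
  }
  wbar <- matrix(0, d[1], d[2])
  for (i in seq_len(K)) wbar <- wbar + t_i[[i]] * cache$w[, , i]
  Ssafe <- cache$S
  Ssafe[cache$degen] <- 1
  dphis <- vector("list", K)
  for (j in seq_len(K)) {
    dChat <- (t_i[[j]] - wbar) / Ssafe
    dChat[cache$degen] <- 0
    dC <- smooth_activity(dChat, cache$r)
    dphis[[j]] <- cache$phis[[j]]
    dphis[[j]][] <- dmat * as.vector(cache$w[, , j]) +
      sign(matrix(cache$phis[[j]], HW, d[3])) * as.vector(dC)
  }
  dphis
}

#' Resize a feature map
#'
#' Per-channel bilinear resize; channel count is unchanged.
#'
#' @param phi H x W x M array.
#' @param target_h,target_w output spatial dimensions.
#' @return target_h x target_w x M array.
#' @export
resize_feature <- function(phi, target_h, target_w) {
  stopifnot(is.array(phi), length(dim(phi)) == 3L)
  bilinear_resize(phi, target_h, target_w)
}

#' Multi-scale fusion of two encoders' features
#'
#' For each scale, fuses the CE-T1WI/T2-Flair feature-map pair with
#' [fuse_features()], resizes the fused map to the target geometry, and
#' combines the per-scale results (elementwise mean by default, or the last
#' scale only).
#'
#' @param features_t1ce,features_flair lists of per-scale feature maps; the
#'   pair at each scale must share a shape.
#' @param r box window half-width for the fusion weights.
#' @param target_h,target_w,target_m output geometry (the deep-feature
#'   geometry, e.g. 30 x 30 x 128 for 240-pixel inputs).
#' @param combine `"average"` over scales or `"last"` scale only.
#' @param eps degenerate-denominator threshold.
#' @return target_h x target_w x target_m fused feature map.
#' @export
multi_scale_fuse <- function(features_t1ce, features_flair, r = 2,
                             target_h = 30, target_w = 30, target_m = NULL,
                             combine = c("average", "last"), eps = 1e-8) {
  combine <- match.arg(combine)
  n <- length(features_t1ce)
  if (n < 1 || length(features_flair) != n) {
    stop_mffc("need matching non-empty per-scale feature lists")
  }
  if (is.null(target_m)) target_m <- dim(features_t1ce[[n]])[3]
  per_scale <- vector("list", n)
  for (s in seq_len(n)) {
    if (dim(features_t1ce[[s]])[3] != target_m) {
      stop_mffc("project feature maps to the common channel count first")
    }
    fused <- fuse_features(list(features_t1ce[[s]], features_flair[[s]]),
                           r = r, eps = eps)
    per_scale[[s]] <- resize_feature(fused, target_h, target_w)
  }
  if (combine == "last") return(per_scale[[n]])
  Reduce(`+`, per_scale) / n
}
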