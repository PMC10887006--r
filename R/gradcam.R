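#' Grad-CAM explanation map
#'
#' Gradient-weighted class activation mapping over one of the three deep
#' feature branches. The gradient of the target-class score (the pre-softmax
#' logit) with respect to the chosen branch's feature maps is spatially
#' averaged into per-channel weights; the map is the ReLU of the weighted
#' channel sum, bilinearly upsampled to `out_size` and min-max normalized to
#' `[0, 1]`.
#'
#' @param fit a fitted [mffc_net()], or a raw parameter list (then `cfg`
#'   must be given).
#' @param x_t1ce,x_flair co-registered input slices in `[0, 255]`; resized
#'   to the model grid if necessary.
#' @param target_class class name (`"GBM"`, `"SBM"`, `"PCNSL"`) or index.
#' @param layer which branch to explain: `"fusion"` (default), `"t1ce"` or
#'   `"flair"`.
#' @param cfg [model_config()] when `fit` is a raw parameter list.
#' @param out_size side length of the returned map (default 240).
#' @return `out_size` x `out_size` matrix with values in `[0, 1]`.
#' @export
grad_cam <- function(fit, x_t1ce, x_flair, target_class = NULL,
                     layer = c("fusion", "t1ce", "flair"), cfg = NULL,
                     out_size = 240) {
  layer <- match.arg(layer)
  if (inherits(fit, "mffc_net")) {
    params <- fit$params
    cfg <- fit$config
  } else {
    params <- fit
    if (is.null(cfg)) stop_mffc("`cfg` is required with raw parameters")
  }
  if (!all(dim(x_t1ce) == cfg$input_size)) {
    x_t1ce <- bilinear_resize(x_t1ce, cfg$input_size, cfg$input_size)
    x_flair <- bilinear_resize(x_flair, cfg$input_size, cfg$input_size)
  }
  fw <- net_forward(x_t1ce, x_flair, params, cfg)
  if (is.null(target_class)) {
    target_class <- which.max(fw$probs)
  } else if (is.character(target_class)) {
    target_class <- match(target_class, tumor_classes())
    if (is.na(target_class)) stop_mffc("unknown target class")
  }
  dlogits <- numeric(3)
  dlogits[target_class] <- 1
  dbr <- net_backward(fw, params, cfg, dlogits, branches_only = TRUE)$dbranches
  A <- fw$branches[[layer]]
  dA <- dbr[[layer]]
  d <- dim(A)
  alpha <- colMeans(matrix(dA, d[1] * d[2], d[3]))
  cam <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  cam <- pmax(cam, 0)
  cam <- bilinear_resize(cam, out_size, out_size)
  cam <- pmax(cam, 0)  # interpolation can produce tiny negatives
  rng <- range(cam)
  if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
}

#' In-lesion vs out-of-lesion Grad-CAM contrast
#'
#' Convenience check used to validate localization: mean map value inside
#' the lesion mask versus outside (restricted to the brain when a brain mask
#' is available).
#'
#' @param cam map from [grad_cam()].
#' @param mask logical lesion mask at the same size.
#' @param brain optional logical brain mask.
#' @return List with `inside`, `outside` and `ratio`.
#' @export
gradcam_contrast <- function(cam, mask, brain = NULL) {
  if (!all(dim(cam) == dim(mask))) {
    mask <- bilinear_resize(mask * 1, nrow(cam), ncol(cam), method = "nearest") > 0.5
  }
  outside <- !mask
  if (!is.null(brain)) {
    if (!all(dim(brain) == dim(cam))) {
      brain <- bilinear_resize(brain * 1, nrow(cam), ncol(cam),
                               method = "nearest") > 0.5
    }
    outside <- outside & brain
  }
  inside_mean <- mean(cam[mask])
  outside_mean <- mean(cam[outside])
  list(inside = inside_mean, outside = outside_mean,
       ratio = inside_mean / max(outside_mean, 1e-12))
}
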