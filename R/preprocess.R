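# Separable bilinear interpolation matrix mapping a length `n_in` axis to
# `n_out` samples using half-pixel-centre alignment (the convention of the
# common image libraries): src = (i + 0.5) * n_in/n_out - 0.5, clamped.
# Resizing an H x W image is then A %*% X %*% t(B); the transpose of the same
# matrices is the exact adjoint, which backpropagation uses.
interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  w <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - w[i])
    A[i, hi[i] + 1] <- A[i, hi[i] + 1] + w[i]
  }
  A
}

#' Bilinear image resize
#'
#' Resizes a 2D matrix (or each channel of an H x W x C array) with separable
#' bilinear interpolation (half-pixel-centre alignment). Resizing to the
#' input's own shape is the identity.
#'
#' @param x matrix or 3D array.
#' @param h,w target height and width.
#' @param method `"bilinear"` or `"nearest"` (nearest is used for masks).
#' @return Resized matrix or array.
#' @export
bilinear_resize <- function(x, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is_count(h), is_count(w))
  d <- dim(x)
  if (method == "nearest") {
    ri <- pmin(pmax(round((seq_len(h) - 0.5) * d[1] / h - 0.5), 0), d[1] - 1) + 1
    ci <- pmin(pmax(round((seq_len(w) - 0.5) * d[2] / w - 0.5), 0), d[2] - 1) + 1
    if (length(d) == 2L) return(x[ri, ci, drop = FALSE])
    return(x[ri, ci, , drop = FALSE])
  }
  A <- interp_matrix(d[1], h)
  B <- interp_matrix(d[2], w)
  if (length(d) == 2L) return(A %*% x %*% t(B))
  out <- array(0, dim = c(h, w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  out
}

#' Square crop around the brain mask
#'
#' Returns the smallest axis-aligned square window containing the mask's
#' bounding box, centred on that box; the window is clamped inside the image
#' where possible and zero-padded where the square exceeds the image bounds.
#'
#' @param s 2D numeric matrix (one slice).
#' @param brain_mask logical matrix of the same shape marking brain tissue.
#' @return List with `pixels` (the square crop) and `window`
#'   (`row_start`, `col_start`, `side` in the input frame; starts may be
#'   non-positive when padding occurred).
#' @export
crop_to_brain_square <- function(s, brain_mask) {
  if (!all(dim(s) == dim(brain_mask))) stop_mffc("mask/slice shape mismatch")
  if (!any(brain_mask)) stop_mffc("no foreground: brain mask is empty")
  rows <- range(which(rowSums(brain_mask) > 0))
  cols <- range(which(colSums(brain_mask) > 0))
  h <- rows[2] - rows[1] + 1
  w <- cols[2] - cols[1] + 1
  side <- max(h, w)
  r0 <- rows[1] - floor((side - h) / 2)
  c0 <- cols[1] - floor((side - w) / 2)
  # clamp inside the image when the square fits along that axis
  if (side <= nrow(s)) r0 <- min(max(r0, 1L), nrow(s) - side + 1L)
  if (side <= ncol(s)) c0 <- min(max(c0, 1L), ncol(s) - side + 1L)
  out <- matrix(0, side, side)
  ri <- r0:(r0 + side - 1)
  ci <- c0:(c0 + side - 1)
  rok <- ri >= 1 & ri <= nrow(s)
  cok <- ci >= 1 & ci <= ncol(s)
  out[which(rok), which(cok)] <- s[ri[rok], ci[cok]]
  list(pixels = out, window = list(row_start = r0, col_start = c0, side = side))
}

# Apply a previously computed crop window to another slice (e.g. the second
# modality or the lesion mask), so paired images share the identical frame.
apply_crop_window <- function(s, window) {
  side <- window$side
  out <- matrix(0, side, side)
  ri <- window$row_start:(window$row_start + side - 1)
  ci <- window$col_start:(window$col_start + side - 1)
  rok <- ri >= 1 & ri <= nrow(s)
  cok <- ci >= 1 & ci <= ncol(s)
  out[which(rok), which(cok)] <- s[ri[rok], ci[cok]]
  out
}

#' Rescale a slice to the model grid and normalize to [0, 255]
#'
#' Bilinearly resizes to `target_size` x `target_size`, then maps intensities
#' affinely so the minimum becomes 0 and the maximum 255. A constant slice
#' maps to all zeros.
#'
#' @param s 2D numeric matrix.
#' @param target_size output side length (default 240).
#' @return `target_size` x `target_size` matrix with values in `[0, 255]`.
#' @export
rescale_and_normalize <- function(s, target_size = 240) {
  if (length(s) == 0) stop_mffc("empty slice")
  r <- bilinear_resize(s, target_size, target_size)
  rng <- range(r)
  if (rng[2] > rng[1]) {
    # clamp: the affine map can overshoot by a few ulps
    pmin(pmax((r - rng[1]) * (255 / (rng[2] - rng[1])), 0), 255)
  } else {
    matrix(0, target_size, target_size)
  }
}

#' Construct a patient record
#'
#' A patient record holds the patient id, the histological class label, and
#' an ordered list of co-registered slice pairs. Each slice element is a list
#' with matrices `t1ce` and `flair` on the same pixel grid, a logical lesion
#' `mask` (possibly empty for tumor-free slices), and a logical `brain` mask.
#'
#' @param patient_id character scalar.
#' @param label one of `"GBM"`, `"SBM"`, `"PCNSL"`.
#' @param slices list of slice elements as described above.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, label, slices) {
  label <- match.arg(label, tumor_classes())
  if (length(slices) < 1) stop_mffc("a patient needs at least one slice")
  for (sl in slices) {
    if (is.null(sl$t1ce) || is.null(sl$flair)) {
      stop_mffc("both modalities must be present for every slice")
    }
    if (!all(dim(sl$t1ce) == dim(sl$flair))) {
      stop_mffc("paired slices must share a pixel grid")
    }
  }
  structure(list(patient_id = as.character(patient_id), label = label,
                 slices = slices),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  nt <- sum(vapply(x$slices, function(s) !is.null(s$mask) && any(s$mask), TRUE))
  cat(sprintf("<patient_record> %s (%s): %d slices (%d with tumor)\n",
              x$patient_id, x$label, length(x$slices), nt))
  invisible(x)
}

# Slices whose lesion mask is non-empty ("slices containing the tumor").
tumor_slice_indices <- function(record) {
  which(vapply(record$slices,
               function(s) !is.null(s$mask) && any(s$mask), TRUE))
}

#' Preprocess a patient's slice stack
#'
#' Applies the standardized chain to every slice of a record: mean +/- 3 sd
#' intensity windowing computed per modality over the patient's whole stack,
#' square cropping around the brain mask (the same window for both modalities
#' and the lesion mask), bilinear rescaling to `target_size`, and [0, 255]
#' min-max normalization. Masks are cropped with the same window and resized
#' with nearest-neighbour interpolation.
#'
#' @param record a [patient_record] with native-resolution slices.
#' @param target_size output side length (default 240).
#' @param window_sigma half-width of the intensity window in sd (default 3).
#' @return A [patient_record] whose slices are `target_size` squares in
#'   `[0, 255]`.
#' @export
preprocess_patient <- function(record, target_size = 240, window_sigma = 3) {
  stopifnot(inherits(record, "patient_record"))
  n <- length(record$slices)
  for (mod in c("t1ce", "flair")) {
    stack <- array(unlist(lapply(record$slices, `[[`, mod)),
                   dim = c(dim(record$slices[[1]][[mod]]), n))
    stack <- intensity_window(stack, nsigma = window_sigma)
    for (k in seq_len(n)) record$slices[[k]][[mod]] <- stack[, , k]
  }
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sl <- record$slices[[k]]
    brain <- if (!is.null(sl$brain)) sl$brain else sl$t1ce > min(sl$t1ce)
    cr <- crop_to_brain_square(sl$t1ce, brain)
    t1 <- rescale_and_normalize(cr$pixels, target_size)
    fl <- rescale_and_normalize(apply_crop_window(sl$flair, cr$window),
                                target_size)
    msk <- if (!is.null(sl$mask)) {
      bilinear_resize(apply_crop_window(sl$mask * 1, cr$window),
                      target_size, target_size, method = "nearest") > 0.5
    } else {
      NULL
    }
    brn <- bilinear_resize(apply_crop_window(brain * 1, cr$window),
                           target_size, target_size, method = "nearest") > 0.5
    out[[k]] <- list(t1ce = t1, flair = fl, mask = msk, brain = brn)
  }
  patient_record(record$patient_id, record$label, out)
}

#' Preprocess a cohort
#'
#' @param cohort list of [patient_record]s.
#' @param target_size,window_sigma see [preprocess_patient()].
#' @return List of preprocessed records with a `manifest` attribute
#'   (data.frame of patient_id, label, n_slices, n_tumor_slices).
#' @export
preprocess_cohort <- function(cohort, target_size = 240, window_sigma = 3) {
  out <- lapply(cohort, preprocess_patient, target_size = target_size,
                window_sigma = window_sigma)
  attr(out, "manifest") <- cohort_manifest(out)
  out
}

#' Cohort manifest table
#'
#' @param cohort list of [patient_record]s.
#' @return data.frame with one row per patient.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    label = vapply(cohort, `[[`, "", "label"),
    n_slices = vapply(cohort, function(p) length(p$slices), 0L),
    n_tumor_slices = vapply(cohort, function(p) length(tumor_slice_indices(p)), 0L),
    stringsAsFactors = FALSE
  )
}
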