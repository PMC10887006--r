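#' Stratified patient-level cross-validation folds
#'
#' Partitions patients into `k` folds, stratified by class, at the patient
#' level (all slices of a patient share a fold). Within each class stratum
#' the fold sizes differ by at most one; the assignment is a deterministic
#' function of the inputs and the seed.
#'
#' @param patients list of [patient_record]s, or a data.frame with columns
#'   `patient_id` and `label`.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return Named integer vector mapping patient_id to fold index in
#'   `0:(k-1)`.
#' @export
make_folds <- function(patients, k = 5, seed = 1) {
  if (!is_count(k, 2L)) stop_mffc("`k` must be an integer >= 2")
  if (is.data.frame(patients)) {
    ids <- as.character(patients$patient_id)
    labels <- as.character(patients$label)
  } else {
    ids <- vapply(patients, `[[`, "", "patient_id")
    labels <- vapply(patients, `[[`, "", "label")
  }
  if (anyDuplicated(ids)) stop_mffc("duplicate patient ids")
  assignments <- integer(length(ids))
  names(assignments) <- ids
  for (cl in unique(labels)) {
    members <- ids[labels == cl]
    if (length(members) < k) {
      stop_mffc("class ", cl, " has fewer than ", k, " patients; cannot stratify")
    }
    ord <- with_seed(derive_seed(seed, match(cl, unique(labels))),
                     sample(members))
    assignments[ord] <- rep_len(0:(k - 1L), length(ord))
  }
  assignments
}

#' Aggregate slice probabilities into a patient prediction
#'
#' The patient-level probability vector is the elementwise mean of the
#' per-slice probability vectors (the mean of simplex points stays on the
#' simplex).
#'
#' @param slice_probs N x 3 matrix or list of length-3 probability vectors.
#' @return Length-3 probability vector.
#' @export
aggregate_patient <- function(slice_probs) {
  if (is.list(slice_probs)) slice_probs <- do.call(rbind, slice_probs)
  if (!is.matrix(slice_probs)) slice_probs <- matrix(slice_probs, nrow = 1)
  if (nrow(slice_probs) < 1) stop_mffc("no slices to aggregate")
  colMeans(slice_probs)
}

# One-vs-rest ROC points (FPR, TPR) at every distinct score threshold,
# including the degenerate ends; by trapezoid integration this is the AUC.
roc_points <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(positive)
  nn <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(scores >= t & positive) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !positive) / nn, 0)
  list(thr = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

auc_trapezoid <- function(scores, positive) {
  if (all(positive) || !any(positive)) return(NA_real_)
  rp <- roc_points(scores, positive)
  sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
}

#' ROC cutoff by Youden's J
#'
#' For each class, computes the one-vs-rest ROC over patient scores and
#' returns the threshold maximizing Youden's J = SEN + SPE - 1. Ties are
#' broken toward higher specificity (the higher threshold).
#'
#' @param scores N x 3 matrix of per-patient class scores (or a vector for a
#'   single binary problem).
#' @param labels length-N class labels.
#' @return Named numeric vector of per-class thresholds (or a scalar for the
#'   vector form).
#' @export
roc_cutoff <- function(scores, labels) {
  if (is.matrix(scores)) {
    labels <- as.character(labels)
    classes <- colnames(scores)
    if (is.null(classes)) classes <- tumor_classes()[seq_len(ncol(scores))]
    out <- vapply(seq_along(classes), function(j) {
      roc_cutoff(scores[, j], labels == classes[j])
    }, 0)
    names(out) <- classes
    return(out)
  }
  if (!is.logical(labels)) stop_mffc("for vector scores, `labels` must be logical")
  if (all(labels) || !any(labels)) {
    stop_mffc("both classes must be present to compute a cutoff")
  }
  rp <- roc_points(scores, labels)
  j <- rp$tpr - rp$fpr
  best <- which(j == max(j))
  # ties broken toward higher specificity = the higher threshold; when the
  # scores carry no signal this is the degenerate all-negative end (+Inf,
  # specificity 1)
  max(rp$thr[best])
}

#' Confusion matrix and the full metric suite
#'
#' Builds the 3x3 confusion matrix (rows = true, columns = predicted) and
#' reports accuracy plus macro-averaged one-vs-rest positive predictive
#' value, sensitivity, specificity and F1. When per-patient probability
#' scores are supplied it also reports the macro one-vs-rest trapezoid AUC
#' and the per-class Youden cutoffs.
#'
#' @param preds data.frame with columns `true` and `predicted`, and
#'   optionally one probability column per class (as produced by
#'   [predict.mffc_net()]).
#' @param classes class levels (default GBM/SBM/PCNSL).
#' @return An object of class `mffc_metrics`: list with `confusion`, `acc`,
#'   `ppv`, `sen`, `spe`, `f1`, `auc`, `cutoff`, `per_class` and `n`.
#' @export
confusion_and_metrics <- function(preds, classes = tumor_classes()) {
  stopifnot(is.data.frame(preds), nrow(preds) >= 1,
            all(c("true", "predicted") %in% names(preds)))
  true <- factor(as.character(preds$true), levels = classes)
  pred <- factor(as.character(preds$predicted), levels = classes)
  confusion <- table(true = true, predicted = pred)
  n <- sum(confusion)
  acc <- sum(diag(confusion)) / n

  per_class <- data.frame(class = classes, ppv = NA_real_, sen = NA_real_,
                          spe = NA_real_, f1 = NA_real_, auc = NA_real_,
                          cutoff = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(classes)) {
    tp <- confusion[j, j]
    fn <- sum(confusion[j, ]) - tp
    fp <- sum(confusion[, j]) - tp
    tn <- n - tp - fn - fp
    per_class$ppv[j] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per_class$sen[j] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per_class$spe[j] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    p <- per_class$ppv[j]
    s <- per_class$sen[j]
    per_class$f1[j] <- if (!is.na(p) && !is.na(s) && p + s > 0) {
      2 * p * s / (p + s)
    } else {
      NA_real_
    }
  }
  have_probs <- all(classes %in% names(preds))
  if (have_probs) {
    scores <- as.matrix(preds[, classes, drop = FALSE])
    for (j in seq_along(classes)) {
      pos <- as.character(preds$true) == classes[j]
      if (any(pos) && !all(pos)) {
        per_class$auc[j] <- auc_trapezoid(scores[, j], pos)
        per_class$cutoff[j] <- roc_cutoff(scores[, j], pos)
      }
    }
  }
  structure(list(
    confusion = unclass(confusion), n = n, acc = acc,
    ppv = mean(per_class$ppv, na.rm = TRUE),
    sen = mean(per_class$sen, na.rm = TRUE),
    spe = mean(per_class$spe, na.rm = TRUE),
    f1 = mean(per_class$f1, na.rm = TRUE),
    auc = if (have_probs) mean(per_class$auc, na.rm = TRUE) else NA_real_,
    cutoff = if (have_probs) stats::setNames(per_class$cutoff, classes) else NULL,
    per_class = per_class
  ), class = "mffc_metrics")
}

#' @export
print.mffc_metrics <- function(x, digits = 3, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf("\nACC %.3f | PPV %.3f | SEN %.3f | SPE %.3f | F1 %.3f",
              x$acc, x$ppv, x$sen, x$spe, x$f1))
  if (!is.na(x$auc)) cat(sprintf(" | AUC %.3f", x$auc))
  cat(sprintf("   (n = %d patients, macro one-vs-rest)\n", x$n))
  invisible(x)
}

#' Plot one-vs-rest ROC curves
#'
#' @param x an `mffc_metrics` object computed from predictions that include
#'   probability columns.
#' @param preds the prediction data.frame used to compute `x`.
#' @param classes class levels.
#' @param ... unused.
#' @export
plot.mffc_metrics <- function(x, preds, classes = tumor_classes(), ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = "One-vs-rest ROC")
  cols <- c("#D55E00", "#0072B2", "#009E73")
  for (j in seq_along(classes)) {
    rp <- roc_points(preds[[classes[j]]],
                     as.character(preds$true) == classes[j])
    graphics::lines(rp$fpr, rp$tpr, col = cols[j], lwd = 2)
  }
  graphics::legend("bottomright", legend = sprintf("%s (AUC %.3f)", classes,
                                                   x$per_class$auc),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Net reclassification improvement between two classifiers
#'
#' Categorical NRI on predicted labels: the proportion of patients the new
#' classifier gets right and the reference gets wrong, minus the proportion
#' the new gets wrong and the reference gets right. Identical classifiers
#' score 0; a perfect classifier against an always-wrong reference scores 1.
#'
#' @param new_pred,ref_pred predicted labels of the two classifiers, aligned
#'   to the same patients.
#' @param true true labels.
#' @return Scalar in `[-1, 1]`.
#' @export
nri <- function(new_pred, ref_pred, true) {
  if (length(new_pred) != length(ref_pred) ||
      length(new_pred) != length(true)) {
    stop_mffc("prediction sets must cover the same patients")
  }
  new_ok <- as.character(new_pred) == as.character(true)
  ref_ok <- as.character(ref_pred) == as.character(true)
  (sum(new_ok & !ref_ok) - sum(!new_ok & ref_ok)) / length(true)
}

#' Patient-level cross-validated evaluation
#'
#' Splits the cohort into stratified patient-level folds, trains one model
#' per fold on the remaining patients (with a fold-derived parameter seed),
#' predicts the held-out patients, pools the predictions, and computes the
#' metric suite.
#'
#' @param cohort list of preprocessed [patient_record]s.
#' @param config a [model_config()].
#' @param train a [train_config()] (its `folds` and `seed` drive the split).
#' @param folds optionally restrict to a subset of fold indices (e.g. `0`
#'   for a single held-out fold).
#' @param verbose print progress.
#' @return List with `predictions` (pooled data.frame), `metrics`
#'   (an `mffc_metrics`), `fold_assignments`, and `fits` (per-fold models).
#' @export
cross_validate <- function(cohort, config = model_config(),
                           train = train_config(), folds = NULL,
                           verbose = FALSE) {
  assignments <- make_folds(cohort, k = train$folds, seed = train$seed)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  run_folds <- if (is.null(folds)) 0:(train$folds - 1L) else as.integer(folds)
  preds <- list()
  fits <- list()
  for (f in run_folds) {
    test_ids <- names(assignments)[assignments == f]
    train_set <- cohort[!(ids %in% test_ids)]
    test_set <- cohort[ids %in% test_ids]
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, f + 1L)
    tc_f <- train
    tc_f$seed <- derive_seed(train$seed, 100L + f)
    if (verbose) message(sprintf("fold %d: %d train / %d test patients",
                                 f, length(train_set), length(test_set)))
    fit <- mffc_net(train_set, cfg_f, tc_f, verbose = verbose)
    p <- predict(fit, test_set, type = "patient")
    p$fold <- f
    preds[[length(preds) + 1L]] <- p
    fits[[length(fits) + 1L]] <- fit
  }
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       metrics = confusion_and_metrics(predictions),
       fold_assignments = assignments,
       fits = fits)
}
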