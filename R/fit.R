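#' Training configuration
#'
#' Optimization protocol. The reference protocol is Adam with learning rate
#' 1e-4, weight decay 1e-5 and 100 epochs under 5-fold patient-level
#' cross-validation; small phantom studies typically use fewer epochs and a
#' larger learning rate (see the package vignette).
#'
#' @param epochs number of passes over the training slices.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient (coupled, as in the
#'   common Adam implementations).
#' @param optimizer only `"adam"` is provided.
#' @param batch_size slices per gradient step.
#' @param folds cross-validation folds.
#' @param seed seed controlling shuffling and fold-derived streams.
#' @return An object of class `mffc_train_config`.
#' @export
train_config <- function(epochs = 100, learning_rate = 1e-4,
                         weight_decay = 1e-5, optimizer = "adam",
                         batch_size = 16, folds = 5, seed = 1) {
  stopifnot(is_count(epochs), learning_rate >= 0, weight_decay >= 0,
            is_count(batch_size), is_count(folds, 2L))
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, optimizer = optimizer,
                 batch_size = as.integer(batch_size), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "mffc_train_config")
}

adam_init <- function(params) {
  paths <- leaf_paths(params)
  list(paths = paths,
       m = lapply(paths, function(p) get_leaf(params, p) * 0),
       v = lapply(paths, function(p) get_leaf(params, p) * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$paths)) {
    p <- state$paths[[i]]
    w <- get_leaf(params, p)
    g <- get_leaf(grads, p)
    if (is.null(g)) next
    if (is.null(dim(w))) dim(g) <- NULL  # compiled grads arrive as n x 1
    if (wd > 0) g <- g + wd * w
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    w <- w - lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    params <- set_leaf(params, p, w)
  }
  list(params = params, state = state)
}

# Flatten a cohort into per-slice training examples (tumor slices only),
# resized to the model's input grid when necessary.
collect_slices <- function(cohort, cfg) {
  xs <- list()
  ids <- character()
  labels <- character()
  for (p in cohort) {
    for (k in tumor_slice_indices(p)) {
      sl <- p$slices[[k]]
      t1 <- sl$t1ce
      fl <- sl$flair
      if (!all(dim(t1) == cfg$input_size)) {
        t1 <- bilinear_resize(t1, cfg$input_size, cfg$input_size)
        fl <- bilinear_resize(fl, cfg$input_size, cfg$input_size)
      }
      xs[[length(xs) + 1L]] <- list(t1ce = t1, flair = fl)
      ids <- c(ids, p$patient_id)
      labels <- c(labels, p$label)
    }
  }
  if (length(xs) == 0) stop_mffc("no tumor-bearing slices in the cohort")
  list(x = xs, patient_id = ids, label = labels)
}

# One optimization run over a prepared slice set. Returns final parameters
# and the per-epoch mean loss history.
train_slices <- function(slices, params, cfg, tc, verbose = FALSE) {
  state <- adam_init(params)
  n <- length(slices$x)
  y <- one_hot(slices$label)
  history <- numeric(tc$epochs)
  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(derive_seed(tc$seed, ep), sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (i in idx) {
        fw <- net_forward(slices$x[[i]]$t1ce, slices$x[[i]]$flair, params, cfg)
        bloss <- bloss - sum(y[i, ] * log(pmax(fw$probs, 1e-12)))
        dlogits <- as.numeric(fw$probs - y[i, ]) / length(idx)
        g <- net_backward(fw, params, cfg, dlogits)
        grads <- if (is.null(grads)) g else add_grads(grads, g)
      }
      ep_loss <- ep_loss + bloss
      upd <- adam_step(params, grads, state, tc$learning_rate, tc$weight_decay)
      params <- upd$params
      state <- upd$state
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, tc$epochs,
                                 history[ep]))
  }
  list(params = params, history = history)
}

add_grads <- function(a, b) {
  for (p in leaf_paths(b)) {
    ga <- get_leaf(a, p)
    a <- set_leaf(a, p, if (is.null(ga)) get_leaf(b, p) else ga + get_leaf(b, p))
  }
  a
}

#' Train a fold
#'
#' Runs the Adam protocol on the tumor-bearing slices of the given patients
#' and returns the trained parameters with the per-epoch loss history.
#'
#' @param cohort list of preprocessed [patient_record]s (the training split).
#' @param cfg a [model_config()].
#' @param tc a [train_config()].
#' @param params optional starting parameters (default: fresh
#'   [init_params()]).
#' @param verbose print per-epoch losses.
#' @return List with `params` and `history` (length `tc$epochs`).
#' @export
train_fold <- function(cohort, cfg, tc, params = NULL, verbose = FALSE) {
  if (length(cohort) == 0) stop_mffc("empty training data")
  slices <- collect_slices(cohort, cfg)
  if (is.null(params)) params <- init_params(cfg)
  train_slices(slices, params, cfg, tc, verbose = verbose)
}

#' Fit the multi-modal feature-fusion classifier
#'
#' Trains the full network -- two DenseBlock encoders, L1-norm activity
#' fusion, spatial-channel attention and the softmax decoder -- on the
#' tumor-bearing slices of a cohort, minimizing the mean cross-entropy over
#' slices with Adam. Per-patient predictions average the slice
#' probabilities.
#'
#' @param cohort list of preprocessed [patient_record]s.
#' @param config a [model_config()].
#' @param train a [train_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `mffc_net` with components `params`, `config`,
#'   `train`, `history`, `classes` and `n_slices`.
#' @examples
#' \donttest{
#' spec <- phantom_spec(patients_per_class = 2, seed = 1)
#' cohort <- preprocess_cohort(generate_cohort(spec), target_size = 64)
#' cfg <- model_config(input_size = 16, stem_channels = 2, growth_rate = 2,
#'                     trans_channels = c(4, 4, 4), fc_hidden = 8)
#' fit <- mffc_net(cohort, cfg, train_config(epochs = 1, batch_size = 4))
#' predict(fit, cohort)
#' }
#' @export
mffc_net <- function(cohort, config = model_config(), train = train_config(),
                     verbose = FALSE) {
  stopifnot(inherits(config, "mffc_config"), inherits(train, "mffc_train_config"))
  res <- train_fold(cohort, config, train, verbose = verbose)
  structure(list(params = res$params, config = config, train = train,
                 history = res$history, classes = tumor_classes(),
                 n_slices = length(collect_slices(cohort, config)$x),
                 n_patients = length(cohort), call = match.call()),
            class = "mffc_net")
}

#' @export
print.mffc_net <- function(x, ...) {
  cat("Multi-modal feature-fusion classifier (CE-T1WI + T2-Flair)\n")
  print(x$config)
  cat(sprintf("  trained on %d slices from %d patients, %d epochs; final loss %.4f\n",
              x$n_slices, x$n_patients, length(x$history),
              x$history[length(x$history)]))
  invisible(x)
}

#' @export
summary.mffc_net <- function(object, ...) {
  out <- list(config = object$config, train = object$train,
              n_parameters = n_parameters(object$params),
              history = object$history)
  class(out) <- "summary.mffc_net"
  out
}

#' @export
print.summary.mffc_net <- function(x, ...) {
  print(x$config)
  cat(sprintf("Parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  cat(sprintf("Training: %d epochs, lr %g, weight decay %g, batch %d\n",
              x$train$epochs, x$train$learning_rate, x$train$weight_decay,
              x$train$batch_size))
  cat(sprintf("Loss: first %.4f -> final %.4f\n",
              x$history[1], x$history[length(x$history)]))
  invisible(x)
}

#' @export
coef.mffc_net <- function(object, ...) object$params

#' Plot the training loss curve
#'
#' @param x a fitted [mffc_net()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.mffc_net <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean cross-entropy",
                 main = "Training loss", ...)
  invisible(x)
}

#' Predict tumor class probabilities
#'
#' @param object a fitted [mffc_net()].
#' @param newdata a list of [patient_record]s (or a single record).
#' @param type `"patient"` for slice-averaged per-patient predictions,
#'   `"slice"` for raw per-slice probabilities.
#' @param ... unused.
#' @return For `type = "patient"`: a data.frame with one row per patient
#'   (probabilities per class, `predicted`, and `true` if labels are
#'   present). For `type = "slice"`: a data.frame with one row per
#'   tumor-bearing slice.
#' @export
predict.mffc_net <- function(object, newdata,
                             type = c("patient", "slice"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "patient_record")) newdata <- list(newdata)
  cfg <- object$config
  slices <- collect_slices(newdata, cfg)
  n <- length(slices$x)
  probs <- matrix(0, n, 3, dimnames = list(NULL, object$classes))
  for (i in seq_len(n)) {
    probs[i, ] <- net_forward(slices$x[[i]]$t1ce, slices$x[[i]]$flair,
                              object$params, cfg)$probs
  }
  slice_df <- data.frame(patient_id = slices$patient_id,
                         true = slices$label, stringsAsFactors = FALSE)
  slice_df <- cbind(slice_df, as.data.frame(probs))
  if (type == "slice") return(slice_df)
  ids <- unique(slices$patient_id)
  agg <- t(vapply(ids, function(id) {
    aggregate_patient(probs[slices$patient_id == id, , drop = FALSE])
  }, numeric(3)))
  colnames(agg) <- object$classes
  out <- data.frame(patient_id = ids,
                    true = slices$label[match(ids, slices$patient_id)],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(agg))
  out$predicted <- object$classes[max.col(agg, ties.method = "first")]
  rownames(out) <- NULL
  out
}
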