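# End-to-end workflow: generate (or load) a cohort, preprocess, train,
# evaluate on held-out folds, and optionally render Grad-CAM examples.
# Configured by a YAML file; every artifact records the config hash so a
# rerun with identical configuration is identifiable and, with fixed seeds,
# byte-identical in its metrics report.

pipeline_defaults <- function() {
  list(
    config_version = "1",
    seed = 1,
    data_dir = NULL,
    phantom = list(image_size = 128, noise_sd = 0.05, patients_per_class = 10,
                   slices_per_patient = c(3, 6), background_slices = c(1, 2)),
    preprocess = list(target_size = 240, window_sigma = 3),
    model = list(input_size = 64, stem_channels = 4, growth_rate = 4,
                 block_layers = 5, trans_channels = c(8, 12, 16),
                 fusion_radius = 2, fusion_scales = c(1, 2, 3),
                 fusion_combine = "average", fc_hidden = 32,
                 attention = TRUE),
    train = list(epochs = 2, learning_rate = 1e-3, weight_decay = 1e-5,
                 batch_size = 16, folds = 5),
    evaluate = list(folds = 0),
    gradcam = list(enabled = FALSE, n_examples = 2, layer = "fusion")
  )
}

# Merge user config over defaults, rejecting unknown keys at both levels.
validate_config <- function(user) {
  defs <- pipeline_defaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad)) {
    stop_mffc("unknown config keys: ", paste(bad, collapse = ", "))
  }
  for (sec in names(user)) {
    if (is.list(defs[[sec]]) && !is.null(names(defs[[sec]]))) {
      if (!is.list(user[[sec]])) stop_mffc("config key `", sec, "` must be a section")
      badk <- setdiff(names(user[[sec]]), names(defs[[sec]]))
      if (length(badk)) {
        stop_mffc("unknown keys in `", sec, "`: ", paste(badk, collapse = ", "))
      }
      defs[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      defs[[sec]] <- user[[sec]]
    }
  }
  if (!is.null(defs$data_dir) && !dir.exists(defs$data_dir)) {
    stop_mffc("config key `data_dir` points to a missing directory: ",
              defs$data_dir)
  }
  defs
}

# Deterministic polynomial hash of the canonical config serialization.
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15,
                                                vec.len = 1e6)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

read_config <- function(path) {
  if (!file.exists(path)) stop_mffc("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and per-patient NIfTI
#'   volumes (`<id>_t1ce`, `<id>_flair`, `<id>_mask`).
#' @return List of [patient_record]s.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$patient_id[i]
    t1 <- read_volume(file.path(dir, paste0(id, "_t1ce.nii.gz")))
    fl <- read_volume(file.path(dir, paste0(id, "_flair.nii.gz")))
    mk <- read_volume(file.path(dir, paste0(id, "_mask.nii.gz")))
    t1s <- volume_slices(t1)
    fls <- volume_slices(fl)
    mks <- volume_slices(mk)
    slices <- lapply(seq_along(t1s), function(k) {
      list(t1ce = t1s[[k]], flair = fls[[k]], mask = mks[[k]] > 0.5,
           brain = NULL)
    })
    patient_record(id, manifest$label[i], slices)
  })
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes generate (or load) -> preprocess -> cross-validated train/eval
#' -> (optional) Grad-CAM, writing `metrics.json`, `predictions.csv`,
#' `loss_history.csv`, figures and a log into `out_dir`. All stages derive
#' their seeds from the single config seed, so a rerun with the same config
#' reproduces the identical metrics report.
#'
#' @param config path to a YAML config file, or a config list.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with `metrics`, `predictions`, `config` and
#'   `hash`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cf <- if (is.character(config)) read_config(config) else validate_config(config)
  if (!is.null(seed)) cf$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cf)
  logf <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE,
                               sep = "")
  cat(sprintf("config_hash: %s\n", hash), file = logf)
  logline("seed: %d", cf$seed)

  cohort <- if (!is.null(cf$data_dir)) {
    logline("loading cohort from %s", cf$data_dir)
    read_cohort(cf$data_dir)
  } else {
    spec <- phantom_spec(image_size = cf$phantom$image_size,
                         noise_sd = cf$phantom$noise_sd,
                         patients_per_class = cf$phantom$patients_per_class,
                         slices_per_patient = cf$phantom$slices_per_patient,
                         background_slices = cf$phantom$background_slices,
                         seed = cf$seed)
    logline("generating %d phantom patients", 3 * spec$patients_per_class)
    generate_cohort(spec)
  }
  pre <- preprocess_cohort(cohort, target_size = cf$preprocess$target_size,
                           window_sigma = cf$preprocess$window_sigma)
  utils::write.csv(attr(pre, "manifest"), file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  cfg <- model_config(input_size = cf$model$input_size,
                      stem_channels = cf$model$stem_channels,
                      growth_rate = cf$model$growth_rate,
                      block_layers = cf$model$block_layers,
                      trans_channels = cf$model$trans_channels,
                      fusion_radius = cf$model$fusion_radius,
                      fusion_scales = cf$model$fusion_scales,
                      fusion_combine = cf$model$fusion_combine,
                      fc_hidden = cf$model$fc_hidden,
                      attention = cf$model$attention,
                      seed = derive_seed(cf$seed, 11L))
  tc <- train_config(epochs = cf$train$epochs,
                     learning_rate = cf$train$learning_rate,
                     weight_decay = cf$train$weight_decay,
                     batch_size = cf$train$batch_size,
                     folds = cf$train$folds,
                     seed = derive_seed(cf$seed, 12L))
  folds <- if (identical(cf$evaluate$folds, "all")) NULL else cf$evaluate$folds
  cv <- cross_validate(pre, cfg, tc, folds = folds)
  logline("evaluated folds: %s",
          paste(unique(cv$predictions$fold), collapse = ","))

  utils::write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  hist_df <- do.call(rbind, lapply(seq_along(cv$fits), function(i) {
    data.frame(fold = unique(cv$predictions$fold)[i],
               epoch = seq_along(cv$fits[[i]]$history),
               loss = cv$fits[[i]]$history)
  }))
  utils::write.csv(hist_df, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)

  m <- cv$metrics
  report <- list(config_hash = hash, seed = cf$seed,
                 n_patients = m$n,
                 confusion = unname(m$confusion),
                 acc = m$acc, ppv = m$ppv, sen = m$sen, spe = m$spe,
                 f1 = m$f1, auc = m$auc,
                 cutoff = as.list(ifelse(is.finite(m$cutoff), m$cutoff, 1)))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  grDevices::png(file.path(out_dir, "roc.png"), width = 600, height = 600)
  plot(m, cv$predictions)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "confusion.png"), width = 500, height = 500)
  plot_confusion(m$confusion)
  grDevices::dev.off()

  if (isTRUE(cf$gradcam$enabled) && length(cv$fits)) {
    fit <- cv$fits[[1]]
    test_ids <- cv$predictions$patient_id
    done <- 0
    for (p in pre) {
      if (done >= cf$gradcam$n_examples) break
      if (!(p$patient_id %in% test_ids)) next
      k <- tumor_slice_indices(p)[1]
      cam <- grad_cam(fit, p$slices[[k]]$t1ce, p$slices[[k]]$flair,
                      target_class = p$label, layer = cf$gradcam$layer,
                      out_size = cf$preprocess$target_size)
      grDevices::png(file.path(out_dir, sprintf("gradcam_%s.png", p$patient_id)),
                     width = 480, height = 480)
      graphics::image(cam, col = grDevices::hcl.colors(64, "inferno"),
                      axes = FALSE, main = sprintf("Grad-CAM %s (%s)",
                                                   p$patient_id, p$label))
      grDevices::dev.off()
      done <- done + 1
    }
  }
  logline("done")
  invisible(list(metrics = m, predictions = cv$predictions, config = cf,
                 hash = hash))
}

plot_confusion <- function(confusion) {
  cl <- colnames(confusion)
  if (is.null(cl)) cl <- tumor_classes()
  graphics::image(seq_len(3), seq_len(3), t(confusion[3:1, ]),
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "Confusion matrix")
  graphics::axis(1, at = 1:3, labels = cl)
  graphics::axis(2, at = 1:3, labels = rev(cl))
  for (i in 1:3) for (j in 1:3) {
    graphics::text(j, 4 - i, confusion[i, j])
  }
}
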