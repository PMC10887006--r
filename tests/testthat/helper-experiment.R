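# The end-to-end phantom recovery experiment is expensive, so it runs once
# per test session and is shared by the tests that need a trained model:
# a 90-patient cohort (30 per class) preprocessed through the standard chain,
# a reduced-width model trained on four folds, and the fifth fold held out.

.experiment_cache <- new.env(parent = emptyenv())

phantom_experiment <- function() {
  if (!is.null(.experiment_cache$res)) {
    return(.experiment_cache$res)
  }
  spec <- phantom_spec(seed = 20240901)
  pre <- preprocess_cohort(generate_cohort(spec), target_size = 240)
  folds <- make_folds(pre, k = 5, seed = 11)
  ids <- vapply(pre, `[[`, "", "patient_id")
  train_set <- pre[folds[ids] != 0]
  test_set <- pre[folds[ids] == 0]
  cfg <- model_config(input_size = 64, stem_channels = 4, growth_rate = 4,
                      trans_channels = c(8, 12, 16), fc_hidden = 32,
                      seed = 101)
  tc <- train_config(epochs = 8, learning_rate = 1e-3, batch_size = 16,
                     seed = 202)
  fit <- mffc_net(train_set, cfg, tc)
  preds <- predict(fit, test_set, type = "patient")
  .experiment_cache$res <- list(fit = fit, test_set = test_set, preds = preds,
                                acc = mean(preds$predicted == preds$true))
  .experiment_cache$res
}
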