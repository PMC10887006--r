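fake_patients <- function(n_per_class) {
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(sum(n_per_class))),
    label = rep(c("GBM", "SBM", "PCNSL"), times = n_per_class),
    stringsAsFactors = FALSE
  )
  df
}

test_that("stratified folds are disjoint, covering, patient-atomic and seeded", {
  df <- fake_patients(c(13, 9, 11))
  for (seed in c(1, 7, 1234)) {
    f <- make_folds(df, k = 5, seed = seed)
    expect_setequal(names(f), df$patient_id)  # coverage, one fold per patient
    expect_true(all(f %in% 0:4))
    # per-class stratum sizes differ by at most one
    for (cl in unique(df$label)) {
      sizes <- table(factor(f[df$patient_id[df$label == cl]], levels = 0:4))
      expect_lte(max(sizes) - min(sizes), 1)
    }
    expect_identical(f, make_folds(df, k = 5, seed = seed))
  }
  expect_false(identical(make_folds(df, 5, 1), make_folds(df, 5, 2)))

  expect_error(make_folds(fake_patients(c(4, 5, 5)), k = 5), "fewer than")
  expect_error(make_folds(df, k = 1), ">= 2")
})

test_that("a 1225-patient cohort splits into five folds of 245", {
  df <- fake_patients(c(490, 440, 295))  # 1225 patients
  f <- make_folds(df, k = 5, seed = 3)
  expect_length(f, 1225)
  expect_equal(unname(table(f)), rep(245L, 5), ignore_attr = TRUE)

  # minimal stratification: 2 per class, 2 folds -> one of each per fold
  f2 <- make_folds(fake_patients(c(2, 2, 2)), k = 2, seed = 1)
  df2 <- fake_patients(c(2, 2, 2))
  for (cl in c("GBM", "SBM", "PCNSL")) {
    expect_setequal(unname(f2[df2$patient_id[df2$label == cl]]), c(0L, 1L))
  }
})

test_that("patient aggregation is the probability mean on the simplex", {
  expect_equal(aggregate_patient(rbind(c(0.9, 0.05, 0.05), c(0.7, 0.2, 0.1))),
               c(0.8, 0.125, 0.075))
  expect_equal(aggregate_patient(matrix(c(0.2, 0.5, 0.3), 1)), c(0.2, 0.5, 0.3))
  same <- matrix(rep(c(0.1, 0.6, 0.3), 5), 5, byrow = TRUE)
  expect_equal(aggregate_patient(same), c(0.1, 0.6, 0.3))
  expect_error(aggregate_patient(matrix(0, 0, 3)), "no slices")

  set.seed(4)
  for (i in 1:5) {
    p <- matrix(rexp(15), 5)
    p <- p / rowSums(p)
    expect_equal(sum(aggregate_patient(p)), 1, tolerance = 1e-12)
  }
})

test_that("the ROC cutoff maximizes Youden's J with a specificity tie-break", {
  # perfectly separated: chosen threshold reaches SEN = SPE = 1
  sc <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  thr <- roc_cutoff(sc, lab)
  expect_gt(thr, 0.1)
  expect_lte(thr, 0.9)
  expect_equal(mean(sc[lab] >= thr), 1)   # sensitivity
  expect_equal(mean(sc[!lab] < thr), 1)   # specificity

  # uninformative scores: J = 0 everywhere, tie-break to the all-negative end
  flat <- rep(0.4, 6)
  thr0 <- roc_cutoff(flat, lab)
  expect_true(mean(flat[!lab] < thr0) == 1)  # SPE = 1 at the degenerate end

  # hand case with one injected error: matches an exhaustive sweep
  sc2 <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lab2 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  thr2 <- roc_cutoff(sc2, lab2)
  sweep_thr <- sort(unique(c(sc2, 1)), decreasing = TRUE)
  js <- vapply(sweep_thr, function(t) {
    mean(sc2[lab2] >= t) + mean(sc2[!lab2] < t) - 1
  }, 0)
  best_j <- max(js)
  got_j <- mean(sc2[lab2] >= thr2) + mean(sc2[!lab2] < thr2) - 1
  expect_equal(got_j, best_j, tolerance = 1e-12)

  expect_error(roc_cutoff(sc, rep(TRUE, 6)), "both classes")
})

test_that("metric suite matches hand computation on the printed confusion case", {
  # confusion [[8,1,1],[0,9,1],[1,0,9]] over 30 patients
  preds <- data.frame(
    true = rep(c("GBM", "SBM", "PCNSL"), each = 10),
    predicted = c(rep("GBM", 8), "SBM", "PCNSL",
                  rep("SBM", 9), "PCNSL",
                  "GBM", rep("PCNSL", 9)),
    stringsAsFactors = FALSE
  )
  m <- confusion_and_metrics(preds)
  expect_equal(unname(m$confusion),
               matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3), ignore_attr = TRUE)
  expect_equal(m$acc, 26 / 30, tolerance = 1e-12)
  expect_equal(m$sen, mean(c(8, 9, 9) / 10), tolerance = 1e-12)
  expect_equal(m$ppv, mean(c(8 / 9, 9 / 10, 9 / 11)), tolerance = 1e-12)
  expect_equal(m$spe, mean(c(19 / 20, 19 / 20, 18 / 20)), tolerance = 1e-12)
  f1 <- function(p, s) 2 * p * s / (p + s)
  expect_equal(m$f1, mean(c(f1(8 / 9, 0.8), f1(9 / 10, 0.9), f1(9 / 11, 0.9))),
               tolerance = 1e-12)

  # perfect predictions
  mp <- confusion_and_metrics(data.frame(true = preds$true,
                                         predicted = preds$true))
  expect_equal(c(mp$acc, mp$ppv, mp$sen, mp$spe, mp$f1), rep(1, 5))
})

test_that("macro AUC matches pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 60
  truth <- sample(c("GBM", "SBM", "PCNSL"), n, replace = TRUE)
  sc <- matrix(rexp(3 * n), n, 3, dimnames = list(NULL, c("GBM", "SBM", "PCNSL")))
  sc <- sc / rowSums(sc)
  preds <- data.frame(true = truth, predicted = truth, stringsAsFactors = FALSE)
  preds <- cbind(preds, as.data.frame(sc))
  m <- confusion_and_metrics(preds)
  ref <- mean(vapply(c("GBM", "SBM", "PCNSL"), function(cl) {
    as.numeric(pROC::auc(pROC::roc(truth == cl, sc[, cl], quiet = TRUE,
                                   direction = "<")))
  }, 0))
  expect_equal(m$auc, ref, tolerance = 1e-9)

  # strictly monotone rescoring leaves the AUC unchanged
  preds2 <- preds
  for (cl in c("GBM", "SBM", "PCNSL")) preds2[[cl]] <- exp(3 * preds2[[cl]])
  expect_equal(confusion_and_metrics(preds2)$auc, m$auc, tolerance = 1e-12)
})

test_that("uniform random scores give macro AUC near one half", {
  set.seed(99)
  n <- 3000
  truth <- rep(c("GBM", "SBM", "PCNSL"), each = n / 3)
  sc <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("GBM", "SBM", "PCNSL")))
  preds <- data.frame(true = truth,
                      predicted = c("GBM", "SBM", "PCNSL")[max.col(sc)],
                      stringsAsFactors = FALSE)
  preds <- cbind(preds, as.data.frame(sc))
  m <- confusion_and_metrics(preds)
  expect_lt(abs(m$auc - 0.5), 0.05)
})

test_that("categorical NRI counts net correct reclassifications", {
  truth <- rep("GBM", 10)
  ref <- c(rep("GBM", 5), rep("SBM", 5))      # 5 correct
  new <- c(rep("GBM", 4), "SBM", "GBM", "GBM", rep("SBM", 3))  # 6 correct
  # new correct where ref wrong: positions 6,7 (2); ref correct where new
  # wrong: position 5 (1)
  expect_equal(nri(new, ref, truth), (2 - 1) / 10)
  expect_equal(nri(ref, ref, truth), 0)
  expect_equal(nri(truth, rep("SBM", 10), truth), 1)
  expect_equal(nri(rep("SBM", 10), truth, truth), -1)
  expect_error(nri(new, ref[1:5], truth), "same patients")
})

test_that("training runs, freezes at zero learning rate, and reduces loss", {
  spec <- phantom_spec(patients_per_class = 2, slices_per_patient = c(2, 2),
                       background_slices = c(1, 1), seed = 31)
  cohort <- preprocess_cohort(generate_cohort(spec), target_size = 16)
  cfg <- tiny_config(seed = 5, input_size = 16)

  # 1-epoch smoke: one history entry, parameters returned
  res <- train_fold(cohort, cfg, train_config(epochs = 1, batch_size = 4,
                                              learning_rate = 1e-3))
  expect_length(res$history, 1)
  expect_true(is.finite(res$history))

  # zero learning rate: parameters unchanged after an epoch
  p0 <- init_params(cfg)
  frozen <- train_fold(cohort, cfg, train_config(epochs = 1, batch_size = 4,
                                                 learning_rate = 0,
                                                 weight_decay = 0),
                       params = p0)
  expect_identical(frozen$params, p0)

  # optimization sanity: loss decreases markedly on a learnable toy problem
  res2 <- train_fold(cohort, cfg, train_config(epochs = 12, batch_size = 4,
                                               learning_rate = 3e-3, seed = 2))
  expect_lt(res2$history[12], res2$history[1])

  expect_error(train_fold(list(), cfg, train_config(epochs = 1)), "empty")
})

test_that("the fitted-model interface exposes the usual S3 surface", {
  spec <- phantom_spec(patients_per_class = 2, slices_per_patient = c(2, 3),
                       seed = 41)
  cohort <- preprocess_cohort(generate_cohort(spec), target_size = 16)
  fit <- mffc_net(cohort, tiny_config(seed = 8, input_size = 16),
                  train_config(epochs = 2, batch_size = 4,
                               learning_rate = 1e-3))
  expect_s3_class(fit, "mffc_net")
  expect_output(print(fit), "feature-fusion")
  expect_output(print(summary(fit)), "Parameters")
  expect_type(coef(fit), "list")

  ps <- predict(fit, cohort, type = "slice")
  expect_true(all(abs(rowSums(ps[, c("GBM", "SBM", "PCNSL")]) - 1) < 1e-6))
  pp <- predict(fit, cohort, type = "patient")
  expect_equal(nrow(pp), length(cohort))
  expect_true(all(pp$predicted %in% c("GBM", "SBM", "PCNSL")))
  # patient rows aggregate exactly the patient's slice rows
  one <- pp[pp$patient_id == cohort[[1]]$patient_id, c("GBM", "SBM", "PCNSL")]
  sl <- ps[ps$patient_id == cohort[[1]]$patient_id, c("GBM", "SBM", "PCNSL")]
  expect_equal(unlist(one), colMeans(sl), tolerance = 1e-12,
               ignore_attr = TRUE)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
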