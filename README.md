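# mffcnet

Three-class brain-tumor classification — glioblastoma (GBM), solitary brain
metastasis (SBM), primary CNS lymphoma (PCNSL) — from co-registered
multi-modal MRI (CE-T1WI + T2-Flair), for imaging researchers who want a
fully inspectable, dependency-light reference implementation of
feature-level modality fusion.

The model runs two parallel DenseBlock encoders (three blocks of five
densely connected 3x3 conv layers each, per modality), fuses the per-scale
feature maps with an **L1-norm activity-level fusion layer**

```
f_fusion(x,y,m) = Σ_i ω_i(x,y) · Φ_i(x,y,m),   ω_i = Ĉ_i / Σ_n Ĉ_n,
C_i(x,y) = ‖Φ_i(x,y,1:M)‖₁,   Ĉ_i = (2r+1)⁻² Σ_{|a|,|b| ≤ r} C_i(x+a, y+b)
```

(r = 2, zero padding, fixed divisor), applies spatial-channel attention to
the two deep modality features and the fused feature, and classifies the
concatenated 30x30x384 block through two fully connected layers and a
softmax. Training minimizes the slice-level cross-entropy
`L = −(1/N) Σ_i Σ_l y_il log p_il` with Adam; per-patient predictions
average the probabilities of all tumor-bearing slices. Evaluation is
patient-level, stratified 5-fold cross-validation with macro one-vs-rest
PPV/SEN/SPE/F1/AUC, Youden-J ROC cutoffs, categorical NRI, and Grad-CAM
explanation maps. Every layer — including the fusion weights — carries a
hand-derived analytic backward pass (verified against finite differences);
convolutions run as im2col + GEMM in compiled code.

Because clinical cohorts of this kind are not shareable, the package ships a
seeded phantom generator (`phantom_spec()`, `generate_cohort()`) producing
co-registered two-modality slice stacks with three separable lesion
phenotypes (ring-enhancing, nodule-with-broad-edema, homogeneous mass), so
the complete pipeline is exercisable end to end without any data. See the
methods vignette (`vignettes/mffcnet-methods.Rmd`) for the model, its
assumptions, and what phantom results do and do not show.

## Worked example

```r
library(mffcnet)

spec   <- phantom_spec(patients_per_class = 30, seed = 20240901)
cohort <- preprocess_cohort(generate_cohort(spec), target_size = 240)

folds  <- make_folds(cohort, k = 5, seed = 11)
ids    <- vapply(cohort, `[[`, "", "patient_id")
fit    <- mffc_net(cohort[folds[ids] != 0],
                   model_config(input_size = 64, stem_channels = 4,
                                growth_rate = 4, trans_channels = c(8, 12, 16),
                                fc_hidden = 32, seed = 101),
                   train_config(epochs = 8, learning_rate = 1e-3,
                                batch_size = 16, seed = 202))

preds  <- predict(fit, cohort[folds[ids] == 0])   # held-out fold
confusion_and_metrics(preds)
```

```
Confusion matrix (rows = true, cols = predicted):
       predicted
true    GBM SBM PCNSL
  GBM     6   0     0
  SBM     0   6     0
  PCNSL   1   0     5

ACC 0.944 | PPV 0.952 | SEN 0.944 | SPE 0.972 | F1 0.944 | AUC 1.000   (n = 18 patients, macro one-vs-rest)
```

The model recovers 17 of the 18 held-out phantom patients; training loss
falls from 0.86 to 0.005 over 8 epochs (`plot(fit)` shows the curve). This
uses the reduced-width study configuration (64-pixel inputs); the default
`model_config()` is the full 240-pixel/128-channel geometry. A Grad-CAM map
for one slice:

```r
p   <- cohort[folds[ids] == 0][[1]]
sl  <- p$slices[[1]]
cam <- grad_cam(fit, sl$t1ce, sl$flair, target_class = p$label)
image(cam)   # 240x240 map in [0, 1], hot where the class evidence lives
```

A YAML-configured end-to-end run (generate → preprocess → train → evaluate →
Grad-CAM) is available as `run_pipeline("config.yaml", "out/")` or through
the CLI at `inst/cli/mffc.R` (subcommands `generate`, `preprocess`, `train`,
`evaluate`, `gradcam`, `run-all`).

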