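---
title: "Multi-modal MRI feature fusion for three-class brain-tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal MRI feature fusion for three-class brain-tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Glioblastoma (GBM), solitary brain metastasis (SBM) and primary CNS lymphoma
(PCNSL) are malignant brain tumors that can look deceptively similar on a
single MRI sequence yet demand very different treatment. Radiologists lean on
the complementary appearance of the lesion across sequences: contrast-enhanced
T1-weighted imaging (CE-T1WI) shows the enhancement pattern (ring-like with
central necrosis in GBM, a compact nodule in SBM, fairly homogeneous in
PCNSL), while T2-Flair shows the surrounding edema, typically broad around a
metastasis and more restrained around lymphoma.

`mffcnet` implements a convolutional classifier built around exactly this
idea: two parallel encoders extract features from co-registered CE-T1WI and
T2-Flair slices, an explicit *activity-level fusion layer* blends the two
feature streams pixel by pixel, a spatial-channel attention block reweights
the result, and a softmax decoder produces per-slice class probabilities that
are averaged into a per-patient prediction.

## The model

**Encoders.** Each modality passes through a 3x3 stem convolution and three
DenseBlocks in series. A DenseBlock layer applies per-feature-map
normalization, ReLU and a 3x3 convolution producing `growth_rate` channels;
its input is the channel concatenation of the block input and every previous
layer's output, so a block maps `C` channels to `C + L * growth_rate` (the
default has `L = 5` layers). A 1x1 transition convolution then sets the
channel width and 2x2 average pooling halves the resolution. With 240x240
inputs and transition widths 32/64/128 the deep features are 30x30x128.

**L1-norm activity fusion.** For each scale `n` the fused feature is the
pixelwise convex combination

    f(x, y, m) = sum_i w_i(x, y) * phi_i(x, y, m)

where the weight of modality `i` derives from its *activity level*: the L1
norm of the channel vector at that pixel, box-averaged over a window of
half-width `r` (default `r = 2`), and normalized across modalities. Where a
pixel's total activity falls below `eps = 1e-8`, the weights fall back to the
uniform `1/K`. The box average uses zero padding with the fixed divisor
`(2r + 1)^2`; we follow that form literally, so border activities shrink
toward zero rather than being renormalized by the partial window — the
weight *ratio* between modalities at a border pixel is unaffected because
both modalities shrink by the same factor. Shallower scales are projected to
the deep width by a learned 1x1 convolution, fused, bilinearly resized to the
deep grid, and averaged across scales (`fusion_combine = "last"` keeps only
the deepest scale instead; averaging is the default because it lets all three
scales contribute as the multi-scale design intends, while preserving the
30x30x128 fused geometry).

**Attention.** The two deep modality features and the fused feature each pass
through a channel gate (a sigmoid MLP over the spatially averaged channel
descriptor) followed by a spatial gate (a sigmoid over a 3x3 convolution of
the channel-mean and channel-max maps). Both gates multiply the input, so
they can only damp activations; a gate saturated at 1 is the identity. The
precise attention form is a design choice — the architecture names
"spatial-channel self-attention" without fixing equations — and the module
can be disabled (`attention = FALSE`) for ablations.

**Decoder and loss.** The three gated 30x30x128 branches are concatenated
(384 channels), flattened, and passed through two fully connected layers
(hidden width 256 by default) into a 3-way softmax. Training minimizes the
mean cross-entropy over slices,

    L = -(1/N) sum_i sum_l y_il log p_il ,

with probabilities clamped at 1e-12 inside the log. Per-patient predictions
average the probabilities of all tumor-bearing slices ("slices containing
the tumor" are identified by a non-empty lesion mask; tumor-free slices are
excluded from training and aggregation).

**Optimization.** Adam with the reference protocol of learning rate 1e-4,
weight decay 1e-5 (added to the gradient, as in the common coupled
implementations) and 100 epochs under stratified 5-fold patient-level
cross-validation. Small phantom studies in this package use a shorter
protocol (8 epochs at 1e-3, batch 16) because the synthetic task converges in
a handful of epochs.

## Everything is differentiated by hand

No deep-learning framework is used: convolutions (im2col + GEMM, in compiled
code), normalization, pooling, the attention gates, the fusion layer — whose
gradient flows through both the convex combination and the activity-derived
weights, including the absolute values and the box filter (which is its own
adjoint) — and the decoder all carry analytic backward passes. The test
suite verifies the complete gradient against central finite differences on a
small model (relative error below 1e-4 across every parameter group) and the
fusion layer against an independent nested-loop implementation.

## Normalization choice

The reference design places a normalization layer before each ReLU +
convolution. Here normalization standardizes each feature map over its
spatial extent (per sample, per channel) rather than across a minibatch.
This keeps train-time and eval-time behaviour identical without running
statistics, and makes every forward pass a pure function of the inputs and
parameters — which in turn makes fixed-seed runs bit-reproducible regardless
of batch composition, a property the package tests assert end to end.

## Preprocessing chain

`resample_to_reference()` brings CE-T1WI onto the T2-Flair grid (trilinear in
world coordinates from spacing/origin/direction; nearest-neighbour for label
volumes). Deformable registration is assumed done upstream by dedicated
tools and is out of scope. `intensity_window()` clips voxels to the volume
mean +/- 3 population standard deviations (computed per volume, over the
whole stack). `crop_to_brain_square()` takes the smallest square containing
the brain mask's bounding box, centred on it, clamped to the image and
zero-padded where the square overhangs. `rescale_and_normalize()` resizes to
240x240 (bilinear, half-pixel-centre convention) and maps intensities
affinely to [0, 255]; a constant slice maps to zeros. Brain masks are an
input: the phantom generator supplies them, and for real data any
skull-stripping output serves.

## The phantom generator

`phantom_spec()` / `generate_cohort()` produce seeded, co-registered
two-modality slice stacks with three lesion phenotypes that caricature the
clinical appearances: a GBM-like ring (bright rim 0.9, core 0.5 against a
0.35 brain background on modality 1, moderate edema on modality 2), an
SBM-like compact nodule with broad modality-2 edema (2.6-3.4x the nodule
radius), and a PCNSL-like homogeneous mass with narrow edema. Geometry and
intensities jitter per patient; per-slice radii shrink away from the lesion
centre as a slice through a roughly ellipsoidal mass would. Defaults: native
128x128 pixels (so the 240x240 rescale path is genuinely exercised),
additive Gaussian noise with sd 0.05 on the 0-1 intensity scale (a clearly
visible but non-trivial noise floor), 3-6 tumor slices plus 1-2 tumor-free
slices per patient (the latter exercise the mask-filtering rule), and 30
patients per class for the main study.

The phantom is intentionally *not* a physical MR simulation: no k-space, no
bias fields, no partial-volume effects, no registration error, and its class
geometry is far cleaner than real tumors. Passing the end-to-end test
therefore shows that the architecture, fusion, training loop and evaluation
machinery work and that the model can exploit cross-modality spatial
structure — it says nothing about clinical performance. The ring vs.
homogeneous-mass distinction is deliberately invisible to mean lesion
intensity alone, so the classifier must use spatial features.

## Study sizes and numerical choices

The packaged experiments run on one CPU, so they use the reduced-width model
(64-pixel inputs, stem 4, growth 4, transitions 8/12/16, hidden 32) — the
identical architecture at smaller width, which the package treats as its
small-scale study configuration; the default 240-pixel/128-channel geometry
is exercised by a forward-pass geometry test. The main phantom study trains
on four of five stratified folds (72 patients, ~320 slices) for 8 epochs and
evaluates the 18 held-out patients. Numerical details: He-normal seeded
initialization; probabilities clamped at 1e-12; fusion fallback eps 1e-8;
normalization variance floor 1e-5; ROC cutoffs maximize Youden's J with ties
broken toward higher specificity (an uninformative score vector yields the
degenerate all-negative threshold, specificity 1); macro one-vs-rest
averaging for PPV/SEN/SPE/F1/AUC with trapezoid AUC; NRI is the categorical
form on predicted labels (the net proportion reclassified correctly versus a
reference classifier) — the risk-threshold variant needs calibrated
probability strata the task does not define.

## Known limitations

* The phantom's simplicity means test accuracies are not evidence of
  clinical accuracy; the reference clinical figures were obtained on a
  private 1225-patient cohort that is not available.
* Grad-CAM explanations are only partially reliable for this decoder. The
  architecture flattens the deep features into fully connected layers, so
  each spatial cell carries independent class weights and nothing constrains
  class evidence to be *positively* encoded in the feature activations — the
  assumption behind Grad-CAM's ReLU of the gradient-weighted channel sum.
  On trained phantom models the signed (pre-ReLU) map pinpoints the lesion
  for every class, but for classes whose evidence a given fit happens to
  encode with negative sign (typically the ring-enhancing class) the ReLU
  zeroes the informative region and the map degenerates; which class is
  affected varies with capacity and initialization. In our small-scale
  phantom study the mean in-lesion activation exceeds the out-of-lesion mean
  on roughly 70% of held-out tumor slices rather than all of them.
  Architectures that end in global average pooling do not have this failure
  mode; with the fully connected decoder specified here it is intrinsic.
* Patient-level aggregation is a plain mean over tumor slices; no weighting
  by lesion area or slice position.
* The attention block and the inter-block channel widths are design choices
  where the architecture description is silent; both are configurable.
* Single-threaded determinism is asserted; multi-threaded BLAS may reorder
  floating-point reductions in ways this package does not control.
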