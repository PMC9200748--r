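---
title: "Label-free Cell Painting: models, synthetic conditions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free Cell Painting: models, synthetic conditions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell Painting images eight cellular components with six dyes across five
fluorescent channels (DNA, ER, RNA, AGP, Mito). The assay is informative but
consumes every available imaging channel. brightpaint implements the
label-free alternative: predict all five fluorescent channels from a
three-plane transmitted-light (brightfield) z-stack — in focus, 4 µm above
and 4 µm below — so the physical channels can be freed for other stains.
The package covers the full workflow: image-to-image models and their two
training regimes, tiled inference, image-level evaluation, morphological
profiling of the predicted images, and a downstream toxicity call, all
runnable end-to-end on a built-in synthetic data generator.

## Models and objectives

The generator is a U-Net with six resolution levels. Each block applies two
kernel-3, stride-1, pad-1 convolutions, each followed by ReLU and then batch
normalization; 2×2 max pooling halves resolution between blocks on the way
down, and kernel-2 stride-2 transposed convolutions mirror it on the way up,
with skip concatenations joining corresponding levels. Filters double per
level from 32 to 1024, and the final layer is a single 1×1 convolution with
no activation or normalization. With these defaults the network has
31,106,661 trainable parameters; the published architecture is summarised
only loosely in prose, and the two-convolutions-per-block reading is the one
that lands on the printed ~31 million total, so it is pinned by test. "Same"
padding is forced by the requirement that input and output share spatial
size (the original valid-padding U-Net would not).

Two regimes train this generator:

* **L1 phase.** Minimize the mean absolute error between predicted and real
  fluorescent stacks over random aligned 256×256 crops; Adam with learning
  rate 2e-4 and weight decay 2e-4, batch 10, 50 epochs at full scale
  (15,000 iterations for 3,000 training wells).
* **cWGAN-GP phase.** Continue the trained U-Net as the generator of a
  conditional Wasserstein GAN. The critic is a patch discriminator over the
  concatenated 8-channel (brightfield + fluorescent) stack: three kernel-4
  stride-2 convolutions ending at 64 filters, LeakyReLU(0.2), then a 1×1
  projection to a spatial score map whose mean is the critic score. The
  critic minimizes `-(E[D(x,y)] - E[D(x,G(x))]) + λ₂·GP` with λ₂ = 10 and
  the standard squared gradient penalty `E[(‖∇_x̂ D(x,x̂)‖₂ − 1)²]` at uniform
  interpolates between real and generated stacks; the generator minimizes
  `λ₁·L1 − λ_e·E[D(x,G(x))]` with λ₁ = 100 and the adaptive weight
  λ_e = 1/epoch (1-based — epoch one carries weight one). Five critic
  updates run per generator update; batch 4; Adam(lr 2e-4, β₁ = 0,
  β₂ = 0.9) for both players, critic weight decay 1e-3.

Two formulation details are deliberate corrections of apparent typos in how
this construction is sometimes written: the gradient penalty is squared (the
unsquared form would reward gradients smaller than 1), and the critic
*minimizes* the negated score gap plus the penalty (a critic that maximized
an objective containing `+λ₂·GP` would be rewarded for violating the
Lipschitz constraint). Both choices are the standard WGAN-GP forms and are
pinned by tests.

### Differentiation details

No deep-learning framework is involved: convolution, pooling, transposed
convolution, batch norm and their reverse-mode gradients are implemented in
the package (R orchestration over Rcpp/Armadillo kernels), and every layer's
backward pass is verified against central finite differences in the test
suite. The gradient penalty needs a second-order term — the derivative of
the critic's input-gradient norm with respect to the critic weights. This is
computed as a central finite difference of the weight gradient along each
sample's (unit) input-gradient direction, which for the piecewise-linear
LeakyReLU critic is exact wherever no activation changes sign; the exported
`gradient_penalty()` value itself uses exact reverse-mode gradients. Batch
normalization uses batch statistics (momentum 0.1 running averages for
evaluation), expectations are realized as mini-batch means, and one
interpolate per sample is drawn for the penalty.

## Tiled inference

Full fields are predicted in 256×256 patches on a stride-128 grid; when the
grid does not land on the far edge (998 is not reachable from a stride-128
grid, since 998 − 256 = 742 is not a multiple of 128) a final origin is
clamped to the edge. Every pixel of the reconstruction is the *median* of
the predictions covering it — four in the interior at half-patch stride,
fewer near edges; even counts use the mean of the two middle order
statistics. Stitching patches cut from a single image reproduces it exactly,
which the tests assert bit-for-bit at 256, 512 and 998 px. No seam-aware
blending is applied; residual seams are an accepted property of the method.

## Image-level evaluation

Five paired metrics per channel: MAE, MSE, PCC over flattened pixels, PSNR,
and SSIM, with cross-channel means and mean ± SD aggregation over test
fields. Two conventions the sources leave open are fixed here and flagged:

* **PSNR 8-bit conversion.** Both images are mapped by a *single* affine
  transform from the min/max of their union onto [0, 255] (no quantization),
  making PSNR symmetric and preserving relative error;
  `PSNR = 10·log10(255²/MSE)` with an `Inf` sentinel for identical images.
* **SSIM.** 7×7 uniform windows over all fully interior positions, unbiased
  local (co)variances, stabilizers C1 = (0.01·L)², C2 = (0.03·L)² with L the
  dynamic range of the pair. This matches the scikit-image reference
  implementation to 1e-6, which the suite checks directly.

Metrics are computed on z-normalized images (the model's I/O domain) by
default; raw-intensity evaluation is a caller choice, since normalization is
invertible per image.

## Synthetic study conditions

The real assay data behind this method is proprietary, so the package ships
a generator of paired fields with a *known* brightfield–fluorescence
relationship. What it emulates, and what it deliberately does not:

* Cells are elliptical nuclei (5–8 px semi-axes at 256 px scale) inside
  larger cytoplasm blobs, placed with nucleus-overlap rejection so cell
  counts are exact. DNA is the nucleus mask; ER a cytoplasm texture; RNA a
  dim cytoplasm plus 1–3 bright nucleolar spots per nucleus; AGP a membrane
  rim plus ~1 px filaments; Mito granular 1–2 px puncta.
* The three brightfield planes are linear mixtures of the five channels,
  blurred with plane-specific defocus widths (σ = 3, 1, 2 px for z−4, focus,
  z+4) plus additive Gaussian noise (default SD 0.02 in scene units where
  structures span ≈ 0–1). The mixture makes the coarse structure linearly
  recoverable — a pooled per-pixel regression from the three planes to DNA
  achieves PCC > 0.5, a tested invariant that guarantees training smoke
  tests are meaningful — while the fine AGP/Mito detail is destroyed by the
  blur, reproducing as an *ordering* the finding that those two channels
  predict worst. It does not simulate optical physics, spectral
  bleed-through or stain chemistry, so passing tests say nothing about
  absolute performance on real microscopes.
* Batches differ by a multiplicative fluorescent intensity factor (default
  spread ±30%, a free parameter since no published magnitude exists);
  per-image standardization in preprocessing removes it, which is the point
  of that normalization. Positive-control scenes enlarge cells by
  `1 + 0.4·effect` and thin mitochondrial puncta by `1/(1 + effect)` —
  an enlarged-area, mitochondria-suppressed cytotoxic phenotype whose
  separability grows monotonically with the effect size.
* Raw files are 16-bit single-channel TIFFs scaled to use ≈ [0, 20000] of
  the range, mimicking real microscopy headroom; signed predictions travel
  as float TIFFs in [0, 1] with the per-channel affine recorded in a JSON
  sidecar (round-trip error below 1e-6).

Desk-scale problem sizes are used throughout the tests and the acceptance
script: ~120–200 fields of 128×128 px with a reduced generator (4 levels,
base 16), which reaches mean held-out PCC ≥ 0.8 in a few epochs; the full
six-level network is built and counted but not trained at that size.
Validation uses a random 90/10 split of the training fields.

## Profiling and toxicity

A lightweight stand-in extractor produces CellProfiler-style per-cell
features (intensity, texture, granularity, radial distribution,
area/shape, neighbors) per compartment × channel, named
`Compartment_FeatureType_Channel_Detail`; real feature tables with that
naming drop in anywhere. Predicted images are measured under the
ground-truth segmentation masks — per-source re-segmentation is outside the
method. Profiles are per-well medians (missing values excluded).

Feature selection applies four rules in order, computed on the ground-truth
source only so predicted values can never shape the survivor set: drop
features with >5% missing *or* >5% exact zeros (the zeros reading of an
ambiguous published phrasing; both thresholds configurable); drop
blocklisted names; drop one member of every pair correlating above 0.9
(absolute Pearson), scanning in decreasing-variance order so the more
informative member survives; drop features whose SD over DMSO
(negative-control) wells exceeds 15 on the raw scale — a scale-dependent
threshold, so it is exposed in configuration, and global rather than
per-plate DMSO statistics are used. Selection is idempotent and blind to
predictions, both tested. The published survivor count on the original data
(611) is dataset-dependent and is not a target here.

Predicted-vs-truth agreement is the per-feature Spearman correlation across
wells (midranks for ties; zero-variance features reported missing and
excluded), averaged within (compartment, channel, feature-type) groups.
Embeddings use UMAP with n_neighbors = 15, min_dist = 0.8, n_components = 2
— implemented compactly in-package (fuzzy k-NN graph, negative-sampling
layout, seeded PCA initialization) because no UMAP implementation exists in
the package's R dependency environment — with PCA as the confirmatory
alternative.

Toxicity calling z-normalizes profiles, then runs a k = 5 Euclidean K-NN
100 times, each run drawing with replacement an equal number of training
profiles from both control classes — the *larger* class count, left
unspecified in the published description — and takes the majority vote.
Control wells are scored leave-self-out (their own resampled copies are
excluded from their neighbor sets), without which control specificity would
be trivially inflated; a tied vote is called non-toxic, the
specificity-preserving default. Truth for sensitivity/specificity can be
either known labels (the synthetic generator records them) or ground-truth
K-NN calls, since the published evaluation is ambiguous between the two.

## Known limitations

* The synthetic mapping is far easier than real brightfield-to-fluorescence
  transfer; desk-scale PCCs (~0.9) say nothing about attainable values on
  real data, where the published full-scale mean is 0.84.
* The in-package UMAP is a compact reimplementation tuned for the qualitative
  properties the pipeline needs (cluster preservation, duplicate
  coincidence), not a numerical match to the reference package.
* The cWGAN-GP phase at desk scale is exercised for correctness (update
  ratio, finite losses, no fidelity collapse) rather than for the small
  metric gains reported at full scale, which require tens of GPU-hours.
* Early stopping is by best mean validation PCC (the headline image metric);
  the governing metric and patience are configuration, as no published
  choice exists.
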