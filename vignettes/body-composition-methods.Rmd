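---
title: "Methods: segmentation, quantification, and sarcopenia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, quantification, and sarcopenia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`bodycomp` implements an automated body-composition pipeline for abdominal
CT: encoder–decoder neural networks segment each axial slice into
subcutaneous fat, visceral fat, and skeletal muscle; per-slice areas are
integrated into compartment volumes; and the skeletal muscle index (SMI) at
the third lumbar vertebra (L3) drives a sarcopenia screen with ROC-based
cutoff optimization. A geometric phantom generator provides fully labelled
synthetic CT with known analytic areas, so every stage can be validated
end to end without patient data.

This vignette records the mathematical model, the numerical choices, and
the phantom's realism and limits.

# Segmentation networks

Three encoder–decoder variants are provided through
`network_config(variant = ...)`:

* **`"unet"`** — a U-Net. Each encoder stage applies two 3×3
  convolution + ReLU layers and then 2×2 max pooling with stride 2,
  doubling the channel count per stage. The decoder mirrors this with
  2×2 up-convolutions (transposed convolutions on non-overlapping 2×2
  blocks) and concatenates the same-resolution encoder feature map (skip
  connection) before two further 3×3 convolutions. A final 1×1
  convolution maps to three logit channels.
* **`"attention_unet"`** — the same backbone with additive attention
  gates on the skip connections: 1×1 convolutions project the skip
  features and the gating (decoder) signal to a common intermediate
  width, their sum passes through ReLU, a 1×1 convolution and a sigmoid
  produce a spatial attention map, and the skip features are multiplied
  by that map before concatenation.
* **`"segnet"`** — a SegNet-style network: max-pooling *indices* from the
  encoder drive sparse unpooling in the decoder (no concatenation), and
  each convolution is followed by a per-image feature normalization with
  learned scale and shift. We use per-image (instance-style)
  normalization rather than batch statistics so that inference is
  deterministic for a single slice and independent of batch composition;
  with the small batch sizes practical on CPU, batch statistics would be
  noisy anyway.

Default geometry is `depth = 4` pooling stages and `base_channels = 16`,
giving a U-Net with about 1.9 million parameters. Inputs must be square
with side divisible by `2^depth`. Hounsfield units are clipped to
[−200, 300] — a window that brackets fat (≈ −100 HU) and muscle
(≈ +40 HU) — and rescaled to [0, 1] before entering the network.

All convolution, pooling, unpooling, and transposed-convolution primitives
are implemented in compiled code (RcppArmadillo, im2col formulation), and
gradients flow through a small reverse-mode tape written in R. Every
operation's analytic gradient is checked against central finite
differences in the test suite.

# Loss

Training minimizes a combined per-channel loss summed over the batch and
the three tissue channels:

$$L = \sum_{n} \sum_{k} \left( \ell_{\mathrm{BCE}}(y_{nk}, p_{nk})
      + \ell_{\mathrm{DICE}}(y_{nk}, p_{nk}) \right)$$

where $\ell_{\mathrm{BCE}}$ is binary cross-entropy summed over pixels
(probabilities clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-7}$) and the soft Dice loss is

$$\ell_{\mathrm{DICE}} = 1 - \frac{2 \sum_i y_i p_i}{\sum_i y_i + \sum_i p_i}.$$

When both the target and the prediction are identically zero the Dice
ratio is 0/0; we define the loss as 0 in that case (an empty channel
predicted empty is a perfect answer). We deliberately do not add a
smoothing constant to numerator and denominator, so that the loss value
for a perfect match is exactly 0 and small worked examples evaluate to
closed-form numbers.

Gradients are taken with respect to the logits:
$\partial \ell_{\mathrm{BCE}} / \partial x_i = p_i - y_i$, and the Dice
term differentiates through the quotient rule multiplied by the sigmoid
derivative $p_i(1-p_i)$.

# Training

`train_model()` runs mini-batch Adam (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁸) with defaults of learning rate 10⁻³, batch size 4, and 100
epochs. When a validation set is supplied, the parameters with the lowest
validation loss over the run are kept (best-checkpoint selection) and
per-epoch validation Dice coefficients for the three tissues are recorded
in the fit history. `split_dataset()` partitions *patients* — never
individual slices — into train/validation/test groups with an 8:1:1
ratio by largest-remainder apportionment, so no patient contributes to
more than one group.

All randomness (initialization, shuffling) is controlled by explicit
seeds; the same seed reproduces the same fit to floating-point accuracy.

# Quantification

Per-slice areas are pixel counts times the pixel area
(`mask_area()`, reported in cm²). Volumes integrate the per-slice area
profile with the trapezoidal rule over slice spacing
(`stack_volume()`): for adjacent slices with areas $S_1, S_2$ and
spacing $H$ the slab contributes $(S_1 + S_2)H/2$. This is exact for any
linearly varying cross-section (prisms, cones between slices) and
second-order accurate otherwise; the test suite verifies both the exact
cases and the expected error decay.

`abdomen_window()` selects the central abdominal portion of a stack by
trimming `floor(0.1 n)` slices superiorly and `floor(0.3 n)` slices
inferiorly; `l3_window()` extracts the 41-slice window centred on a
designated L3 slice (±20 slices). Agreement against reference areas or
volumes is summarized with `percent_difference()` (relative to the
automatic measurement), Bland–Altman limits of agreement
(mean ± 1.96 · sample SD of automatic − manual), and the Pearson
correlation.

# Sarcopenia screening

SMI is the L3 muscle area divided by height squared (cm²/m²);
`classify_sarcopenia()` flags `smi < cutoff` with sex-specific defaults
of 38.5 (female) and 52.4 (male). `roc_curve()` sweeps every distinct
observed SMI value (plus ±∞ sentinels) as a candidate cutoff, with
"positive" meaning below-cutoff; `auc()` integrates the exact empirical
curve with the trapezoidal rule, which makes it identical to the
normalized Mann–Whitney U statistic. `youden_optimal()` maximizes
J = sensitivity + specificity − 1, breaking ties toward higher
sensitivity and then lower cutoff.

# The phantom generator

`phantom_spec()` describes a simplified axial abdomen:

* an elliptical body outline (default semi-axes 100 × 80 mm);
* a subcutaneous fat annulus of constant thickness just inside the
  outline (default 14 mm, ≈ −100 HU);
* a muscle ring inside that (default 11 mm, ≈ +40 HU);
* disjoint circular visceral-fat blobs placed wholly inside the inner
  cavity (default 3 blobs, radii 9–22 mm, ≈ −90 HU), over soft-tissue
  background (≈ +20 HU);
* additive Gaussian HU noise (default SD 10).

Pixels are labelled by their centre coordinates, so each mask is an exact
rasterization of the geometry, and every compartment has a closed-form
analytic area — e.g. the subcutaneous annulus is
$\pi(ab - a'b')/100$ cm² for outer semi-axes $a, b$ and inner semi-axes
reduced by the thickness. `generate_volume()` scales the whole geometry
slice-by-slice with an axis profile (areas scale with the square of the
factor), yielding stacks whose exact volumes are known through the same
trapezoidal rule. `generate_cohort()` draws heights from
N(1.591 m, 0.059 m) and muscle areas from a normal rescaled so that a
target fraction (default 38.3 %) falls below a planted SMI cutoff;
labels are exact threshold evaluations, which makes the noise-free ROC a
perfect step.

**Realism and limits.** The phantom reproduces the geometric and
attenuation structure that the pipeline actually measures — closed
compartments with correct HU ranges, partial-volume-free labels, smooth
slice-to-slice variation — but it is not anatomically realistic: organs,
bone, lumen gas, and muscle substructure are absent, and compartments are
exactly concentric. Results on phantoms therefore validate the
*machinery* (losses, gradients, integration, ROC logic, I/O round-trips)
and the networks' capacity to learn the task, not clinical performance.

# Problem sizes

The package targets CPU-only execution. Representative sizes used in the
package's own validation: 64 × 64 phantom slices, U-Net depth 4 with 16
base channels (≈ 1.9 M parameters), 200 training slices, 10 epochs —
about ten minutes on one core — reaching held-out Dice ≥ 0.93 for all
three tissues. Smaller configurations (depth 2, 4–8 base channels,
32 × 32 inputs) train in seconds and are used for gradient checks and
overfitting sanity tests. Clinical-resolution inputs (512 × 512) are
supported by the same code paths but are slow without vectorized
hardware; for methodological work the phantom scale is sufficient.

# File formats

Volumes and mask stacks are exchanged as NIfTI (`.nii.gz`) via the
RNifti package, with mask channels stored as a 4D array plus a JSON
sidecar naming the channels. Cohorts are plain CSV. Fitted models are
saved with `save_checkpoint()` (RDS with a format version field).
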