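---
title: "Anatomy-guided PET-CT fusion segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-guided PET-CT fusion segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(anatofuse)
```

## The problem

PET and CT are complementary views of the same anatomy. PET voxels measure
metabolic tracer uptake — tumors are bright, but the image is low-resolution
and blurred, and non-tumor tissue (inflammation, glands, brain) can also be
hot. CT voxels measure tissue density in Hounsfield Units — boundaries are
crisp, but a tumor's density contrast against surrounding soft tissue is
modest. A segmenter that sees only PET has poor boundaries and false
positives; one that sees only CT struggles to tell tumor from other soft
tissue. `anatofuse` implements an intermediate-fusion encoder-decoder that
encodes each modality separately, weights channels with squeeze-and-excite
(SE) attention, fuses the two streams at every depth, and *gates* the fused
features with the excited CT features so that anatomy steers the final
delineation.

## The architecture

All feature maps are `(x, y[, z], channel)` arrays; the model is built in 2D
or 3D from the same code (`ModelConfig@dims`).

**Zero layers.** Each raw modality volume $V$ first passes through a
"zero layer": a convolution with kernel $k$ and $F$ filters, ReLU $\rho$,
and a *learnable* normalization
$$N(P) = \lambda \cdot \frac{P - \mu(P)}{\sqrt{\sigma^2(P) + \epsilon}} + \delta,$$
where $\mu$ and $\sigma^2$ are computed per channel over spatial positions
(instance style) and the scale $\lambda$, shift $\delta$ *and* the
stabilizer $\epsilon$ are trained parameters. $\epsilon$ is stored through a
softplus reparameterization so it remains strictly positive under any
gradient step. Fixed preprocessing cannot adapt to scanner- and
center-specific intensity statistics; the zero layer learns a residual
normalization per modality. Defaults: $F = 16$, $k = 3$,
$\epsilon_0 = 10^{-5}$.

**SE encoders.** Each modality has its own encoder stack over the filter
schedule `encoderFilters` (default `[128, 64, 32, 16]`, applied as listed
with depth; `reverseFilters` gives the conventional increasing ordering).
A stage computes
$Enc = \rho(\mathrm{Conv}_3(x))$, global average pooling
$g = \mathrm{GAP}(Enc)$, an excitation
$Exc = \sigma(W_2\,\rho(W_1 g))$ with bottleneck width
$\max(1, C/r)$ (default $r = 4$), channel-wise modulation
$f = Enc \otimes Exc$, and finally
$\mathrm{Norm}(\mathrm{MaxPool}_2(f))$ with the same learnable
normalization type. Every excitation lies strictly in $(0, 1)$; clamping
all excitations to 1 reduces a stage exactly to its non-SE counterpart
(this identity is tested).

**Anatomy-guided fusion decoder.** At every stage the excited outputs of
the two encoders are fused:
$$m^{pf} = \mathrm{Conv}_{1\times1}(\mathrm{MaxPool}(\mathrm{AvgPool}(m))),
\qquad f_{fused} = \rho(PET^{pf} \oplus CT^{pf}),$$
followed by an optional $1\times1$ convolution (`fusionConv`). The pooling
in this branch uses window 2 / stride 1 with same-padding, so the fused map
keeps the stage's spatial size and the guidance product
$$CT_{guidance} = CT_{excited} \ast f_{fused}$$
is element-wise without any resampling. The per-stage decoder output is
$Dec_{out} = \mathrm{Norm}(\sigma(\mathrm{Conv}_{1\times1}(CT_{guidance})))$.
Setting `guidance = "pet"` swaps the gating modality (the functional- vs
anatomy-awareness comparison in the ablation harness).

Two readings of the fusion activation exist — an additive fusion followed by
ReLU, or by a sigmoid; the package defaults to ReLU and exposes
`fusionActivation = "sigmoid"` as the alternative.

**Decoder path.** Only the per-stage fusion outputs feed the decoder: the
deepest $Dec_{out}$ is repeatedly upsampled (nearest neighbour, factor 2),
projected to the shallower stage's width by a $1\times1$ convolution, added
to that stage's $Dec_{out}$, and refined by a $3^d$ convolution + ReLU.
After the last stage a final upsample restores full resolution, a
$1\times1$ convolution reduces to the zero-layer width (keeping the
full-resolution head light), and a $3^d$ convolution + sigmoid produces the
per-voxel probability map. This "one fusion-guidance-head block per depth,
combined on an upsampling path" design is the package's resolution of a
genuinely open wiring question; it keeps every stated element-wise
operation shape-consistent without inventing resampling inside the fusion
block.

**Baseline comparator.** `buildBaselineUNet()` is a standard encoder-decoder
with a doubling schedule (default base 32) and channel-stacked input — the
early-fusion and single-modality arms of the ablation harness, and the
parameter-count reference. At matched depth the fusion model is much
lighter (~0.7M vs ~5M parameters for the default 4-stage 3D
configurations), because its decreasing filter schedule and $1\times1$
fusion branches avoid wide deep stages.

## Preprocessing and augmentation

- CT: clip to $[-1024, 1024]$ HU, divide by 1024 — an exact linear map onto
  $[-1, 1]$.
- PET: per-volume z-score over all voxels of the stored volume (population
  standard deviation); a constant volume is a degenerate-input error. The
  statistics are deliberately not restricted to a body mask — the simplest
  defensible reading of per-volume normalization.
- Augmentation: horizontal flip, vertical flip (probability 1/2 each) and
  an axial rotation, drawn per training step from a seeded stream and
  applied identically to PET, CT and mask. Rotations default to
  quarter-turns, which are exact on the voxel grid and keep masks binary
  without interpolation; a small-angle mode (uniform in ±15°, bilinear for
  images, nearest-neighbour for masks) exists for completeness.

## Training

Adam with initial learning rate 0.005 and batch size 1; the learning rate
is multiplied by 0.1 (floor $10^{-6}$) whenever the monitored loss has not
improved for 10 consecutive epochs. The monitored quantity is the
validation loss when a validation split exists (by default a seeded 10% of
the training set when it has at least 5 samples), otherwise the epoch
training loss.

**Loss.** The default is BCE + soft Dice
($1 - (2\sum pt + s)/(\sum p + \sum t + s)$, $s = 1$). Pure soft Dice is
available but not the default for an empirical reason found during
development: at batch size 1 with a foreground of 1–2% of voxels, soft Dice
alone reliably collapses to the empty prediction — the background term
dominates early, the sigmoid saturates, and the loss freezes at
$1 - s/(|t| + s)$ with vanishing gradients. The cross-entropy term keeps a
nonzero gradient on saturated foreground voxels; it is computed in logit
space ($t\,\mathrm{softplus}(-z) + (1-t)\,\mathrm{softplus}(z)$, gradient
$\sigma(z) - t$), which stays informative even where the probability
underflows in double precision.

The whole network is differentiated by a small reverse-mode tape built into
the package, with compiled im2col convolution and pooling kernels; every
backward rule is verified against central finite differences in the test
suite, and the full model gradient is finite-difference-checked end to end.

## The phantom generator

Real PET-CT pairs at GPU scale are out of reach for a desk-scale test
suite, so the package generates co-registered phantoms whose *statistical
structure* rewards exactly the mechanisms the model claims to exploit:

- CT: air at $-1000$ HU, an elliptical body of textured soft tissue
  (40 ± 25 HU smooth field), one dense bone-like structure (700 HU), and
  tumors as crisp-edged ellipsoids at +60 HU over soft tissue — visible in
  CT but at modest contrast against the texture.
- PET: body baseline uptake 1, tumor uptake 8, then a Gaussian blur
  (σ = 1.5 voxels) applied to PET only — bright but smeared boundaries.
- Confounders: PET-hot blobs with *no* CT correlate, excluded from the
  mask. A PET-only segmenter therefore has a precision floor by
  construction; only cross-modality evidence separates tumor from
  confounder.
- Noise: additive Gaussian, 20 HU (CT) and 0.2 uptake units (PET).
- Multi-center datasets apply deterministic per-center jitter to the noise
  levels and PET intensity scale (factors cycling through ±40%), mimicking
  the acquisition variation across centers that motivates learnable
  normalization, and tag each sample with its center for
  leave-one-center-out splitting.

Default grids are 64×64 (2D) and 32×32×32 (3D) at 1 mm spacing — sizes a
CPU trains in minutes. The generator is seeded end to end: a spec
reproduces its sample bit-exactly, and a dataset call derives per-sample
seeds deterministically from one master seed.

What the phantoms do *not* emulate: reconstruction physics (attenuation,
scatter, partial-volume beyond the Gaussian blur), anatomical atlases,
SUV calibration, metastases, or inter-patient anatomy variation. Passing
phantom-scale tests demonstrates that the implementation's mechanisms work
and order as designed — not that the architecture reaches any particular
performance on clinical data.

## Metrics and aggregation

- DSC $= 2|x \cap y| / (|x| + |y|)$; the both-empty convention returns a
  flagged 1.
- HD95: boundary voxels are mask voxels with a face-adjacent background
  neighbour (the outside of the grid counts as background); directed
  nearest-boundary Euclidean distances are computed in millimetres via the
  voxel spacing in both directions, pooled, and the 95th percentile taken
  with linear interpolation between order statistics. The bracketed
  percentile notation is ambiguous between this pooled reading and the
  maximum of the two directed percentiles; both are implemented
  (`mode = "max_directed"`), pooled is the default. An empty mask is an
  error, surfaced as `NA` in case reports rather than imputed.
- Precision/recall on voxel counts, with flagged 0 for 0/0.
- Fold aggregation: arithmetic fold average, median across folds, and the
  maximum absolute deviation of any fold from that median (a worst-case
  band, not a standard deviation).

## Evaluation protocols and the ablation harness

`makeSplit()` implements leave-one-center-out (one fold per center, that
center as test set) and a seeded random 80/20 split
(`round(0.2 n)` test samples). `evaluateSplit()` trains a fresh seeded
model per fold and emits per-case CSV rows plus the fold summary.

`runAblation()` trains named variants under an identical protocol:
single-modality and early-fusion baseline UNets, the attentive-fusion
decoder without zero layers and SE, the same plus zero layers, the full
model (equivalently CT-guided), and the PET-guided counterpart. The
harness reports held-out mean DSC/HD95 per variant and seed and asserts
nothing itself. On default phantoms the expected *directional* ordering —
CT-only worst, early fusion better, attentive fusion better still, and
CT-guided at least as good as PET-guided — is checked in the acceptance
suite across three seeds; only the direction is meaningful at this scale.

## Numerical choices and edge cases

- Instance statistics use population variance; a constant channel is
  guarded by the learnable $\epsilon$ (output = $\delta$).
- Mask files are binarized at 0.5 on read to tolerate lossy label
  compression.
- Co-registration validation requires identical shapes and spacings within
  a relative tolerance of $10^{-4}$; mismatches are errors, never silently
  resampled, because resampling would change the evaluation surface.
- Input grids must be divisible by $2^{n_{stages}}$; `padToStages()`
  zero-pads symmetrically (CT with −1000 HU air) rather than having pooling
  silently truncate.
- Pooling in the encoder uses window = stride = 2; the fusion branch uses
  window 2 / stride 1 with edge clamping so shapes are preserved.
- All randomness (weights, shuffling, augmentation, phantoms) flows from
  explicit integer seeds through locally scoped RNG streams that restore
  the caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the desk-scale study conditions:
single-sample overfitting on one 32³ phantom with the default 4-stage 3D
model (≤200 Adam steps, with a staged learning-rate schedule
0.005 → 0.001 → 5·10⁻⁴ → 2·10⁻⁴ because at a constant 0.005 the
boundary voxels of a ~200-voxel tumor can keep oscillating; how many steps
the overfit needs varies with the phantom draw and the initialization);
and the ablation harness on the default 2D
dataset — 3 centers × 20 samples at 64×64 — with a 2-stage configuration
(filters 32/16, zero-layer width 8, baseline UNet base 16) trained for 8
epochs per variant over 3 seeds. These sizes were chosen as the smallest at
which training converges reliably and the ablation directions stabilize.

## Known limitations

- No DICOM ingestion, affine reorientation or resampling; inputs must be
  pre-registered.
- No patch-based inference: volumes are processed whole, so very large
  grids are memory-bound.
- The decoder wiring beyond the per-stage fusion output is this package's
  design (documented above), not an externally fixed reference.
- Phantom-scale results are directional evidence only; clinical-scale
  performance claims require clinical data and GPU-scale training.
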