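---
title: "Adversarial CS-MRI reconstruction: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial CS-MRI reconstruction: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(csmrigan)
```

## The reconstruction problem

Compressed-sensing MRI acquires only a fraction of the k-space samples a
full scan would collect. Retrospective simulation of that process — the
setting this package implements — takes a fully sampled magnitude image
$X_t \in [0,1]^{H \times W}$, transforms it to k-space, discards the
unsampled points, and inverse-transforms:

$$X_u = \left| F^{-1}( M \odot F X_t ) \right|$$

where $F$ is the 2-D discrete Fourier transform, $M$ a binary sampling
mask, and $\odot$ the element-wise product. $X_u$ is the aliased,
blurred zero-filled baseline; the generator $G$ learns the residual
correction $X_t \approx X_u + G_\text{corr}(X_u)$.

**FFT normalization.** The transform is orthonormal ($1/\sqrt{N}$ in each
direction), so Parseval's identity holds exactly and the image-domain and
frequency-domain losses live on the same scale. This makes the printed
loss weights transferable across image sizes. A consequence worth
stating: under this convention the frequency-domain MSE of two *images*
is mathematically identical to their image-domain MSE, so the $\beta$
term duplicates the $\alpha$ term up to scale. The term is kept as a
separately computed, separately weighted objective — the identity is
asserted in the test suite as a property, and the two terms would
diverge under any non-unitary scaling.

## Sampling masks

Masks are 2-D point-wise variable-density patterns: a centred square
holding ≈4% of all grid points (the high-energy low frequencies that set
tissue contrast) is always fully sampled; remaining points are drawn
*without replacement* with probabilities proportional to an isotropic
Gaussian density centred on DC. Exact-count sampling (via exponential
sort keys) rather than independent Bernoulli thresholding means the
realized rate equals the target exactly, which keeps cardinality
assertions deterministic.

Open parameters the study context does not fix, chosen once:

* **Centre geometry** — a square, the simplest region with exactly
  controllable cardinality (a circle would serve equally; nothing
  downstream depends on the shape).
* **Gaussian width** — `sigma_scale = 0.25` of the grid side. At this
  width the corner-to-centre density ratio is ≈exp(−4), giving strongly
  variable density while leaving high frequencies reachable; the value is
  exposed in every interface.
* **Point-wise (not line-wise) sampling** — maximizes incoherence of the
  aliasing; 1-D Cartesian line masks are a non-goal.

## Phantoms

The synthetic phantoms emulate the image statistics the networks assume
of a T1-weighted brain slice: an elliptical "skull" ring, a darker brain
interior, randomly placed nested tissue ellipses at a few discrete
intensities, a bright compact central structure, optional additive
Gaussian noise, everything clipped to $[0,1]$. Zero-filled undersampled
versions show realistic aliasing/blur, and the degradation is monotone in
the sampling rate — which is what makes them a meaningful reconstruction
benchmark. They do **not** model tissue relaxometry, coil sensitivities,
complex-valued phase, or anatomical variability; a passing test on
phantoms therefore demonstrates that the pipeline learns and measures
de-aliasing, not that a given PSNR would transfer to clinical MPRAGE
data. A NIfTI ingestion path (`load_nifti_slices()`, per-slice min-max
normalization, constant slices mapped to zero) exists for real volumes,
but no test depends on external data.

## Generator

Each encoder level applies (after 2×2 max-pool downsampling, from level 2
on) a channel-lifting 3×3 convolution + batch norm + ReLU, then three
**dilated residual blocks** with dilation rates (1, 2, 3), then a
**channel attention** block. A DR block is
`conv3x3 → BN → ReLU → conv3x3(dilation r, padding r) → BN → +skip → ReLU`;
dilation inserts gaps between kernel taps, so the parameter count is
independent of the rate while the footprint of the (1,2,3) stack grows to
19×19 pixels — both properties are asserted numerically (the receptive
field by a finite-difference footprint oracle with positive weights, so
no path can cancel).

The same rate tuple is used at every level. The alternative reading —
rates varying across levels rather than within a stack — is expressible
through `generator_config(dilation_rates = ...)`, but three rates per
stack is the configuration whose receptive field the architecture
describes, so it is the default. DR blocks live in the encoder only; the
decoder halves mirror the encoder with bilinear upsampling and
skip-connection concatenation.

**Channel attention.** Global max-pool and global average-pool
descriptors each pass through a shared two-layer bottleneck (hidden width
`channels / 8`), are summed per channel, and squashed by a logistic to
weights in (0, 1). The bottleneck weights are shared across channels and
across the two pooling branches — the minimal design that "combines" the
two statistics while being permutation-equivariant, so channels with
identical content provably receive identical weights (a property the test
suite checks to 1e-6). Its first layer is initialized positive because
the pooled descriptors of post-ReLU features are nonnegative; this keeps
every bottleneck unit active at initialization rather than leaving
dead-ReLU branches to chance.

**Multi-scale fusion.** Decoder features from every resolution are
projected to a common width by 1×1 convolutions, bilinearly upsampled to
full resolution (projection before upsampling — the two linear maps
commute exactly, and the projected tensors are smaller), summed, and
fused by one 3×3 convolution.

**Global residual.** The 1×1 output head is zero-initialized and its
output added to the input, so the untrained generator is exactly the
identity. This is an extension beyond the minimal architecture: it
anchors tiny-scale training (the model starts at the zero-filled
baseline and can only improve on it) and gives the test suite an exact
identity property. It can be disabled (`use_residual = FALSE`).

Unprinted sizes default to conventional U-net values — depth 4, 32 base
channels doubling per level — and everything is configurable, so no test
depends on them. Normalization is batch norm and the activation ReLU
throughout the generator; inference mode uses the running statistics
accumulated during training.

## Discriminator

Stride-2 3×3 convolutions perform all downsampling — the layer graph
contains no pooling operator, which the suite asserts structurally —
each followed by batch normalization and LeakyReLU (slope 0.2), then
global average pooling, an affine map, and a logistic output. The first
layer omits batch normalization, the usual convention for this family;
this is the one deliberate deviation from "normalization after every
convolution". Four layers reach a global receptive field at 64×64.

## Losses and training

$$L_\text{combine} = \alpha L_\text{iMSE} + \beta L_\text{fMSE} + \delta L_\text{VGG} + L_\text{GEN}, \qquad \alpha = 15,\ \beta = 0.1,\ \delta = 0.0025$$

The $\tfrac12\lVert\cdot\rVert^2$ terms are implemented as ½ × *mean*
squared error, not sum, so magnitudes are resolution-independent and the
printed weights remain meaningful at any image size. Probabilities are
clamped to $[10^{-7}, 1-10^{-7}]$ before logarithms.

The perceptual term is computed by an injectable feature extractor. The
default is a fixed, seeded, randomly initialized two-layer convolutional
stack: deterministic, dependency-free, and sensitive to local texture,
which is the role the term plays at phantom scale. Pretrained VGG16
features can be supplied through the same interface when reproducing
full-scale perceptual behaviour; random convolutional features are a
standing-in feature space, not an approximation of VGG's.

Training alternates one discriminator update and one generator update per
batch (the "one or more epochs" of discriminator training is exposed as
`disc_steps`). Fresh Monte-Carlo masks are drawn for every training
sample in every batch — the model sees maximal sampling incoherence —
while validation and test masks are fixed per image by a seeded hash so
metrics are reproducible run to run. Augmentation (flip, ±10% integer
translation with zero padding, mirror, 90° rotation, each with
probability ¼) is applied online per sample and never materialized. Both
optimizers are Adam (β₁ = 0.9, β₂ = 0.999) on the shared schedule
`lr = 1e-4 × 0.5^floor(epoch/10)`; early stopping keeps the best
validation-MSE checkpoint and halts after 20 non-improving epochs. A
non-finite loss aborts with the offending term values in the error.

## Numerical choices and degenerate inputs

* Bilinear resampling uses the align-corners convention; it is exact on
  constants and linear ramps (asserted), and its adjoint is used in the
  backward pass.
* Max-pool ties break toward the first candidate in column-major order;
  pooling requires even spatial sizes and the generator refuses inputs
  not divisible by $2^{\text{depth}-1}$ with an explicit error.
* SSIM uses the standard 11×11 Gaussian window (σ = 1.5), K₁ = 0.01,
  K₂ = 0.03, data range 1, averaged over the fully overlapping region;
  PSNR of an exact reconstruction is reported as a capped 100 dB flag so
  reports stay serializable.
* Constant NIfTI slices min-max-normalize to zero rather than NaN.
* Masks with `target_rate` below what the forced centre requires are
  rejected rather than silently shrinking the centre.

## Problem sizes used by the tests

The test suite runs entirely on phantoms at sizes chosen as the smallest
that still exercise each property: 8–32 px images for gradient checks and
smoke tests, 64×64 for the end-to-end experiment. That experiment trains
depth-2 / 8-channel networks with batch 8 for 300 alternating steps on
320 phantoms at 20% sampling — 320 images keeps the per-epoch decay
schedule in its first two steps over those 300 updates, matching how the
schedule behaves in full-size training — and asserts a ≥ 1 dB held-out
PSNR gain over the zero-filled baseline (the measured gain is ≈ 2 dB).
Mask-density and augmentation frequencies are checked over 10 000
Monte-Carlo draws.

## Known limitations

* Single-channel magnitude images only: no complex-valued or two-channel
  real/imaginary variant, no multi-coil or non-Cartesian trajectories.
* 2-D slices only; no 3-D convolutions.
* The default perceptual extractor is not VGG16; absolute values of the
  $\delta$ term differ from a pretrained-VGG setup even though its role
  in the objective is the same.
* Phantom experiments quantify de-aliasing ability, not clinical image
  quality; full-scale PSNR/SSIM on real MPRAGE data requires GPU-scale
  training outside this package's test budget.
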