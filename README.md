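# csmrigan

Compressed-sensing MRI (CS-MRI) reconstruction with an adversarially
trained dilated-residual, channel-attention U-net — implemented end to end
in R, from k-space undersampling simulation to image-quality evaluation,
and exercisable entirely on synthetic brain-like phantoms.

## The problem

MRI acquisition time scales with the number of k-space (spatial-frequency)
samples. Compressed sensing accelerates scans by sampling k-space below the
Nyquist rate and reconstructing the image from incomplete data. Simply
zero-filling the missing samples and inverse-transforming produces an
aliased, blurred image; the reconstruction task is to recover the
fully-sampled image from that degraded input. This package implements a
GAN-based reconstruction model for that task, together with the full
surrounding pipeline a reconstruction study needs:

* **Acquisition simulation** — unitary 2-D FFT, variable-density
  Monte-Carlo undersampling masks (Gaussian density over k-space, the
  central 4% of samples always retained), zero-filled baselines.
* **Synthetic data** — brain-like 2-D phantoms (piecewise-smooth tissue
  regions, sharp edges, bright central structure), four-way stochastic
  augmentation, 70/10/20 dataset splits.
* **Generator** — a U-net whose encoder levels stack three *dilated
  residual (DR) blocks* with dilation rates 1, 2, 3 (expanding the
  receptive field to 19×19 per stack without adding parameters), a
  *channel attention mechanism (CAM)* combining global max and average
  pooling, skip connections, and *multi-scale information fusion* with
  bilinear upsampling. A zero-initialized output head plus a global
  residual connection make the untrained network the identity map.
* **Discriminator** — stride-2 convolutions (no max pooling), batch
  normalization, LeakyReLU, logistic output.
* **Losses** — the weighted combination

  L_combine = α·L_iMSE + β·L_fMSE + δ·L_VGG + L_GEN,  α = 15, β = 0.1, δ = 0.0025

  of image-domain MSE, frequency-domain MSE, a perceptual feature loss,
  and the adversarial term −log D(G(x_u)), plus the discriminator's binary
  cross entropy.
* **Training** — alternating per-batch updates with Adam (β₁ = 0.9,
  β₂ = 0.999), initial learning rate 1e-4 halved every 10 epochs,
  patience-20 early stopping on validation MSE, fresh random masks per
  training sample, fixed per-image validation masks.
* **Evaluation** — PSNR, SSIM (11×11 Gaussian window, σ = 1.5), MSE,
  per-pixel error maps, per-rate aggregate reports, and ablation runs
  (full model vs no-dilation / no-CAM / no-fusion).

The convolution engine (forward and reverse-mode) is implemented in the
package itself on top of RcppArmadillo; every gradient path is verified
against central differences in the test suite.

## Worked example

```r
library(csmrigan)

# a 64x64 phantom, a 20% variable-density mask, and the degraded input
xt <- make_phantom(phantom_spec(seed = 3))
mask <- generate_mask(64, 64, target_rate = 0.2, seed = 1)
xu <- zero_fill_recon(xt, mask)

sum(mask$pattern)                     # 819  == round(0.2 * 64 * 64)
round(psnr(xt, xu), 2)                # 16.03 dB  (aliased baseline)
round(ssim(xt, xu), 3)                # 0.533

# train a small model on phantoms and reconstruct
images <- make_phantom_set(320, phantom_spec(size = c(64, 64),
                                             noise_std = 0.01, seed = 100))
fit <- train(images,
             generator_config(depth = 2, base_channels = 8),
             discriminator_config(n_layers = 3, base_channels = 8),
             loss_weights(),
             train_config(batch_size = 8, max_steps = 300, rate = 0.2,
                          seed = 11, patience = 1000, max_epochs = 100))
ev <- evaluate_model(fit$generator, images[fit$split$test], rates = 0.2,
                     seed = 11)
round(ev$psnr_mean, 2)                # 18.45 dB reconstruction
round(ev$zf_psnr_mean, 2)             # 16.32 dB zero-filled baseline
```

The ~2 dB gain over the zero-filled baseline after only 300 alternating
generator/discriminator steps is what the tiny-scale end-to-end test
asserts (at a conservative ≥ 1 dB). Full-scale runs use
`generator_config()` defaults (depth 4, 32 base channels) and
`train_config()` defaults (batch 16, 50 epochs).

A thin command-line surface wraps the same functions
(`inst/cli/csmrigan.R`): `make-phantoms`, `make-masks`, `train`,
`reconstruct`, `evaluate`, `ablate`, with YAML configurations and
self-describing run directories.

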