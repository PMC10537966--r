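#' Loss-term weights of the combined generator objective
#'
#' The generator minimizes
#' `L = alpha * L_imse + beta * L_fmse + delta * L_vgg + L_gen`,
#' the weighted sum of the image-domain MSE, the frequency-domain MSE, the
#' perceptual feature loss, and the adversarial term. Defaults are the
#' weights used for training: alpha = 15, beta = 0.1, delta = 0.0025.
#'
#' @param alpha Weight of the image-domain MSE term. Default 15.
#' @param beta Weight of the frequency-domain MSE term. Default 0.1.
#' @param delta Weight of the perceptual feature term. Default 0.0025.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 15, beta = 0.1, delta = 0.0025) {
  if (alpha < 0 || beta < 0 || delta < 0)
    stop("loss_weights: weights must be nonnegative")
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "loss_weights")
}

EPS_PROB <- 1e-7

clamp_prob <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probability outside [0, 1]")
  pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)
}

#' Image-domain MSE loss
#'
#' `0.5 * mean((xt - xu)^2)` over pixels: half the mean squared pixel
#' difference between the fully sampled image and the reconstruction. The
#' mean (rather than sum) keeps the magnitude independent of image size, so
#' the printed weights transfer across resolutions.
#'
#' @param xt,xu Real matrices of identical shape (ground truth,
#'   reconstruction).
#' @return Nonnegative scalar, zero iff the images are identical.
#' @export
image_mse_loss <- function(xt, xu) {
  check_same_shape(xt, xu)
  0.5 * mean((xt - xu)^2)
}

#' Frequency-domain MSE loss
#'
#' `0.5 * mean(|F(xt) - F(xu)|^2)` over k-space points, with `F` the
#' unitary Fourier transform. Under the unitary convention this equals
#' [image_mse_loss()] exactly (Parseval); the term is kept as a separate,
#' separately weighted objective because the two coincide only under this
#' normalization.
#'
#' @inheritParams image_mse_loss
#' @return Nonnegative scalar.
#' @export
freq_mse_loss <- function(xt, xu) {
  check_same_shape(xt, xu)
  0.5 * mean(Mod(forward_fft(xt) - forward_fft(xu))^2)
}

#' Perceptual feature-space loss
#'
#' `0.5 * mean((f(xt) - f(xu))^2)` where `f` is a feature extractor.
#' The default extractor (see [default_extractor()]) is a fixed, seeded,
#' randomly initialized convolutional stack, giving a deterministic
#' texture-sensitive feature space with no external weight files; any
#' extractor exposing `$forward()` (and `$backward()` when used in
#' training) can be injected, e.g. pretrained VGG16 features.
#'
#' @inheritParams image_mse_loss
#' @param extractor A feature extractor: a layer object, or a plain
#'   function mapping an image to a feature array.
#' @return Nonnegative scalar.
#' @export
perceptual_loss <- function(xt, xu, extractor = default_extractor()) {
  check_same_shape(xt, xu)
  ft <- extract_features(extractor, xt)
  fu <- extract_features(extractor, xu)
  0.5 * mean((ft - fu)^2)
}

extract_features <- function(extractor, x) {
  if (is.function(extractor)) return(extractor(x))
  if (is.matrix(x)) x <- promote4d(x)
  extractor$forward(x, train = FALSE)
}

the_extractor <- new.env(parent = emptyenv())

#' Default perceptual feature extractor
#'
#' A small convolutional stack (1 -> 8 -> 8 channels, 3x3 kernels, ReLU)
#' with fixed, seeded random weights and identity-preserving batch
#' statistics frozen at initialization. Deterministic across sessions,
#' needs no downloads, and is sensitive to local texture, which is all the
#' perceptual term requires at phantom scale. Built once and memoized.
#'
#' @param channels Feature width. Default 8.
#' @param seed Seed for the fixed random weights. Default 727.
#' @return A frozen feature-extractor layer.
#' @export
default_extractor <- function(channels = 8L, seed = 727L) {
  key <- paste0("c", channels, "s", seed)
  if (is.null(the_extractor[[key]])) {
    local_seed(seed, {
      net <- nn_sequential(nn_conv(1L, channels, 3L), nn_relu(),
                           nn_conv(channels, channels, 3L), nn_relu())
    })
    the_extractor[[key]] <- net
  }
  the_extractor[[key]]
}

#' Adversarial generator loss
#'
#' `-log(d)` for the discriminator probability `d` assigned to a generated
#' image (probabilities are clamped to `[1e-7, 1 - 1e-7]` before the log).
#' Decreases as the generator fools the discriminator.
#'
#' @param d_out Discriminator probability (scalar or vector; vectors are
#'   averaged).
#' @return Nonnegative scalar.
#' @export
adversarial_gen_loss <- function(d_out) {
  mean(-log(clamp_prob(d_out)))
}

#' Discriminator loss
#'
#' Binary cross entropy against the real/reconstructed labels:
#' `-log(d_real) - log(1 - d_fake)`, averaged over a batch.
#'
#' @param d_real Probabilities assigned to fully sampled images.
#' @param d_fake Probabilities assigned to reconstructions.
#' @return Nonnegative scalar; approaches 0 for a perfect discriminator.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  mean(-log(clamp_prob(d_real))) + mean(-log(1 - clamp_prob(d_fake)))
}

#' Weighted combination of precomputed loss terms
#'
#' `alpha * l_imse + beta * l_fmse + delta * l_vgg + l_gen`. Exposed
#' separately so the weighting can be exercised on constructed term values.
#'
#' @param weights A [loss_weights()].
#' @param l_imse,l_fmse,l_vgg,l_gen Term values.
#' @return The combined scalar loss.
#' @export
combine_terms <- function(weights, l_imse, l_fmse, l_vgg, l_gen) {
  weights$alpha * l_imse + weights$beta * l_fmse + weights$delta * l_vgg + l_gen
}

#' Full generator loss bundle
#'
#' Computes all four terms and their weighted combination for a ground
#' truth / reconstruction pair.
#'
#' @inheritParams image_mse_loss
#' @param d_out Discriminator probability for the reconstruction.
#' @param weights A [loss_weights()].
#' @param extractor Perceptual feature extractor.
#' @return A `loss_bundle` list with `l_imse`, `l_fmse`, `l_vgg`, `l_gen`,
#'   `l_combine`.
#' @export
combined_loss <- function(xt, xu, d_out, weights = loss_weights(),
                          extractor = default_extractor()) {
  l_imse <- image_mse_loss(xt, xu)
  l_fmse <- freq_mse_loss(xt, xu)
  l_vgg <- perceptual_loss(xt, xu, extractor)
  l_gen <- adversarial_gen_loss(d_out)
  structure(list(l_imse = l_imse, l_fmse = l_fmse, l_vgg = l_vgg,
                 l_gen = l_gen,
                 l_combine = combine_terms(weights, l_imse, l_fmse, l_vgg, l_gen)),
            class = "loss_bundle")
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
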