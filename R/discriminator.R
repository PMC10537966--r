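#' Discriminator configuration
#'
#' @param n_layers Number of stride-2 convolution layers. Default 4.
#' @param base_channels Channels after the first layer, doubling per layer.
#'   Default 32.
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#'   Default 0.2.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(n_layers = 4L, base_channels = 32L,
                                 leaky_slope = 0.2) {
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

#' Build the real/reconstructed image discriminator
#'
#' A stack of stride-2 3x3 convolutions — spatial downsampling is done
#' entirely by convolution strides, never by max pooling — each followed by
#' batch normalization and LeakyReLU (the first layer, conventionally,
#' omits the normalization), then global average pooling, an affine map,
#' and a logistic output giving the per-image probability that the input is
#' a fully sampled acquisition rather than a reconstruction.
#'
#' @param cfg A [discriminator_config()].
#' @return A `discriminator` object; run it with [discriminator_forward()].
#' @export
discriminator <- function(cfg = discriminator_config()) {
  L <- cfg$n_layers
  ch <- cfg$base_channels * 2^(seq_len(L) - 1L)
  layers <- list()
  c_in <- 1L
  for (l in seq_len(L)) {
    layers <- c(layers, list(nn_conv(c_in, ch[l], 3L, stride = 2L, pad = 1L)))
    if (l > 1) layers <- c(layers, list(nn_batchnorm(ch[l])))
    layers <- c(layers, list(nn_leaky_relu(cfg$leaky_slope)))
    c_in <- ch[l]
  }
  body <- do.call(nn_sequential, layers)
  fc <- nn_dense(ch[L], 1L)
  sig <- nn_sigmoid()
  self <- new_layer("discriminator", cfg = cfg, layers = list(body, fc, sig))
  self$forward <- function(x, train = FALSE) {
    x <- promote4d(x)
    h <- body$forward(x, train)
    self$hdims <- dim(h)
    pooled <- global_avg_pool(h)                 # (C, N)
    logits <- fc$forward(pooled)                 # (1, N)
    as.numeric(sig$forward(logits))
  }
  self$backward <- function(gp) {
    # gp: numeric gradient per image w.r.t. the output probability
    gl <- sig$backward(matrix(gp, 1L))
    gpool <- fc$backward(gl)                     # (C, N)
    d <- self$hdims
    gh <- array(rep(gpool / (d[1] * d[2]), each = d[1] * d[2]), d)
    body$backward(gh)
  }
  self
}

#' Run the discriminator on a batch
#'
#' @param disc A [discriminator()].
#' @param x Matrix, list of matrices, or (H, W, 1, N) array.
#' @param train Logical; batch-statistics mode.
#' @return Numeric vector of per-image probabilities, each strictly in
#'   (0, 1).
#' @export
discriminator_forward <- function(disc, x, train = FALSE) {
  if (is.list(x)) x <- as_batch(x)
  disc$forward(x, train)
}

#' Layer types present in a network
#'
#' Recursively lists the class of every layer in a network's graph —
#' useful for structural assertions (e.g., that a discriminator contains no
#' max-pooling operator).
#'
#' @param layer A layer or network object.
#' @return Character vector of layer type names.
#' @export
layer_types <- function(layer) {
  out <- class(layer)[1]
  for (ch in layer$layers) out <- c(out, layer_types(ch))
  out
}
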