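#' Dilated residual block
#'
#' A residual unit whose second convolution is dilated: 3x3 convolution ->
#' batch norm -> ReLU -> 3x3 convolution with the given dilation rate
#' (padding equal to the rate, preserving shape) -> batch norm -> identity
#' skip addition -> ReLU. Because dilation inserts gaps between kernel taps
#' rather than adding taps, the parameter count is independent of the rate
#' while the receptive field grows: one block with rate r spans
#' `2*(1+r)+1` pixels per axis.
#'
#' @param channels Number of feature channels (input == output).
#' @param dilation_rate Dilation of the second convolution, typically 1-3.
#' @return A layer object; run it with [dr_block_forward()].
#' @export
dr_block <- function(channels, dilation_rate = 1L) {
  conv1 <- nn_conv(channels, channels, 3L, dilation = 1L)
  bn1 <- nn_batchnorm(channels)
  relu1 <- nn_relu()
  conv2 <- nn_conv(channels, channels, 3L, dilation = as.integer(dilation_rate))
  bn2 <- nn_batchnorm(channels)
  relu2 <- nn_relu()
  self <- new_layer("dr_block", channels = channels,
                    dilation_rate = as.integer(dilation_rate),
                    layers = list(conv1, bn1, relu1, conv2, bn2, relu2))
  self$forward <- function(x, train = FALSE) {
    if (dim(x)[3] != channels)
      stop("dr_block: expected ", channels, " channels, got ", dim(x)[3])
    h <- relu1$forward(bn1$forward(conv1$forward(x, train), train), train)
    h <- bn2$forward(conv2$forward(h, train), train)
    relu2$forward(h + x, train)
  }
  self$backward <- function(gy) {
    g <- relu2$backward(gy)
    gx_skip <- g
    g <- conv1$backward(bn1$backward(relu1$backward(
      conv2$backward(bn2$backward(g)))))
    g + gx_skip
  }
  self
}

#' @rdname dr_block
#' @param block A [dr_block()].
#' @param x Feature tensor (H, W, C, N) — a matrix or (H, W, C) array is
#'   promoted to a single-sample batch.
#' @param train Logical; use batch statistics in the normalization layers.
#' @return Feature tensor of the same shape as the input.
#' @export
dr_block_forward <- function(block, x, train = FALSE) {
  x <- promote4d(x)
  block$forward(x, train)
}

promote4d <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1, 1)
  else if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  x
}

#' Channel attention block
#'
#' Channel reweighting that combines global max pooling and global average
#' pooling: each channel's pooled descriptors pass through a shared
#' two-layer bottleneck transform (one scalar in, `channels / reduction`
#' hidden units, one scalar out; the same weights are applied to every
#' channel and to both pooling branches), the two branch outputs are
#' summed per channel and squashed by a logistic function to weights in
#' (0, 1), and the input is scaled channel-wise. Because the transform is
#' shared across channels it is permutation-equivariant: channels with
#' identical content receive identical weights, and uninformative
#' low-activity background channels are suppressed consistently.
#'
#' @param channels Number of input channels (>= 2).
#' @param reduction Bottleneck reduction ratio (hidden width is
#'   `channels / reduction`); clamped to give at least one hidden unit
#'   (with a warning) when `channels < reduction`.
#' @return A layer object; run it with [cam_forward()].
#' @export
cam_block <- function(channels, reduction = 8L) {
  if (channels < 2) stop("cam_block: need at least 2 channels")
  if (channels < reduction) {
    warning("cam_block: channels < reduction; clamping reduction to give 1 hidden unit")
    reduction <- channels
  }
  hidden <- max(1L, channels %/% as.integer(reduction))
  # both branches share the bottleneck weights but keep their own caches
  fc1a <- nn_dense(1L, hidden)
  # pooled descriptors of post-ReLU features are nonnegative; a positive
  # first layer keeps every bottleneck unit active at initialization
  fc1a$params$w$value[] <- abs(fc1a$params$w$value)
  fc2a <- nn_dense(hidden, 1L)
  fc1m <- nn_dense(1L, hidden, share = fc1a)
  fc2m <- nn_dense(hidden, 1L, share = fc2a)
  fc1m$params <- list(); fc2m$params <- list()  # parameters owned by fc*a
  relu_a <- nn_relu2d(); relu_m <- nn_relu2d()
  self <- new_layer("cam", channels = channels, hidden = hidden,
                    layers = list(fc1a, fc2a))
  # descriptors enter as (C, N); the shared transform sees each channel as
  # an independent scalar sample: reshape to (1, C*N)
  mlp_fwd <- function(v, fc1, fc2, relu) {
    d <- dim(v)
    matrix(fc2$forward(relu$forward(fc1$forward(matrix(v, 1L)))), d[1], d[2])
  }
  mlp_bwd <- function(g, fc1, fc2, relu) {
    d <- dim(g)
    matrix(fc1$backward(relu$backward(fc2$backward(matrix(g, 1L)))), d[1], d[2])
  }
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    a <- global_avg_pool(x)                    # (C, N)
    mx <- global_max_pool(x)
    z <- mlp_fwd(a, fc1a, fc2a, relu_a) + mlp_fwd(mx$value, fc1m, fc2m, relu_m)
    s <- 1 / (1 + exp(-z))                     # (C, N) weights in (0, 1)
    self$x <- x; self$s <- s; self$argmax <- mx$argmax; self$dims <- d
    x * rep(s, each = d[1] * d[2])
  }
  self$backward <- function(gy) {
    d <- self$dims
    s_full <- rep(self$s, each = d[1] * d[2])
    gx <- gy * s_full
    gs <- matrix(colSums(matrix(gy * self$x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    gz <- gs * self$s * (1 - self$s)
    ga <- mlp_bwd(gz, fc1a, fc2a, relu_a)      # avg branch
    gm <- mlp_bwd(gz, fc1m, fc2m, relu_m)      # max branch (shared weights)
    gx <- gx + rep(ga / (d[1] * d[2]), each = d[1] * d[2])
    # scatter max-branch gradient to the argmax positions
    gxm <- matrix(0, d[1] * d[2], d[3] * d[4])
    gxm[cbind(self$argmax, seq_along(self$argmax))] <- as.numeric(gm)
    gx + array(gxm, d)
  }
  self
}

# ReLU on (F, N) matrices (used inside the CAM bottleneck)
nn_relu2d <- function() {
  self <- new_layer("relu2d")
  self$forward <- function(x, train = FALSE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(gy) gy * self$mask
  self
}

#' @rdname cam_block
#' @param cam A [cam_block()].
#' @param x Feature tensor (H, W, C, N).
#' @param train Unused (kept for interface symmetry).
#' @return The channel-reweighted tensor, same shape.
#' @export
cam_forward <- function(cam, x, train = FALSE) {
  x <- promote4d(x)
  cam$forward(x, train)
}

#' Per-channel attention weights of a CAM block
#'
#' Runs only the squeeze/excitation path and returns the (C, N) weight
#' matrix, each entry strictly in (0, 1).
#'
#' @param cam A [cam_block()].
#' @param x Feature tensor.
#' @return Matrix of channel weights (C, N).
#' @export
cam_weights <- function(cam, x) {
  cam$forward(promote4d(x))
  cam$s
}

#' Multi-scale information fusion block
#'
#' Aggregates decoder features from several resolutions into one
#' full-resolution map: each level is projected to a common channel width by
#' a 1x1 convolution, upsampled to full resolution by bilinear
#' interpolation (the two linear operations commute, so projection is
#' applied first for speed), the levels are summed, and a final 3x3
#' convolution fuses the sum. Avoids losing mid-decoder detail in the
#' bottom-up decoding path.
#'
#' @param in_channels Integer vector: channels of each input level, finest
#'   (stride 1) first.
#' @param width Common channel width after projection.
#' @return A layer object; run it with [fusion_forward()].
#' @export
fusion_block <- function(in_channels, width) {
  projs <- lapply(in_channels, function(ci) nn_conv(ci, width, 1L, pad = 0L))
  fuse <- nn_conv(width, width, 3L)
  self <- new_layer("fusion", width = width, layers = c(projs, list(fuse)))
  self$forward <- function(feats, train = FALSE) {
    feats <- lapply(feats, promote4d)
    d1 <- dim(feats[[1]])
    self$ups <- vector("list", length(feats))
    acc <- 0
    for (i in seq_along(feats)) {
      p <- projs[[i]]$forward(feats[[i]], train)
      up <- nn_upsample(d1[1], d1[2])
      acc <- acc + up$forward(p, train)
      self$ups[[i]] <- up
    }
    fuse$forward(acc, train)
  }
  self$backward <- function(gy) {
    gacc <- fuse$backward(gy)
    lapply(seq_along(self$ups), function(i)
      projs[[i]]$backward(self$ups[[i]]$backward(gacc)))
  }
  self
}

#' @rdname fusion_block
#' @param fus A [fusion_block()].
#' @param feats List of feature tensors at strides 1, 2, 4, ... (finest
#'   first); each is upsampled to the size of the first.
#' @param train Logical.
#' @return Full-resolution fused tensor of `width` channels.
#' @export
fusion_forward <- function(fus, feats, train = FALSE) {
  if (length(feats) == 0) stop("fusion_forward: empty feature list")
  fus$forward(feats, train)
}

#' Generator configuration
#'
#' @param depth Number of encoder levels. Default 4.
#' @param base_channels Channels at the first level, doubling per level.
#'   Default 32.
#' @param dilation_rates Dilation rates of the three dilated residual blocks
#'   at every encoder level. Default `c(1, 2, 3)`.
#' @param use_dilation If `FALSE`, all rates are forced to 1 (ablation);
#'   parameter count is unchanged.
#' @param use_cam Include channel attention blocks. Default `TRUE`.
#' @param use_fusion Include the multi-scale fusion head. Default `TRUE`.
#' @param use_residual Add the global input-plus-correction skip so a
#'   zero-initialized network is the identity map. Default `TRUE`.
#' @param cam_reduction Bottleneck reduction of the CAM blocks. Default 8.
#' @return A `generator_config` list.
#' @export
generator_config <- function(depth = 4L, base_channels = 32L,
                             dilation_rates = c(1L, 2L, 3L),
                             use_dilation = TRUE, use_cam = TRUE,
                             use_fusion = TRUE, use_residual = TRUE,
                             cam_reduction = 8L) {
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dilation_rates = as.integer(dilation_rates),
                 use_dilation = use_dilation, use_cam = use_cam,
                 use_fusion = use_fusion, use_residual = use_residual,
                 cam_reduction = as.integer(cam_reduction)),
            class = "generator_config")
}

#' Build the reconstruction generator
#'
#' U-net mapping a zero-filled magnitude image to a de-aliased
#' reconstruction. Each encoder level applies (after a 2x2 max-pool
#' downsample, from level 2 on) a channel-lifting 3x3 convolution with batch
#' norm and ReLU, three dilated residual blocks with rates
#' `cfg$dilation_rates`, and a channel attention block. The decoder mirrors
#' the encoder with bilinear upsampling and skip-connection concatenation.
#' Decoder features from every resolution feed the multi-scale fusion head;
#' a zero-initialized 1x1 convolution predicts a correction that is added to
#' the input, so an untrained network is exactly the identity.
#'
#' @param cfg A [generator_config()].
#' @return A `generator` object; run it with [generator_forward()].
#' @export
generator <- function(cfg = generator_config()) {
  D <- cfg$depth; B <- cfg$base_channels
  ch <- B * 2^(seq_len(D) - 1L)
  rates <- if (cfg$use_dilation) cfg$dilation_rates else rep(1L, length(cfg$dilation_rates))

  stems <- vector("list", D); blocks <- vector("list", D)
  cams <- vector("list", D); pools <- vector("list", D)
  for (l in seq_len(D)) {
    c_in <- if (l == 1) 1L else ch[l - 1]
    stems[[l]] <- nn_sequential(nn_conv(c_in, ch[l], 3L), nn_batchnorm(ch[l]), nn_relu())
    blocks[[l]] <- lapply(rates, function(r) dr_block(ch[l], r))
    if (cfg$use_cam) cams[[l]] <- cam_block(ch[l], cfg$cam_reduction)
    if (l > 1) pools[[l]] <- nn_maxpool2()
  }
  dec <- vector("list", D); dec_up <- vector("list", D)
  for (l in seq_len(D - 1)) {
    dec[[l]] <- nn_sequential(nn_conv(ch[l + 1] + ch[l], ch[l], 3L),
                              nn_batchnorm(ch[l]), nn_relu())
  }
  fusion <- if (cfg$use_fusion) fusion_block(ch, B) else NULL
  head_in <- if (cfg$use_fusion) B else ch[1]
  head <- nn_conv(head_in, 1L, 1L, pad = 0L, init = "zero")

  children <- c(stems, unlist(blocks, recursive = FALSE),
                Filter(Negate(is.null), cams),
                Filter(Negate(is.null), dec),
                if (!is.null(fusion)) list(fusion), list(head))
  self <- new_layer("generator", cfg = cfg, layers = children)

  enc_level <- function(l, x, train) {
    h <- stems[[l]]$forward(x, train)
    for (b in blocks[[l]]) h <- b$forward(h, train)
    if (cfg$use_cam) h <- cams[[l]]$forward(h, train)
    h
  }
  enc_level_bwd <- function(l, g) {
    if (cfg$use_cam) g <- cams[[l]]$backward(g)
    for (b in rev(blocks[[l]])) g <- b$backward(g)
    stems[[l]]$backward(g)
  }

  self$forward <- function(x, train = FALSE) {
    x <- promote4d(x)
    d <- dim(x)
    div <- 2^(D - 1)
    if (d[1] %% div != 0 || d[2] %% div != 0)
      stop("generator: spatial size ", d[1], "x", d[2],
           " must be divisible by 2^(depth-1) = ", div)
    enc <- vector("list", D)
    h <- x
    for (l in seq_len(D)) {
      if (l > 1) h <- pools[[l]]$forward(h, train)
      h <- enc_level(l, h, train)
      enc[[l]] <- h
    }
    decf <- vector("list", D)
    decf[[D]] <- h
    for (l in seq(D - 1, 1)) {
      dd <- dim(enc[[l]])
      up <- nn_upsample(dd[1], dd[2])
      hu <- up$forward(decf[[l + 1]], train)
      dec_up[[l]] <<- up
      cat_in <- abind4(hu, enc[[l]])
      decf[[l]] <- dec[[l]]$forward(cat_in, train)
    }
    self$enc_dims <- lapply(enc, dim)
    feat <- if (cfg$use_fusion) fusion$forward(decf, train) else decf[[1]]
    corr <- head$forward(feat, train)
    self$input <- x
    if (cfg$use_residual) x + corr else corr
  }

  self$backward <- function(gy) {
    g_corr <- head$backward(gy)
    D <- cfg$depth
    gdec <- vector("list", D)
    if (cfg$use_fusion) {
      gdec <- fusion$backward(g_corr)
    } else {
      for (l in seq_len(D)) gdec[[l]] <- 0
      gdec[[1]] <- g_corr
    }
    genc <- vector("list", D)
    gnext <- 0
    for (l in seq(1, D - 1)) {
      g <- gdec[[l]]
      if (!identical(gnext, 0)) g <- g + gnext
      gcat <- dec[[l]]$backward(g)
      nup <- self$enc_dims[[l + 1]][3]  # channels coming up from below
      ch_l <- dim(gcat)[3] - nup
      ghu <- gcat[, , seq_len(nup), , drop = FALSE]
      genc[[l]] <- gcat[, , nup + seq_len(ch_l), , drop = FALSE]
      gnext <- dec_up[[l]]$backward(ghu)
    }
    gD <- gdec[[D]]
    if (!identical(gD, 0) && !identical(gnext, 0)) gD <- gD + gnext
    else if (identical(gD, 0)) gD <- gnext
    g <- enc_level_bwd(D, gD)
    for (l in seq(D - 1, 1)) {
      g <- pools[[l + 1]]$backward(g)
      g <- g + genc[[l]]
      g <- enc_level_bwd(l, g)
    }
    if (cfg$use_residual) g + gy else g
  }
  self
}

# concatenate two (H, W, C, N) tensors along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Run the generator on a batch of zero-filled images
#'
#' @param gen A [generator()].
#' @param x Matrix (single image), list of matrices, or (H, W, 1, N) array.
#' @param train Logical; batch-statistics mode for normalization layers.
#' @return Same container type as the input: reconstructed image(s).
#' @export
generator_forward <- function(gen, x, train = FALSE) {
  if (is.list(x)) return(batch_to_list(gen$forward(as_batch(x), train)))
  was_mat <- is.matrix(x)
  y <- gen$forward(x, train)
  if (was_mat) y[, , 1, 1] else y
}
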