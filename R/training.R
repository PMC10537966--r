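#' Training configuration
#'
#' Optimizer and schedule settings for adversarial training. Defaults are
#' the reference protocol: Adam with beta1 = 0.9, beta2 = 0.999, initial
#' learning rate 1e-4 halved every 10 epochs, patience-20 early stopping on
#' validation MSE, batch size 16, at most 50 epochs.
#'
#' @param lr0 Initial learning rate. Default 1e-4.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param lr_decay Multiplicative decay factor. Default 0.5.
#' @param lr_interval Epochs between decays. Default 10.
#' @param patience Early-stopping patience in epochs. Default 20.
#' @param batch_size Images per batch. Default 16.
#' @param max_epochs Epoch cap. Default 50.
#' @param max_steps Optional cap on total generator update steps.
#'   Default `Inf`.
#' @param rate Undersampling rate used for training masks. Default 0.2.
#' @param center_fraction,sigma_scale Mask parameters.
#' @param disc_steps Discriminator updates per generator update. Default 1.
#' @param use_adversarial Train the discriminator and include the
#'   adversarial term; when `FALSE`, training reduces to supervised
#'   regression under the weighted MSE/perceptual objective. Default
#'   `TRUE`.
#' @param use_augment Apply the four-way stochastic augmentation online.
#'   Default `TRUE`.
#' @param seed Global seed for initialization, shuffling, masks and
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         lr_decay = 0.5, lr_interval = 10L, patience = 20L,
                         batch_size = 16L, max_epochs = 50L, max_steps = Inf,
                         rate = 0.2, center_fraction = 0.04,
                         sigma_scale = 0.25, disc_steps = 1L,
                         use_adversarial = TRUE, use_augment = TRUE,
                         seed = 1L) {
  structure(list(lr0 = lr0, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 lr_decay = lr_decay, lr_interval = as.integer(lr_interval),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), max_steps = max_steps,
                 rate = rate, center_fraction = center_fraction,
                 sigma_scale = sigma_scale, disc_steps = as.integer(disc_steps),
                 use_adversarial = use_adversarial, use_augment = use_augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * lr_decay^floor(epoch / lr_interval)` with epochs
#' counted from 0, so the defaults give 1e-4 for epochs 0-9, 5e-5 for
#' epochs 10-19, and so on.
#'
#' @param cfg A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 0)) stop("lr_at_epoch: epoch must be nonnegative")
  cfg$lr0 * cfg$lr_decay^floor(epoch / cfg$lr_interval)
}

#' Early-stopping decision on a validation-MSE history
#'
#' Training halts once the best validation MSE has not improved for
#' `patience` consecutive epochs; the checkpoint retained is the one from
#' the best epoch.
#'
#' @param val_mse Numeric vector of per-epoch validation MSE values (or a
#'   history data frame with a `val_mse` column).
#' @param patience Number of non-improving epochs tolerated.
#' @return List with `stop` (logical) and `best_epoch` (1-based index of
#'   the minimum).
#' @export
early_stop <- function(val_mse, patience) {
  if (is.data.frame(val_mse)) val_mse <- val_mse$val_mse
  if (length(val_mse) == 0) stop("early_stop: empty history")
  best <- which.min(val_mse)
  list(stop = (length(val_mse) - best) >= patience, best_epoch = best)
}

# deterministic per-image mask seed for validation/test reproducibility
val_mask_seed <- function(base_seed, idx) (base_seed * 7919L + idx * 104729L) %% 2147483647L

#' Adversarial training of the reconstruction GAN
#'
#' Alternating optimization: for every batch the discriminator takes
#' `disc_steps` updates on real/reconstructed pairs, then the generator
#' takes one update on the combined weighted loss. Both optimizers are Adam
#' with the configured moment decays and share the step-decayed learning
#' rate. Training masks are drawn fresh per sample per batch (maximizing
#' the sampling incoherence the model sees); validation masks are fixed per
#' image by a seeded hash so per-epoch metrics are reproducible. Validation
#' PSNR/SSIM/MSE are computed each epoch and drive patience-based early
#' stopping on MSE; the best-epoch parameters are restored in the returned
#' model. A non-finite loss aborts with a diagnostic error.
#'
#' @param images List of ground-truth H x W matrices in \[0, 1\].
#' @param gen_cfg A [generator_config()].
#' @param disc_cfg A [discriminator_config()].
#' @param weights A [loss_weights()].
#' @param cfg A [train_config()].
#' @param extractor Perceptual feature extractor.
#' @param verbose Print per-epoch progress.
#' @return A `csmri_fit` list: `generator`, `discriminator`, `history`
#'   (per-epoch data frame), `best_epoch`, `split`, and the configs.
#' @export
train <- function(images, gen_cfg = generator_config(),
                  disc_cfg = discriminator_config(),
                  weights = loss_weights(), cfg = train_config(),
                  extractor = default_extractor(), verbose = FALSE) {
  stopifnot(is.list(images), length(images) >= 10)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  npix <- h * w

  set.seed(cfg$seed)
  split <- split_dataset(seq_along(images), seed = cfg$seed)
  G <- generator(gen_cfg)
  D <- discriminator(disc_cfg)
  optG <- adam_optimizer(collect_params(G), cfg$adam_beta1, cfg$adam_beta2)
  optD <- adam_optimizer(collect_params(D), cfg$adam_beta1, cfg$adam_beta2)

  history <- NULL
  best_state <- NULL
  best_mse <- Inf
  best_epoch <- 0L
  step <- 0L
  done <- FALSE

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    order <- sample(split$train)
    batch_starts <- seq(1, length(order), by = cfg$batch_size)
    ep_loss <- NULL
    for (bs in batch_starts) {
      ids <- order[seq(bs, min(bs + cfg$batch_size - 1L, length(order)))]
      xt_list <- images[ids]
      if (cfg$use_augment) xt_list <- lapply(xt_list, augment)
      xu_list <- lapply(xt_list, function(im) {
        m <- generate_mask(h, w, cfg$rate, cfg$center_fraction,
                           cfg$sigma_scale, seed = sample.int(2147483646L, 1L))
        zero_fill_recon(im, m)
      })
      xt <- as_batch(xt_list)
      xu <- as_batch(xu_list)
      B <- length(ids)

      # --- discriminator update(s) ---
      l_disc <- NA_real_
      for (k in seq_len(if (cfg$use_adversarial) cfg$disc_steps else 0L)) {
        fake <- G$forward(xu, train = TRUE)
        d_real <- clamp_prob(D$forward(xt, train = TRUE))
        zero_grads(D)
        D$backward(-1 / d_real / B)
        d_fake <- clamp_prob(D$forward(fake, train = TRUE))
        D$backward(1 / (1 - d_fake) / B)
        l_disc <- discriminator_loss(d_real, d_fake)
        if (!is.finite(l_disc))
          stop("train: non-finite discriminator loss at step ", step)
        optD$step(lr)
        zero_grads(D)
      }

      # --- generator update ---
      fake <- G$forward(xu, train = TRUE)
      diff <- fake - xt
      l_imse <- 0.5 * sum(diff^2) / npix / B
      l_fmse <- mean(vapply(seq_len(B), function(n)
        freq_mse_loss(xt[, , 1, n], fake[, , 1, n]), numeric(1)))
      g_fake <- (weights$alpha + weights$beta) * diff / npix / B

      ft <- extractor$forward(xt, train = FALSE)
      fu <- extractor$forward(fake, train = FALSE)
      fdiff <- fu - ft
      l_vgg <- 0.5 * mean(fdiff^2)
      zero_grads(extractor)
      g_fake <- g_fake + weights$delta * extractor$backward(fdiff / length(fdiff))

      if (cfg$use_adversarial) {
        d_fake <- clamp_prob(D$forward(fake, train = TRUE))
        l_gen <- adversarial_gen_loss(d_fake)
        zero_grads(D)
        g_fake <- g_fake + D$backward(-1 / d_fake / B)
        zero_grads(D)
      } else {
        l_gen <- 0
      }

      l_comb <- combine_terms(weights, l_imse, l_fmse, l_vgg, l_gen)
      if (!is.finite(l_comb))
        stop("train: non-finite generator loss at step ", step,
             " (imse=", l_imse, ", fmse=", l_fmse, ", vgg=", l_vgg,
             ", gen=", l_gen, ")")
      zero_grads(G)
      G$backward(g_fake)
      optG$step(lr)
      zero_grads(G)

      step <- step + 1L
      ep_loss <- rbind(ep_loss, c(l_imse, l_fmse, l_vgg, l_gen, l_comb, l_disc))
      if (step >= cfg$max_steps) { done <- TRUE; break }
    }

    # --- validation with fixed per-image masks ---
    val <- vapply(split$val, function(i) {
      xt_i <- images[[i]]
      m <- generate_mask(h, w, cfg$rate, cfg$center_fraction, cfg$sigma_scale,
                         seed = val_mask_seed(cfg$seed, i))
      xu_i <- zero_fill_recon(xt_i, m)
      xr <- pmin(pmax(generator_forward(G, xu_i), 0), 1)
      c(psnr(xt_i, xr), ssim(xt_i, xr), mse(xt_i, xr))
    }, numeric(3))

    ml <- colMeans(ep_loss)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, steps = step,
      l_imse = ml[1], l_fmse = ml[2], l_vgg = ml[3], l_gen = ml[4],
      l_combine = ml[5], l_disc = ml[6],
      val_psnr = mean(val[1, ]), val_ssim = mean(val[2, ]),
      val_mse = mean(val[3, ])))
    if (verbose)
      message(sprintf("epoch %d  lr %.2g  L=%.4f  val PSNR %.2f dB  val MSE %.5f",
                      epoch, lr, ml[5], mean(val[1, ]), mean(val[3, ])))

    if (mean(val[3, ]) < best_mse) {
      best_mse <- mean(val[3, ])
      best_epoch <- epoch
      best_state <- list(gen = state_dict(G), disc = state_dict(D))
    }
    if (done || early_stop(history$val_mse, cfg$patience)$stop) break
  }

  if (!is.null(best_state)) {
    load_state_dict(G, best_state$gen)
    load_state_dict(D, best_state$disc)
  }
  structure(list(generator = G, discriminator = D, history = history,
                 best_epoch = best_epoch, split = split,
                 gen_cfg = gen_cfg, disc_cfg = disc_cfg,
                 weights = weights, train_cfg = cfg),
            class = "csmri_fit")
}

# ---- checkpointing ---------------------------------------------------------

state_dict <- function(layer) {
  sd <- list(params = lapply(layer$params, function(p) p$value))
  if (inherits(layer, "batchnorm"))
    sd$running <- list(mean = layer$running_mean, var = layer$running_var)
  sd$children <- lapply(layer$layers, state_dict)
  sd
}

load_state_dict <- function(layer, sd) {
  for (nm in names(layer$params)) layer$params[[nm]]$value <- sd$params[[nm]]
  if (inherits(layer, "batchnorm")) {
    layer$running_mean <- sd$running$mean
    layer$running_var <- sd$running$var
  }
  for (i in seq_along(layer$layers)) load_state_dict(layer$layers[[i]], sd$children[[i]])
  invisible(layer)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint embeds the generator and discriminator configurations
#' together with all parameter values and normalization statistics, so
#' loading rebuilds the networks without any other context.
#'
#' @param fit A `csmri_fit` from [train()].
#' @param path File path (RDS).
#' @return `path` (save) or the rebuilt `csmri_fit` (load).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(gen_cfg = fit$gen_cfg, disc_cfg = fit$disc_cfg,
               weights = fit$weights, train_cfg = fit$train_cfg,
               gen_state = state_dict(fit$generator),
               disc_state = state_dict(fit$discriminator),
               history = fit$history, best_epoch = fit$best_epoch),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  G <- generator(do.call(generator_config, unclass(ck$gen_cfg)))
  D <- discriminator(do.call(discriminator_config, unclass(ck$disc_cfg)))
  load_state_dict(G, ck$gen_state)
  load_state_dict(D, ck$disc_state)
  structure(list(generator = G, discriminator = D, history = ck$history,
                 best_epoch = ck$best_epoch, gen_cfg = ck$gen_cfg,
                 disc_cfg = ck$disc_cfg, weights = ck$weights,
                 train_cfg = ck$train_cfg),
            class = "csmri_fit")
}
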