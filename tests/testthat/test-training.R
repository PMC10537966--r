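test_that("learning-rate schedule follows the closed-form step decay", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(cfg, 0), 1e-4)
  expect_identical(lr_at_epoch(cfg, 9), 1e-4)
  expect_identical(lr_at_epoch(cfg, 10), 5e-5)
  expect_identical(lr_at_epoch(cfg, 25), 2.5e-5)
  expect_equal(lr_at_epoch(cfg, 0:39), rep(c(1e-4, 5e-5, 2.5e-5, 1.25e-5), each = 10))
  expect_error(lr_at_epoch(cfg, -1), "nonnegative")
})

test_that("early stopping halts patience epochs after the best validation MSE", {
  # strictly improving: never stops, best is the last epoch
  dec <- seq(1, 0.5, length.out = 50)
  es <- early_stop(dec, patience = 20)
  expect_false(es$stop)
  expect_identical(es$best_epoch, 50L)

  # minimum at epoch 3, flat afterwards: stops exactly at epoch 23
  seq23 <- c(0.5, 0.4, 0.3, rep(0.35, 20))
  expect_false(early_stop(seq23[1:22], patience = 20)$stop)
  es23 <- early_stop(seq23, patience = 20)
  expect_true(es23$stop)
  expect_identical(es23$best_epoch, 3L)

  expect_false(early_stop(c(0.3, 0.2), patience = 20)$stop)
  expect_error(early_stop(numeric(0), 5), "empty")
})

test_that("a short adversarial run completes and logs a well-formed history", {
  imgs <- make_phantom_set(12, phantom_spec(size = c(32, 32), seed = 70))
  fit <- train(imgs,
               generator_config(depth = 2, base_channels = 4, cam_reduction = 2),
               discriminator_config(n_layers = 2, base_channels = 4),
               loss_weights(),
               train_config(batch_size = 4, max_epochs = 2, rate = 0.3, seed = 5))
  expect_s3_class(fit, "csmri_fit")
  h <- fit$history
  expect_identical(h$epoch, 1:2)
  expect_true(all(c("l_imse", "l_fmse", "l_vgg", "l_gen", "l_combine", "l_disc",
                    "val_psnr", "val_ssim", "val_mse", "lr") %in% names(h)))
  expect_true(all(is.finite(unlist(h))))
  expect_gte(fit$best_epoch, 1L)
})

test_that("training is deterministic given the seed", {
  imgs <- make_phantom_set(12, phantom_spec(size = c(16, 16), seed = 71))
  run_once <- function() {
    fit <- train(imgs,
                 generator_config(depth = 2, base_channels = 4, cam_reduction = 2),
                 discriminator_config(n_layers = 2, base_channels = 4),
                 loss_weights(),
                 train_config(batch_size = 4, max_epochs = 1, rate = 0.3, seed = 9))
    fit$history$l_combine[1]
  }
  l1 <- run_once()
  l2 <- run_once()
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("generator and discriminator gradients stay isolated", {
  set.seed(72)
  G <- generator(generator_config(depth = 2, base_channels = 4, cam_reduction = 2))
  D <- discriminator(discriminator_config(n_layers = 2, base_channels = 4))
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))

  # a discriminator backward pass leaves every generator gradient at zero
  fake <- G$forward(x, train = TRUE)
  csmrigan:::zero_grads(G); csmrigan:::zero_grads(D)
  p <- D$forward(fake, train = TRUE)
  D$backward(-1 / p)
  g_gen <- vapply(collect_params(G), function(q) sum(abs(q$grad)), numeric(1))
  expect_true(all(g_gen == 0))
  g_disc <- vapply(collect_params(D), function(q) sum(abs(q$grad)), numeric(1))
  expect_true(all(g_disc > 0))

  # propagating into the generator does not touch discriminator values
  d_before <- lapply(collect_params(D), function(q) q$value)
  gx <- D$backward(-1 / p)
  G$backward(gx)
  d_after <- lapply(collect_params(D), function(q) q$value)
  expect_identical(d_before, d_after)
})

test_that("pure supervised training descends on easy phantoms", {
  imgs <- make_phantom_set(20, phantom_spec(size = c(32, 32), noise_std = 0, seed = 73))
  fit <- train(imgs,
               generator_config(depth = 2, base_channels = 4, cam_reduction = 2),
               discriminator_config(n_layers = 2, base_channels = 4),
               loss_weights(alpha = 15, beta = 0, delta = 0),
               train_config(batch_size = 4, max_epochs = 5, rate = 0.3, seed = 3,
                            use_adversarial = FALSE, patience = 100))
  expect_true(all(diff(fit$history$val_mse) <= 0))
  expect_true(all(is.na(fit$history$l_disc)))
})

test_that("checkpoints rebuild an identical model", {
  imgs <- make_phantom_set(12, phantom_spec(size = c(16, 16), seed = 74))
  fit <- train(imgs,
               generator_config(depth = 2, base_channels = 4, cam_reduction = 2),
               discriminator_config(n_layers = 2, base_channels = 4),
               loss_weights(),
               train_config(batch_size = 4, max_epochs = 1, rate = 0.3, seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  x <- fixture_image(16, 9)
  expect_identical(generator_forward(back$generator, x),
                   generator_forward(fit$generator, x))
  expect_identical(discriminator_forward(back$discriminator, x),
                   discriminator_forward(fit$discriminator, x))
  expect_identical(back$history, fit$history)
})
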