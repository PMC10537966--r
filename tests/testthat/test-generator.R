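test_that("dilated residual block: identity path, parameter invariance, receptive field", {
  set.seed(51)
  # zero conv weights + identity normalization leave activation(input)
  blk <- dr_block(4, dilation_rate = 2)
  for (p in collect_params(blk)) {
    if (length(dim(p$value)) == 4) p$value[] <- 0
  }
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- dr_block_forward(blk, x)
  expect_equal(y, x * (x > 0), tolerance = 1e-6)

  # dilation inserts gaps, not taps: parameter count independent of rate
  expect_identical(n_params(dr_block(8, 1)), n_params(dr_block(8, 3)))

  # footprint of one block with rate r spans 2*(1+r)+1 pixels per axis
  for (r in c(1, 3)) {
    span <- rf_span(list(dr_block(2, r)), n = 15, channels = 2)
    expect_identical(span, rep(2 * (1 + r) + 1, 2))
  }

  expect_error(dr_block_forward(blk, array(0, c(8, 8, 3, 1))), "channels")
})

test_that("channel attention: logistic weights, shared-transform equivariance", {
  set.seed(52)
  cam <- cam_block(8, reduction = 4)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))

  # weights strictly inside (0,1); output is the channel-scaled input
  w <- cam_weights(cam, x)
  expect_true(all(w > 0 & w < 1))
  y <- cam_forward(cam, x)
  expect_equal(y, x * rep(w, each = 36), tolerance = 1e-12)

  # zeroed attention transform gives logistic(0) = 0.5 everywhere
  cam0 <- cam_block(8, reduction = 4)
  for (p in collect_params(cam0)) p$value[] <- 0
  expect_equal(cam_forward(cam0, x), 0.5 * x, tolerance = 1e-12)
  expect_true(all(cam_weights(cam0, x) == 0.5))

  # duplicated channels receive identical weights
  xd <- x
  xd[, , 2, ] <- xd[, , 1, ]
  wd <- cam_weights(cam, xd)
  expect_lt(max(abs(wd[1, ] - wd[2, ])), 1e-6)

  expect_warning(cam_block(4, reduction = 8), "clamping")
  expect_error(cam_block(1), "2 channels")
})

test_that("multi-scale fusion: single-level reduction and exact constant upsampling", {
  set.seed(53)
  fus <- fusion_block(c(4), width = 3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- fusion_forward(fus, list(x))
  # reduces to 1x1 projection followed by the 3x3 fusion convolution
  proj <- fus$layers[[1]]; fuse <- fus$layers[[2]]
  expect_equal(y, fuse$forward(proj$forward(x)), tolerance = 1e-12)

  # constant coarse maps upsample exactly
  fus2 <- fusion_block(c(2, 2), width = 2)
  lvl1 <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  lvl2 <- array(1.25, c(4, 4, 2, 1))
  expect_equal(bilinear_resize(lvl2, 8, 8), array(1.25, c(8, 8, 2, 1)))
  expect_identical(dim(fusion_forward(fus2, list(lvl1, lvl2))), c(8L, 8L, 2L, 1L))

  expect_error(fusion_forward(fus, list()), "empty")
})

test_that("generator: zero-initialized network is the identity map", {
  set.seed(54)
  G <- generator(generator_config(depth = 2, base_channels = 4, cam_reduction = 2))
  x <- fixture_image(16, seed = 5)
  expect_identical(generator_forward(G, x), x)
})

test_that("generator preserves shape and enforces divisibility", {
  set.seed(55)
  cfg <- generator_config(depth = 3, base_channels = 4, cam_reduction = 2)
  G <- generator(cfg)
  for (n in c(16L, 32L)) {
    y <- generator_forward(G, fixture_image(n, seed = n))
    expect_identical(dim(y), c(n, n))
  }
  expect_error(generator_forward(G, fixture_image(18, seed = 1)), "divisible")
})

test_that("ablation toggles change parameters as the architecture dictates", {
  set.seed(56)
  base <- function(...) generator_config(depth = 2, base_channels = 4,
                                         cam_reduction = 2, ...)
  p_full <- n_params(generator(base()))
  expect_identical(n_params(generator(base(use_dilation = FALSE))), p_full)
  expect_lt(n_params(generator(base(use_cam = FALSE))), p_full)

  x <- fixture_image(16, seed = 3)
  for (cfg in list(base(use_dilation = FALSE), base(use_cam = FALSE),
                   base(use_fusion = FALSE))) {
    expect_identical(dim(generator_forward(generator(cfg), x)), c(16L, 16L))
  }
})

test_that("three stacked blocks with rates 1,2,3 span a 19x19 receptive field", {
  set.seed(57)
  span <- rf_span(lapply(1:3, function(r) dr_block(2, r)), n = 25, channels = 2)
  expect_identical(span, c(19, 19))
})

test_that("generator is deterministic in inference and trains every parameter", {
  set.seed(58)
  G <- generator(generator_config(depth = 2, base_channels = 4, cam_reduction = 2))
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  expect_identical(G$forward(x, train = FALSE), G$forward(x, train = FALSE))

  # after the first optimizer step unlocks the zero-initialized head,
  # gradient reaches every trainable parameter
  tgt <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  opt <- adam_optimizer(collect_params(G))
  for (step in 1:2) {
    y <- G$forward(x, train = TRUE)
    csmrigan:::zero_grads(G)
    G$backward(y - tgt)
    if (step == 1) opt$step(1e-3)
  }
  gnorm <- vapply(collect_params(G), function(p) sum(abs(p$grad)), numeric(1))
  expect_true(all(gnorm > 0))
})

test_that("generator backward matches central differences through the full net", {
  set.seed(59)
  G <- generator(generator_config(depth = 2, base_channels = 3, cam_reduction = 3))
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  tgt <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  loss <- function(no_back = FALSE) {
    y <- G$forward(x, train = TRUE)
    L <- 0.5 * sum((y - tgt)^2)
    if (!no_back) {
      csmrigan:::zero_grads(G)
      G$backward(y - tgt)
    }
    L
  }
  errs <- fd_grad_errors(loss, collect_params(G), k = 3)
  expect_lt(max(errs), 1e-4)
})
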