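test_that("forward transform is unitary: round trip, Parseval, delta spectrum", {
  x <- fixture_image(64, seed = 11)
  k <- forward_fft(x)
  expect_lt(max(Mod(inverse_fft(k) - x)), 1e-10)
  expect_lt(abs(sum(Mod(k)^2) - sum(x^2)), 1e-10 * sum(x^2))

  expect_equal(forward_fft(matrix(0, 8, 8)), matrix(0 + 0i, 8, 8))

  for (pos in list(c(1, 1), c(3, 5), c(8, 8))) {
    d <- matrix(0, 8, 8)
    d[pos[1], pos[2]] <- 1
    expect_equal(Mod(forward_fft(d)), matrix(1 / 8, 8, 8), tolerance = 1e-12)
  }

  expect_error(forward_fft(matrix(c(NA, 1, 2, 3), 2, 2)), "finite")
  expect_error(forward_fft(matrix(1, 1, 5)), "2x2")
})

test_that("inverse transform: zeros, conjugate symmetry of real images, Parseval", {
  expect_equal(inverse_fft(matrix(0 + 0i, 4, 4)), matrix(0 + 0i, 4, 4))

  # spectrum of any real image inverts to a real image
  x <- fixture_image(32, seed = 2)
  xi <- inverse_fft(forward_fft(x))
  expect_lt(max(abs(Im(xi))), 1e-10)

  k <- forward_fft(x)
  expect_lt(abs(sum(Mod(inverse_fft(k))^2) - sum(Mod(k)^2)), 1e-10 * sum(x^2))
})

test_that("mask generation: exact cardinality, forced centre, determinism", {
  # full-rate mask is all ones regardless of seed
  for (s in c(1, 99)) {
    expect_true(all(generate_mask(16, 16, 1.0, seed = s)$pattern == 1))
  }

  cases <- expand.grid(n = c(32, 64), rate = c(0.1, 0.2, 0.5))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; rate <- cases$rate[i]
    m <- generate_mask(n, n, rate, seed = i)
    expect_identical(sum(m$pattern), round(rate * n * n))
    expect_true(all(m$pattern[m$center] == 1))
  }

  # central region holds ~4% of a 256x256 grid and is always fully sampled
  m <- generate_mask(256, 256, 0.1, center_fraction = 0.04, seed = 7)
  expect_equal(sum(m$center) / 256^2, 0.04, tolerance = 0.01)
  expect_true(all(m$pattern[m$center] == 1))

  # deterministic given seed; different seeds give incoherent patterns
  m1 <- generate_mask(64, 64, 0.2, seed = 5)
  m1b <- generate_mask(64, 64, 0.2, seed = 5)
  m2 <- generate_mask(64, 64, 0.2, seed = 6)
  expect_identical(m1$pattern, m1b$pattern)
  expect_lt(sum(m1$pattern * m2$pattern), sum(m1$pattern))

  expect_error(generate_mask(64, 64, 1.2), "target_rate")
  # at 64x64 the 4% centre square rounds up to 169 points but
  # round(0.04 * 64^2) = 164 sampled points are requested
  expect_error(generate_mask(64, 64, 0.04, center_fraction = 0.04),
               "forced central region")
})

test_that("sampling density outside the centre decays with radius", {
  counts <- matrix(0, 32, 32)
  n_draws <- 400
  for (s in seq_len(n_draws))
    counts <- counts + generate_mask(32, 32, 0.25, seed = s)$pattern
  out <- !generate_mask(32, 32, 0.25, seed = 1)$center
  ctr <- floor(32 / 2) + 1
  r <- sqrt(outer(((1:32) - ctr)^2, ((1:32) - ctr)^2, "+"))
  bins <- cut(r[out], quantile(r[out], seq(0, 1, 0.25)), include.lowest = TRUE)
  mean_freq <- tapply(counts[out] / n_draws, bins, mean)
  expect_true(all(diff(mean_freq) < 0))
})

test_that("undersampling zeroes exactly the unsampled points", {
  k <- forward_fft(fixture_image(16, seed = 3))
  ones <- matrix(1, 16, 16)
  expect_identical(undersample(k, ones), k)

  m <- generate_mask(16, 16, 0.3, seed = 1)
  ku <- undersample(k, m)
  expect_true(all(ku[m$pattern == 0] == 0))
  expect_lte(sum(ku != 0), sum(m$pattern))
  # random spectra have no exact zeros, so the counts agree exactly
  expect_identical(sum(ku != 0), as.integer(sum(m$pattern)))

  # centre-only mask leaves energy only in the central region
  mc <- generate_mask(16, 16, sum(m$center) / 256, center_fraction = sum(m$center) / 256,
                      seed = 1)
  kc <- undersample(k, mc)
  expect_true(all(kc[!mc$center] == 0))

  expect_error(undersample(k, matrix(1, 8, 8)), "mismatch|8x8")
})

test_that("zero-filled reconstruction degrades gracefully and contracts energy", {
  ph <- make_phantom(phantom_spec(seed = 4))
  full <- matrix(1, 64, 64)
  expect_lt(max(abs(zero_fill_recon(ph, full) - ph)), 1e-8)

  m20 <- generate_mask(64, 64, 0.2, seed = 9)
  z20 <- zero_fill_recon(ph, m20)
  expect_lt(psnr(ph, z20), psnr(ph, zero_fill_recon(ph, full)))
  # unitary transform + masking projection can only remove energy
  expect_lte(sum(z20^2), sum(ph^2) + 1e-10)

  # undersampling is idempotent in k-space
  ku <- undersample(forward_fft(ph), m20)
  expect_identical(undersample(ku, m20), ku)
})

test_that("masks round-trip through their plain-text serialization", {
  m <- generate_mask(24, 20, 0.3, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$pattern, m$pattern)
  expect_equal(m2$target_rate, m$target_rate)
  expect_equal(m2$sigma_scale, m$sigma_scale)
})
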