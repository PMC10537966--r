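test_that("phantom generation is deterministic, bounded, and structured", {
  spec <- phantom_spec(seed = 21)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # bright structure covers a nontrivial area
  expect_gt(mean(a > 0.5), 0.05)

  # all-zero intensities with no noise give a blank image
  blank <- make_phantom(phantom_spec(intensity_levels = 0, noise_std = 0, seed = 1))
  expect_identical(blank, matrix(0, 64, 64))

  expect_error(phantom_spec(n_ellipses = 2), "n_ellipses")

  # noiseless histogram concentrates on the specified levels (plus 0 and
  # the skull-interior base)
  lv <- c(0.9, 0.35, 0.55, 0.75, 0.95)
  vals <- unique(as.numeric(make_phantom(phantom_spec(intensity_levels = lv, seed = 2))))
  expect_true(all(vals %in% c(0, 0.2 * lv[1], lv)))
})

test_that("reconstruction difficulty increases as the sampling rate drops", {
  ph <- make_phantom(phantom_spec(seed = 30))
  z10 <- zero_fill_recon(ph, generate_mask(64, 64, 0.1, seed = 1))
  z50 <- zero_fill_recon(ph, generate_mask(64, 64, 0.5, seed = 1))
  expect_lt(psnr(ph, z10), psnr(ph, z50))
})

test_that("augmentation transforms satisfy their group laws", {
  x <- fixture_image(20, seed = 8)
  expect_equal(rot90(rot90(rot90(rot90(x)))), x)
  expect_equal(flip_ud(flip_ud(x)), x)
  expect_equal(mirror_lr(mirror_lr(x)), x)
  # flip/mirror/rotation preserve the pixel multiset; translation pads
  expect_identical(sort(as.numeric(rot90(x))), sort(as.numeric(x)))
  expect_identical(sort(as.numeric(flip_ud(x))), sort(as.numeric(x)))
  t1 <- translate(x, 2, -3)
  expect_identical(dim(t1), dim(x))
  expect_true(all(t1[1:2, ] == 0))
})

test_that("augment applies exactly one of four transforms, seeded", {
  x <- fixture_image(20, seed = 9)
  expect_identical(augment(x, seed = 5), augment(x, seed = 5))
  expect_identical(dim(augment(x, seed = 6)), dim(x))
  counts <- table(vapply(1:800, function(s) classify_augment(x, augment(x, seed = s)),
                         character(1)))
  expect_setequal(names(counts), c("flip", "mirror", "rot90", "translate"))
  expect_true(all(counts / 800 > 0.25 - 0.06 & counts / 800 < 0.25 + 0.06))
})

test_that("dataset split is 70/10/20 with remainder to training", {
  s <- split_dataset(1:100, seed = 1)
  expect_identical(lengths(s[c("train", "val", "test")]),
                   c(train = 70L, val = 10L, test = 20L))
  s10 <- split_dataset(1:10, seed = 2)
  expect_identical(lengths(s10[c("train", "val", "test")]),
                   c(train = 7L, val = 1L, test = 2L))
  expect_error(split_dataset(1:9), "at least 10")

  set.seed(3)
  for (n in sample(10:500, 8)) {
    sp <- split_dataset(seq_len(n), seed = n)
    all_items <- c(sp$train, sp$val, sp$test)
    expect_identical(sort(all_items), seq_len(n))
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
  }
})

test_that("phantom sets round-trip through their serialization", {
  spec <- phantom_spec(size = c(16, 16), seed = 12)
  imgs <- make_phantom_set(3, spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_phantom_set(imgs, spec, path)
  back <- read_phantom_set(path)
  expect_length(back$images, 3)
  expect_equal(back$images, imgs)
})
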