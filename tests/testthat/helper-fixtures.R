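# shared fixtures and oracles for the test suite

# small deterministic square test image
fixture_image <- function(n = 16, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# central-difference gradient check: fwd_loss(no_back = TRUE) evaluates the
# loss only; fwd_loss() also runs the backward pass, leaving gradients in
# the parameter environments. Returns relative errors at sampled entries.
fd_grad_errors <- function(fwd_loss, params, eps = 1e-5, k = 5) {
  fwd_loss()
  errs <- c()
  for (p in params) {
    idx <- sample(length(p$value), min(k, length(p$value)))
    for (i in idx) {
      g_an <- p$grad[i]
      old <- p$value[i]
      p$value[i] <- old + eps
      lp <- fwd_loss(no_back = TRUE)
      p$value[i] <- old - eps
      lm <- fwd_loss(no_back = TRUE)
      p$value[i] <- old
      g_fd <- (lp - lm) / (2 * eps)
      errs <- c(errs, abs(g_an - g_fd) / max(1e-4, abs(g_an) + abs(g_fd)))
    }
  }
  errs
}

# finite-difference receptive-field footprint of a stack of layers.
# Convolution weights are replaced by strictly positive values so no path
# can cancel and every ReLU stays open; the footprint then equals the
# theoretical support exactly.
rf_span <- function(blocks, n, channels) {
  for (b in blocks) for (p in collect_params(b)) {
    if (length(dim(p$value)) == 4) p$value <- abs(p$value) + 0.5
  }
  run <- function(x) {
    h <- x
    for (b in blocks) h <- b$forward(h, FALSE)
    h
  }
  x0 <- array(0.5, c(n, n, channels, 1))
  base <- run(x0)
  cmid <- (n + 1) / 2
  nz <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xp <- x0
    xp[i, j, 1, 1] <- xp[i, j, 1, 1] + 1e-3
    nz[i, j] <- abs(run(xp)[cmid, cmid, 1, 1] - base[cmid, cmid, 1, 1]) > 1e-8
  }
  c(diff(range(which(rowSums(nz) > 0))) + 1,
    diff(range(which(colSums(nz) > 0))) + 1)
}

# direct windowed SSIM oracle: explicit loop over valid 11x11 windows with
# Gaussian weights, following the standard definition term by term
ssim_oracle <- function(ref, test, data_range = 1) {
  g1 <- dnorm(seq(-5, 5), sd = 1.5)
  g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  vals <- c()
  for (i in seq_len(nrow(ref) - 10)) {
    for (j in seq_len(ncol(ref) - 10)) {
      a <- ref[i:(i + 10), j:(j + 10)]
      b <- test[i:(i + 10), j:(j + 10)]
      mu1 <- sum(w * a); mu2 <- sum(w * b)
      v1 <- sum(w * a^2) - mu1^2
      v2 <- sum(w * b^2) - mu2^2
      cv <- sum(w * a * b) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
                  ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
    }
  }
  mean(vals)
}

# classify which of the four augmentation transforms produced `out`
classify_augment <- function(image, out) {
  if (isTRUE(all.equal(out, flip_ud(image)))) "flip"
  else if (isTRUE(all.equal(out, mirror_lr(image)))) "mirror"
  else if (isTRUE(all.equal(out, rot90(image)))) "rot90"
  else "translate"
}
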