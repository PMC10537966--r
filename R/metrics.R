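#' Mean squared error between two images
#'
#' Plain mean of squared differences (no 1/2 factor — this is the
#' evaluation metric, distinct from the training loss).
#'
#' @param ref,test Real matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(ref, test) {
  check_same_shape(ref, test)
  mean((ref - test)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(data_range^2 / mse)`. A perfect reconstruction (zero MSE)
#' is reported as a capped 100 dB flag value so reports stay serializable.
#'
#' @inheritParams mse
#' @param data_range Dynamic range of the images. Default 1 (normalized
#'   magnitude images).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 1) {
  if (data_range <= 0) stop("psnr: data_range must be positive")
  m <- mse(ref, test)
  if (m == 0) return(100)
  min(10 * log10(data_range^2 / m), 100)
}

#' Structural similarity index
#'
#' Standard single-scale SSIM: 11x11 Gaussian window with sigma 1.5,
#' stability constants K1 = 0.01 and K2 = 0.03 on a data range of 1, local
#' statistics by Gaussian filtering, map averaged over the valid (fully
#' overlapping) region.
#'
#' @inheritParams mse
#' @param data_range Dynamic range. Default 1.
#' @return Scalar in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(ref, test, data_range = 1) {
  check_same_shape(ref, test)
  win <- 11L
  if (nrow(ref) < win || ncol(ref) < win)
    stop("ssim: images must be at least ", win, "x", win)
  g <- stats::dnorm(seq(-5, 5), sd = 1.5)
  g <- g / sum(g)
  smooth <- function(m) {
    v <- apply(m, 2, function(col) stats::convolve(col, rev(g), type = "filter"))
    t(apply(t(v), 2, function(row) stats::convolve(row, rev(g), type = "filter")))
  }
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu1 <- smooth(ref); mu2 <- smooth(test)
  s11 <- smooth(ref * ref) - mu1^2
  s22 <- smooth(test * test) - mu2^2
  s12 <- smooth(ref * test) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(map)
}

#' Per-pixel squared-error map
#'
#' The spatial distribution of reconstruction error; its mean equals
#' [mse()]. Export with [write_png_image()] for heatmap figures.
#'
#' @inheritParams mse
#' @return Matrix of per-pixel squared differences.
#' @export
mse_map <- function(ref, test) {
  check_same_shape(ref, test)
  (ref - test)^2
}

#' Evaluate a generator over a set of images and sampling rates
#'
#' For each sampling rate, each image is undersampled with a fixed
#' per-image mask (seeded deterministically from `seed` and the image
#' index), reconstructed, and scored against the ground truth; the
#' zero-filled input is scored as the baseline.
#'
#' @param gen A trained [generator()] (or `NULL` to score only the
#'   zero-filled baseline).
#' @param images List of ground-truth matrices in \[0, 1\].
#' @param rates Numeric vector of undersampling rates. Default
#'   `c(0.1, 0.2, 0.3, 0.5)`.
#' @param seed Base seed for the fixed evaluation masks.
#' @param sigma_scale,center_fraction Mask parameters.
#' @return A data frame with one row per rate: mean and sd of PSNR, SSIM,
#'   MSE for the reconstruction and PSNR of the zero-filled baseline.
#' @export
evaluate_model <- function(gen, images, rates = c(0.1, 0.2, 0.3, 0.5),
                           seed = 1L, sigma_scale = 0.25,
                           center_fraction = 0.04) {
  rows <- lapply(rates, function(rate) {
    per <- vapply(seq_along(images), function(i) {
      xt <- images[[i]]
      m <- generate_mask(nrow(xt), ncol(xt), rate, center_fraction,
                         sigma_scale, seed = seed * 10000L + i)
      xu <- zero_fill_recon(xt, m)
      xr <- if (is.null(gen)) xu else pmin(pmax(generator_forward(gen, xu), 0), 1)
      c(psnr(xt, xr), ssim(xt, xr), mse(xt, xr), psnr(xt, xu))
    }, numeric(4))
    data.frame(rate = rate,
               psnr_mean = mean(per[1, ]), psnr_sd = stats::sd(per[1, ]),
               ssim_mean = mean(per[2, ]), ssim_sd = stats::sd(per[2, ]),
               mse_mean = mean(per[3, ]), mse_sd = stats::sd(per[3, ]),
               zf_psnr_mean = mean(per[4, ]))
  })
  do.call(rbind, rows)
}
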