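#' Shift the zero-frequency component to the grid centre
#'
#' Circularly shifts a matrix so the DC term of an unshifted DFT ends up at
#' position `(floor(H/2)+1, floor(W/2)+1)`. `ifftshift()` undoes the shift
#' (the two differ for odd dimensions).
#'
#' @param m A matrix.
#' @return The shifted matrix.
#' @keywords internal
fftshift <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq_len(ceiling(h / 2)) + floor(h / 2), seq_len(floor(h / 2))),
    c(seq_len(ceiling(w / 2)) + floor(w / 2), seq_len(floor(w / 2))), drop = FALSE]
}

#' @rdname fftshift
#' @keywords internal
ifftshift <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(seq_len(floor(h / 2)) + ceiling(h / 2), seq_len(ceiling(h / 2))),
    c(seq_len(floor(w / 2)) + ceiling(w / 2), seq_len(ceiling(w / 2))), drop = FALSE]
}

#' Unitary 2-D Fourier transform of an image
#'
#' Computes the orthonormal (1/sqrt(N) each way) 2-D discrete Fourier
#' transform of a magnitude image and returns the spectrum with the DC
#' component at the grid centre. With this scaling Parseval's identity holds
#' exactly: `sum(Mod(k)^2) == sum(image^2)`, so loss terms defined in the
#' image and frequency domains live on the same scale.
#'
#' @param image Real (or complex) H x W matrix, H, W >= 2, all values finite.
#' @return Complex H x W matrix, DC-centred.
#' @seealso [inverse_fft()], [zero_fill_recon()]
#' @export
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' k <- forward_fft(x)
#' all.equal(sum(Mod(k)^2), sum(x^2))
forward_fft <- function(image) {
  if (!is.matrix(image)) stop("forward_fft: 'image' must be a matrix")
  if (nrow(image) < 2 || ncol(image) < 2) stop("forward_fft: need at least 2x2")
  if (!all(is.finite(Mod(image)))) stop("forward_fft: non-finite values in input")
  fftshift(stats::fft(image) / sqrt(length(image)))
}

#' Unitary inverse 2-D Fourier transform
#'
#' Exact inverse of [forward_fft()]. The result is complex in general; take
#' `Mod()` for a magnitude image.
#'
#' @param kspace Complex H x W matrix, DC-centred.
#' @return Complex H x W matrix in the image domain.
#' @export
inverse_fft <- function(kspace) {
  if (!is.matrix(kspace)) stop("inverse_fft: 'kspace' must be a matrix")
  if (!all(is.finite(Mod(kspace)))) stop("inverse_fft: non-finite values in input")
  stats::fft(ifftshift(kspace), inverse = TRUE) / sqrt(length(kspace))
}

#' Variable-density random undersampling mask
#'
#' Draws a binary Cartesian k-space sampling pattern for retrospective
#' compressed-sensing simulation. A centred square holding approximately
#' `center_fraction` of all grid points (the high-energy low frequencies) is
#' always fully sampled; the remaining points are drawn without replacement
#' with probabilities proportional to an isotropic 2-D Gaussian density
#' centred on DC with standard deviation `sigma_scale * min(H, W)`, so the
#' sampling density decays with distance from the k-space centre. The total
#' number of sampled points equals `round(target_rate * H * W)` exactly.
#'
#' @param height,width Grid size (positive integers).
#' @param target_rate Fraction of k-space points to sample, in (0, 1].
#' @param center_fraction Fraction of grid points inside the always-sampled
#'   central square. Default 0.04.
#' @param sigma_scale Gaussian standard deviation as a fraction of
#'   `min(height, width)`. Default 0.25.
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @return An object of class `sampling_mask`: list with `pattern` (binary
#'   H x W matrix), `center` (logical H x W matrix flagging the forced
#'   region), and the generating parameters.
#' @export
#' @examples
#' m <- generate_mask(64, 64, target_rate = 0.2, seed = 1)
#' sum(m$pattern) == round(0.2 * 64 * 64)
generate_mask <- function(height, width, target_rate,
                          center_fraction = 0.04, sigma_scale = 0.25,
                          seed = 1L) {
  if (target_rate <= 0 || target_rate > 1)
    stop("generate_mask: target_rate must be in (0, 1]")
  if (center_fraction < 0 || center_fraction > target_rate)
    stop("generate_mask: need 0 <= center_fraction <= target_rate")
  n <- height * width
  n_keep <- round(target_rate * n)

  center <- center_square(height, width, center_fraction)
  n_center <- sum(center)
  if (n_keep < n_center)
    stop("generate_mask: target_rate ", target_rate,
         " is below the ", n_center, "/", n,
         " points the forced central region requires")

  pattern <- matrix(0, height, width)
  pattern[center] <- 1
  n_extra <- n_keep - n_center
  if (n_extra > 0) {
    w <- gaussian_density_grid(height, width, sigma_scale)
    cand <- which(!center)
    local_seed(seed, {
      # weighted sampling without replacement via exponential keys
      # (Efraimidis-Spirakis): take the n_extra smallest rexp(1)/w_i
      keys <- stats::rexp(length(cand)) / w[cand]
      pick <- cand[order(keys)[seq_len(n_extra)]]
    })
    pattern[pick] <- 1
  }
  structure(list(pattern = pattern, center = center,
                 target_rate = target_rate, center_fraction = center_fraction,
                 sigma_scale = sigma_scale, seed = as.integer(seed)),
            class = "sampling_mask")
}

# centred square whose area is the nearest achievable to frac * H * W
center_square <- function(height, width, frac) {
  side <- min(round(sqrt(frac * height * width)), height, width)
  ctr <- matrix(FALSE, height, width)
  if (side > 0) {
    rows <- floor((height - side) / 2) + seq_len(side)
    cols <- floor((width - side) / 2) + seq_len(side)
    ctr[rows, cols] <- TRUE
  }
  ctr
}

# isotropic Gaussian density over the DC-centred grid
gaussian_density_grid <- function(height, width, sigma_scale) {
  sd <- sigma_scale * min(height, width)
  dh <- seq_len(height) - (floor(height / 2) + 1)
  dw <- seq_len(width) - (floor(width / 2) + 1)
  r2 <- outer(dh^2, dw^2, "+")
  exp(-r2 / (2 * sd^2))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Apply a sampling mask to k-space data
#'
#' Element-wise product of a spectrum with a binary mask: unsampled k-space
#' points become exactly zero (the zero-filling step of retrospective
#' undersampling).
#'
#' @param kspace Complex H x W matrix.
#' @param mask A `sampling_mask` or a binary H x W matrix.
#' @return Complex H x W matrix with unsampled entries zero.
#' @export
undersample <- function(kspace, mask) {
  p <- mask_pattern(mask)
  if (!all(dim(kspace) == dim(p)))
    stop("undersample: k-space is ", paste(dim(kspace), collapse = "x"),
         " but mask is ", paste(dim(p), collapse = "x"))
  kspace * p
}

mask_pattern <- function(mask) {
  if (inherits(mask, "sampling_mask")) mask$pattern
  else if (is.matrix(mask)) mask * 1
  else stop("expected a 'sampling_mask' or a binary matrix")
}

#' Zero-filled reconstruction of an undersampled image
#'
#' The degraded baseline a reconstruction network starts from: transform the
#' image to k-space, discard unsampled points, transform back and take the
#' magnitude. Exhibits the aliasing/blur characteristic of sub-Nyquist
#' variable-density sampling.
#'
#' @param image Real H x W matrix (normalized ground truth).
#' @param mask A `sampling_mask` or binary matrix of the same size.
#' @return Real H x W matrix, the zero-filled magnitude image.
#' @export
zero_fill_recon <- function(image, mask) {
  Mod(inverse_fft(undersample(forward_fft(image), mask)))
}

#' Serialize a sampling mask to a plain-text JSON file
#'
#' @param mask A `sampling_mask`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  obj <- list(height = nrow(mask$pattern), width = ncol(mask$pattern),
              target_rate = mask$target_rate,
              center_fraction = mask$center_fraction,
              sigma_scale = mask$sigma_scale, seed = mask$seed,
              pattern = as.integer(mask$pattern))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sampling mask written by [write_mask()]
#'
#' @param path File path.
#' @return A `sampling_mask`.
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pattern <- matrix(as.numeric(obj$pattern), obj$height, obj$width)
  structure(list(pattern = pattern,
                 center = center_square(obj$height, obj$width, obj$center_fraction),
                 target_rate = obj$target_rate,
                 center_fraction = obj$center_fraction,
                 sigma_scale = obj$sigma_scale, seed = as.integer(obj$seed)),
            class = "sampling_mask")
}

#' Export a mask (or any [0,1] image) as an 8-bit PNG for visualization
#'
#' @param x A `sampling_mask` or a numeric matrix in \[0, 1\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_png_image <- function(x, path) {
  m <- if (inherits(x, "sampling_mask")) x$pattern else x
  m <- pmin(pmax(m, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}
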