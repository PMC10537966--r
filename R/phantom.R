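#' Specification for a synthetic brain-like phantom
#'
#' Describes a 2-D magnitude image that emulates what the reconstruction
#' networks assume of a T1-weighted brain slice: piecewise-smooth tissue
#' regions bounded by sharp edges, an outer "skull" ring, nested tissue
#' ellipses at distinct intensities, a bright compact central structure, and
#' optional additive Gaussian noise, all clipped to \[0, 1\].
#'
#' @param size Length-2 integer vector `(H, W)`. Default `c(64, 64)`.
#' @param n_ellipses Number of nested tissue ellipses inside the skull
#'   (>= 3). Default 5.
#' @param intensity_levels Tissue intensities in \[0, 1\], recycled over
#'   ellipses. Default `c(0.9, 0.35, 0.55, 0.75, 0.95)`.
#' @param noise_std Standard deviation of additive Gaussian noise. Default 0.
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L), n_ellipses = 5L,
                         intensity_levels = c(0.9, 0.35, 0.55, 0.75, 0.95),
                         noise_std = 0, seed = 1L) {
  if (n_ellipses < 3) stop("phantom_spec: n_ellipses must be >= 3")
  if (any(intensity_levels < 0 | intensity_levels > 1))
    stop("phantom_spec: intensity_levels must lie in [0, 1]")
  if (noise_std < 0) stop("phantom_spec: noise_std must be nonnegative")
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 intensity_levels = intensity_levels, noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic brain-like phantom image
#'
#' Renders the spec: an elliptical "skull" ring at the first intensity, a
#' darker brain interior, randomly placed and oriented nested tissue
#' ellipses at the remaining intensities, and a bright compact structure
#' near the centre (emulating high-signal deep grey matter), plus optional
#' Gaussian noise. The result is clipped to \[0, 1\]. Zero-filled
#' undersampled versions of these images show the aliasing and blur that
#' reconstruction should measurably remove.
#'
#' @param spec A [phantom_spec()].
#' @return Real H x W matrix in \[0, 1\].
#' @export
#' @examples
#' x <- make_phantom(phantom_spec(seed = 7))
#' range(x)
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$size[1]; w <- spec$size[2]
  levels <- rep_len(spec$intensity_levels, spec$n_ellipses)
  if (all(levels == 0) && spec$noise_std == 0) return(matrix(0, h, w))

  # normalized coordinates in [-1, 1]
  yy <- matrix(seq(-1, 1, length.out = h), h, w)
  xx <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  img <- matrix(0, h, w)

  in_ellipse <- function(cx, cy, a, b, theta) {
    xr <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
    yr <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
    (xr / a)^2 + (yr / b)^2 <= 1
  }

  local_seed(spec$seed, {
    # skull ring: outer ellipse at levels[1], interior dropped to a dark base
    img[in_ellipse(0, 0, 0.92, 0.95, 0)] <- levels[1]
    interior <- in_ellipse(0, 0, 0.82, 0.85, 0)
    img[interior] <- 0.2 * levels[1]
    # nested tissue ellipses
    for (i in seq(2, spec$n_ellipses)) {
      cx <- stats::runif(1, -0.35, 0.35)
      cy <- stats::runif(1, -0.35, 0.35)
      a <- stats::runif(1, 0.15, 0.45)
      b <- stats::runif(1, 0.15, 0.45)
      th <- stats::runif(1, 0, pi)
      sel <- in_ellipse(cx, cy, a, b, th) & interior
      img[sel] <- levels[i]
    }
    # bright compact central structure
    img[in_ellipse(0, 0.05, 0.12, 0.16, 0) & interior] <- max(levels)
    if (spec$noise_std > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_std), h, w)
  })
  pmin(pmax(img, 0), 1)
}

#' Generate a list of phantoms with varying geometry
#'
#' Convenience wrapper producing `n` phantoms that share a base spec but use
#' per-image seeds `seed, seed + 1, ...`, so each image has different tissue
#' geometry.
#'
#' @param n Number of phantoms.
#' @param spec Base [phantom_spec()]; its `seed` is the offset origin.
#' @return List of H x W matrices.
#' @export
make_phantom_set <- function(n, spec = phantom_spec()) {
  lapply(seq_len(n) - 1L, function(i) {
    s <- spec; s$seed <- spec$seed + i
    make_phantom(s)
  })
}

#' Stochastic four-way augmentation of a training image
#'
#' Applies exactly one of four transforms, each chosen with probability 1/4:
#' flip up-down, integer translation (uniform shift up to 10\% of each
#' dimension, zero padding), horizontal mirror, or 90-degree rotation.
#' Intended to be applied online, per sample, inside the training loop.
#'
#' @param image Real H x W matrix.
#' @param seed Integer seed controlling both the choice and the translation
#'   offsets, or `NULL` to use the current RNG stream.
#' @return Transformed H x W matrix (same shape).
#' @export
augment <- function(image, seed = NULL) {
  if (!is.matrix(image)) stop("augment: 'image' must be a matrix")
  run <- function() {
    choice <- sample.int(4L, 1L)
    switch(choice,
           flip_ud(image),
           translate(image,
                     sample(seq(-round(0.1 * nrow(image)), round(0.1 * nrow(image))), 1),
                     sample(seq(-round(0.1 * ncol(image)), round(0.1 * ncol(image))), 1)),
           mirror_lr(image),
           rot90(image))
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' Elementary image transforms
#'
#' `flip_ud()` reverses rows, `mirror_lr()` reverses columns, `rot90()`
#' rotates counter-clockwise by 90 degrees, and `translate()` shifts by an
#' integer offset with zero padding.
#'
#' @param image Real matrix.
#' @param dy,dx Integer row/column shifts.
#' @return Transformed matrix.
#' @export
flip_ud <- function(image) image[rev(seq_len(nrow(image))), , drop = FALSE]

#' @rdname flip_ud
#' @export
mirror_lr <- function(image) image[, rev(seq_len(ncol(image))), drop = FALSE]

#' @rdname flip_ud
#' @export
rot90 <- function(image) t(image)[rev(seq_len(ncol(image))), , drop = FALSE]

#' @rdname flip_ud
#' @export
translate <- function(image, dy, dx) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Random 70/10/20 train/validation/test split
#'
#' Shuffles the item identifiers with a seeded RNG, then slices contiguously
#' into 70\% training, 10\% validation, 20\% test. Validation and test sizes
#' are `round(0.1 n)` and `round(0.2 n)`; the remainder goes to training.
#'
#' @param item_ids Vector of at least 10 unique identifiers.
#' @param seed Integer seed.
#' @return An object of class `dataset_split` with elements `train`, `val`,
#'   `test`, `fractions`, `seed`.
#' @export
#' @examples
#' s <- split_dataset(1:100, seed = 1)
#' lengths(s[c("train", "val", "test")])
split_dataset <- function(item_ids, seed = 1L) {
  n <- length(item_ids)
  if (n < 10) stop("split_dataset: need at least 10 items, got ", n)
  n_val <- round(0.1 * n)
  n_test <- round(0.2 * n)
  n_train <- n - n_val - n_test
  local_seed(seed, perm <- sample(item_ids))
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[n_train + n_val + seq_len(n_test)],
                 fractions = c(train = 0.7, val = 0.1, test = 0.2),
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Write / read a phantom set as plain-text JSON
#'
#' Stores the images (column-major flattened) together with the generating
#' spec, so a saved dataset is self-describing.
#'
#' @param images List of H x W matrices.
#' @param spec The generating [phantom_spec()] (stored as metadata).
#' @param path File path.
#' @return `path` (write) or a list with `images` and `spec` (read).
#' @export
write_phantom_set <- function(images, spec, path) {
  obj <- list(n = length(images),
              height = nrow(images[[1]]), width = ncol(images[[1]]),
              spec = unclass(spec),
              images = lapply(images, as.numeric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_set
#' @export
read_phantom_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  imgs <- obj$images
  images <- lapply(seq_len(obj$n), function(i) {
    v <- if (is.matrix(imgs)) imgs[i, ] else imgs[[i]]
    matrix(as.numeric(v), obj$height, obj$width)
  })
  list(images = images, spec = obj$spec)
}
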