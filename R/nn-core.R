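# Minimal feed-forward conv-net engine with explicit reverse-mode gradients.
#
# Conventions:
#   * feature tensors are numeric arrays with dim (H, W, C, N)
#   * every layer is an environment of class c(<type>, "nn_layer") holding
#     parameter environments in $params, child layers in $layers, and
#     closures $forward(x, train) / $backward(gy) that cache what the
#     backward pass needs
#   * parameter environments carry $value, $grad and Adam state
#
# Heavy convolutions run through RcppArmadillo (src/conv2d.cpp); everything
# else is vectorized R.

nn_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- value * 0  # same shape and attributes as the value
  class(e) <- "nn_param"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  list2env(list(...), e)
  e$params <- e$params %||% list()
  e$layers <- e$layers %||% list()
  class(e) <- c(type, "nn_layer")
  e
}

#' Collect the trainable parameters of a network
#'
#' Walks a layer tree and returns every parameter environment. Used by the
#' optimizer and by [n_params()].
#'
#' @param layer A layer or network object.
#' @return List of parameter environments.
#' @export
collect_params <- function(layer) {
  out <- layer$params
  for (ch in layer$layers) out <- c(out, collect_params(ch))
  out
}

#' Number of trainable scalars in a network
#'
#' @param layer A layer or network object.
#' @return Integer count of trainable scalar parameters.
#' @export
n_params <- function(layer) {
  sum(vapply(collect_params(layer), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(layer) {
  for (p in collect_params(layer)) p$grad[] <- 0
  invisible(layer)
}

# He-normal initialization for conv kernels
he_init <- function(dim, fan_in) array(stats::rnorm(prod(dim), 0, sqrt(2 / fan_in)), dim)

# ---- convolution -----------------------------------------------------------

nn_conv <- function(c_in, c_out, k = 3L, stride = 1L, dilation = 1L,
                    pad = NULL, init = c("he", "zero")) {
  init <- match.arg(init)
  if (is.null(pad)) pad <- (dilation * (k - 1L)) %/% 2L
  wdim <- c(k, k, c_in, c_out)
  w <- nn_param(if (init == "zero") array(0, wdim) else he_init(wdim, k * k * c_in))
  b <- nn_param(numeric(c_out))
  self <- new_layer("conv", w = w, b = b, stride = as.integer(stride),
                    dilation = as.integer(dilation), pad = as.integer(pad),
                    params = list())
  self$params <- list(w = w, b = b)
  self$forward <- function(x, train = FALSE) {
    self$x <- x
    conv2d_fwd_cpp(x, w$value, b$value, self$stride, self$dilation, self$pad)
  }
  self$backward <- function(gy) {
    g <- conv2d_bwd_cpp(self$x, w$value, gy, self$stride, self$dilation, self$pad)
    w$grad <- w$grad + g$gw
    b$grad <- b$grad + g$gb
    g$gx
  }
  self
}

# ---- batch normalization ---------------------------------------------------

nn_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  gamma <- nn_param(rep(1, channels))
  beta <- nn_param(rep(0, channels))
  self <- new_layer("batchnorm", gamma = gamma, beta = beta,
                    running_mean = rep(0, channels), running_var = rep(1, channels),
                    momentum = momentum, eps = eps)
  self$params <- list(gamma = gamma, beta = beta)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N, C)
    if (train) {
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      self$running_mean <- (1 - momentum) * self$running_mean + momentum * mu
      self$running_var <- (1 - momentum) * self$running_var + momentum * v
    } else {
      mu <- self$running_mean
      v <- self$running_var
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
    self$xhat <- xhat; self$invstd <- invstd; self$dims <- d; self$train <- train
    ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
    aperm(array(ym, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  }
  self$backward <- function(gy) {
    d <- self$dims
    gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = d[3])
    gamma$grad <- gamma$grad + colSums(gym * self$xhat)
    beta$grad <- beta$grad + colSums(gym)
    if (self$train) {
      m <- nrow(gym)
      t1 <- sweep(gym, 2, colMeans(gym))
      t2 <- sweep(self$xhat, 2, colMeans(gym * self$xhat), "*")
      gxm <- sweep(t1 - t2, 2, gamma$value * self$invstd, "*")
    } else {
      gxm <- sweep(gym, 2, gamma$value * self$invstd, "*")
    }
    aperm(array(gxm, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  }
  self
}

# ---- activations -----------------------------------------------------------

nn_relu <- function() {
  self <- new_layer("relu")
  self$forward <- function(x, train = FALSE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(gy) gy * self$mask
  self
}

nn_leaky_relu <- function(slope = 0.2) {
  self <- new_layer("leaky_relu", slope = slope)
  self$forward <- function(x, train = FALSE) {
    self$mask <- x > 0
    ifelse(self$mask, x, slope * x)
  }
  self$backward <- function(gy) ifelse(self$mask, gy, slope * gy)
  self
}

nn_sigmoid <- function() {
  self <- new_layer("sigmoid")
  self$forward <- function(x, train = FALSE) {
    y <- 1 / (1 + exp(-x))
    self$y <- y
    y
  }
  self$backward <- function(gy) gy * self$y * (1 - self$y)
  self
}

# ---- pooling ---------------------------------------------------------------

# 2x2 max pooling, even spatial dims required
nn_maxpool2 <- function() {
  self <- new_layer("maxpool2")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
      stop("maxpool2: spatial dims must be even, got ", d[1], "x", d[2])
    cand <- list(
      x[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE],
      x[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE],
      x[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE],
      x[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE])
    best <- cand[[1]]
    arg <- array(1L, dim(best))
    for (k in 2:4) {
      upd <- cand[[k]] > best
      arg[upd] <- k
      best[upd] <- cand[[k]][upd]
    }
    self$arg <- arg; self$dims <- d
    best
  }
  self$backward <- function(gy) {
    d <- self$dims
    gx <- array(0, d)
    rows <- list(seq(1, d[1], 2), seq(2, d[1], 2), seq(1, d[1], 2), seq(2, d[1], 2))
    cols <- list(seq(1, d[2], 2), seq(1, d[2], 2), seq(2, d[2], 2), seq(2, d[2], 2))
    for (k in 1:4) {
      sel <- self$arg == k
      sub <- array(0, dim(gy))
      sub[sel] <- gy[sel]
      gx[rows[[k]], cols[[k]], , ] <- gx[rows[[k]], cols[[k]], , , drop = FALSE] + sub
    }
    gx
  }
  self
}

# global average + global max pooling over (H, W): returns (C, N) matrices
global_avg_pool <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3] * d[4])) |> matrix(d[3], d[4])
}

global_max_pool <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(xm), ties.method = "first")
  list(value = matrix(xm[cbind(idx, seq_along(idx))], d[3], d[4]),
       argmax = idx)
}

# ---- bilinear interpolation ------------------------------------------------

# interpolation matrix mapping a length-n_in axis to n_out samples
# (align-corners linear interpolation; exact on constants and on linear ramps)
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1) { A[, 1] <- 1; return(A) }
  pos <- if (n_out == 1) 1 else seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1)
  frac <- pos - lo
  A[cbind(seq_len(n_out), lo)] <- 1 - frac
  A[cbind(seq_len(n_out), lo + 1)] <- A[cbind(seq_len(n_out), lo + 1)] + frac
  A
}

# apply y[,,c,n] = Ah %*% x[,,c,n] %*% t(Aw) for all channels/samples
apply_interp <- function(x, Ah, Aw) {
  d <- dim(x)
  y <- Ah %*% matrix(x, d[1], prod(d[-1]))           # (Ho, W*C*N)
  y <- array(y, c(nrow(Ah), d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Aw %*% matrix(y, d[2], prod(c(nrow(Ah), d[3], d[4])))
  aperm(array(y, c(nrow(Aw), nrow(Ah), d[3], d[4])), c(2, 1, 3, 4))
}

#' Bilinear resampling of a feature tensor
#'
#' Separable linear interpolation (align-corners convention) used for
#' decoder upsampling and multi-scale fusion. Exact on spatially constant
#' maps and on linear ramps.
#'
#' @param x Array (H, W, C, N) or a matrix.
#' @param out_h,out_w Target spatial size.
#' @return Resampled array (or matrix if a matrix was given).
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(dim(x), 1, 1))
  y <- apply_interp(x, interp_matrix(out_h, dim(x)[1]), interp_matrix(out_w, dim(x)[2]))
  if (was_mat) y[, , 1, 1] else y
}

nn_upsample <- function(out_h, out_w) {
  self <- new_layer("upsample", out_h = out_h, out_w = out_w)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$Ah <- interp_matrix(out_h, d[1])
    self$Aw <- interp_matrix(out_w, d[2])
    apply_interp(x, self$Ah, self$Aw)
  }
  self$backward <- function(gy) apply_interp(gy, t(self$Ah), t(self$Aw))
  self
}

# ---- dense -----------------------------------------------------------------

# fully connected layer on (F, N) matrices; `share` reuses another dense
# layer's parameter environments (shared weights, separate caches)
nn_dense <- function(n_in, n_out, init = c("he", "zero"), share = NULL) {
  init <- match.arg(init)
  if (!is.null(share)) {
    w <- share$params$w
    b <- share$params$b
  } else {
    w <- nn_param(if (init == "zero") matrix(0, n_in, n_out)
                  else matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out))
    b <- nn_param(numeric(n_out))
  }
  self <- new_layer("dense", w = w, b = b)
  self$params <- list(w = w, b = b)
  self$forward <- function(x, train = FALSE) {
    self$x <- x
    t(w$value) %*% x + b$value
  }
  self$backward <- function(gy) {
    w$grad <- w$grad + self$x %*% t(gy)
    b$grad <- b$grad + rowSums(gy)
    w$value %*% gy
  }
  self
}

# ---- sequential container --------------------------------------------------

nn_sequential <- function(...) {
  self <- new_layer("sequential", layers = list(...))
  self$forward <- function(x, train = FALSE) {
    for (l in self$layers) x <- l$forward(x, train)
    x
  }
  self$backward <- function(gy) {
    for (l in rev(self$layers)) gy <- l$backward(gy)
    gy
  }
  self
}

# ---- Adam optimizer --------------------------------------------------------

#' Adam optimizer over a parameter list
#'
#' Standard Adam with bias correction. `opt$step(lr)` applies one update
#' using the gradients currently accumulated in the parameters and then
#' leaves the gradients untouched (call [zero_grads()] between steps).
#'
#' @param params List of parameter environments (from [collect_params()]).
#' @param beta1,beta2 Exponential decay rates for the first and second
#'   moment estimates. Defaults 0.9 and 0.999.
#' @param eps Numerical stabilizer. Default 1e-8.
#' @return An optimizer environment with a `$step(lr)` method.
#' @export
adam_optimizer <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    p$m <- p$value * 0
    p$v <- p$m
  }
  self <- new.env(parent = emptyenv())
  self$t <- 0L
  self$step <- function(lr) {
    self$t <- self$t + 1L
    bc1 <- 1 - beta1^self$t
    bc2 <- 1 - beta2^self$t
    for (p in params) {
      p$m <- beta1 * p$m + (1 - beta1) * p$grad
      p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
      p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
    }
    invisible(self)
  }
  self
}

# batchify a list of matrices into an (H, W, 1, N) tensor
as_batch <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images), c(h, w, 1, length(images)))
}

batch_to_list <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(n) x[, , 1, n])
}
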