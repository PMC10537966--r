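#' Default run configuration
#'
#' A fully resolved, nested configuration covering every module: phantom
#' generation, mask parameters, generator and discriminator architecture,
#' loss weights, and the training schedule. Round-trips unchanged through
#' YAML serialization, and every run directory receives the exact resolved
#' configuration used.
#'
#' @param seed Global seed.
#' @return A nested `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(n = 40L, height = 64L, width = 64L, n_ellipses = 5L,
                   noise_std = 0.01),
    mask = list(rate = 0.2, center_fraction = 0.04, sigma_scale = 0.25),
    generator = unclass(generator_config()),
    discriminator = unclass(discriminator_config()),
    weights = unclass(loss_weights()),
    train = unclass(train_config())
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config` (nested list).
#' @param path YAML file path.
#' @return `path` (save) or the configuration (load).
#' @export
save_config <- function(config, path) {
  cfg <- rapply(unclass(config), function(x)
    if (length(x) == 1 && is.numeric(x) && is.infinite(x)) ".inf" else x,
    how = "replace")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- rapply(cfg, function(x)
    if (identical(x, ".inf")) Inf else x, how = "replace")
  structure(cfg, class = "run_config")
}

# materialize module configs from a run_config
config_parts <- function(config) {
  list(
    gen_cfg = do.call(generator_config, config$generator),
    disc_cfg = do.call(discriminator_config, config$discriminator),
    weights = do.call(loss_weights, config$weights),
    train_cfg = do.call(train_config, config$train)
  )
}

#' Execute a full training run from a configuration
#'
#' Generates (or accepts) the phantom dataset, trains the GAN, and writes
#' the resolved configuration, the per-epoch history (CSV), a JSONL log,
#' and the best checkpoint into `out_dir`.
#'
#' @param config A `run_config` from [default_config()] / [load_config()].
#' @param out_dir Output run directory (created if missing).
#' @param images Optional list of images; when `NULL`, phantoms are
#'   generated from `config$phantom`.
#' @param verbose Print progress.
#' @return The `csmri_fit`, invisibly.
#' @export
train_run <- function(config, out_dir, images = NULL, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(images)) {
    ph <- config$phantom
    images <- make_phantom_set(ph$n, phantom_spec(
      size = c(ph$height, ph$width), n_ellipses = ph$n_ellipses,
      noise_std = ph$noise_std, seed = config$seed))
  }
  parts <- config_parts(config)
  parts$train_cfg$rate <- config$mask$rate
  parts$train_cfg$center_fraction <- config$mask$center_fraction
  parts$train_cfg$sigma_scale <- config$mask$sigma_scale
  parts$train_cfg$seed <- config$seed
  save_config(config, file.path(out_dir, "config.yaml"))
  fit <- train(images, parts$gen_cfg, parts$disc_cfg, parts$weights,
               parts$train_cfg, verbose = verbose)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  writeLines(vapply(seq_len(nrow(fit$history)), function(i)
    jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE, digits = NA),
    character(1)), log_path)
  save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  invisible(fit)
}

#' Ablation study over the architectural components
#'
#' Trains the four model variants — the full model and single ablations of
#' the dilated-residual rates, the channel attention, and the multi-scale
#' fusion — with identical seeds, data, and evaluation masks, then scores
#' each on the test split at the requested sampling rates.
#'
#' @param images List of ground-truth images.
#' @param config A `run_config`; its `generator` entry is the full model.
#' @param rates Sampling rates to evaluate. Default `c(0.1, 0.2)`.
#' @param verbose Print progress.
#' @return List with `table` (data frame: variant x rate metrics) and
#'   `mask_signatures` (per-variant checksums of the evaluation masks —
#'   identical across variants by construction).
#' @export
run_ablation <- function(images, config = default_config(),
                         rates = c(0.1, 0.2), verbose = FALSE) {
  variants <- list(
    full = list(),
    no_dilation = list(use_dilation = FALSE),
    no_cam = list(use_cam = FALSE),
    no_fusion = list(use_fusion = FALSE)
  )
  split <- split_dataset(seq_along(images), seed = config$seed)
  test_images <- images[split$test]
  parts <- config_parts(config)
  parts$train_cfg$seed <- config$seed

  rows <- NULL
  sigs <- list()
  for (v in names(variants)) {
    gcfg <- utils::modifyList(unclass(parts$gen_cfg), variants[[v]])
    gcfg <- do.call(generator_config, gcfg)
    fit <- tryCatch(
      train(images, gcfg, parts$disc_cfg, parts$weights, parts$train_cfg,
            verbose = verbose),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("run_ablation: variant '", v, "' failed: ",
              conditionMessage(fit), "; table is partial")
      next
    }
    ev <- evaluate_model(fit$generator, test_images, rates,
                         seed = config$seed,
                         sigma_scale = config$mask$sigma_scale,
                         center_fraction = config$mask$center_fraction)
    rows <- rbind(rows, cbind(variant = v, ev))
    sigs[[v]] <- eval_mask_signature(test_images, rates, config)
  }
  list(table = rows, mask_signatures = sigs)
}

# checksum of the fixed evaluation masks used by evaluate_model()
eval_mask_signature <- function(images, rates, config) {
  vapply(rates, function(rate) {
    sums <- vapply(seq_along(images), function(i) {
      m <- generate_mask(nrow(images[[i]]), ncol(images[[i]]), rate,
                         config$mask$center_fraction, config$mask$sigma_scale,
                         seed = config$seed * 10000L + i)
      sum(which(m$pattern == 1))
    }, numeric(1))
    paste(sums, collapse = "-")
  }, character(1))
}

#' Extract normalized 2-D slices from a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` volume and returns its slices along the chosen
#' axis, each min-max normalized to \[0, 1\] (a constant slice maps to all
#' zeros). Slice order follows the volume's index order.
#'
#' @param path NIfTI file path.
#' @param axis Slicing axis (1, 2 or 3). Default 3.
#' @param normalize Min-max normalize each slice. Default `TRUE`.
#' @return List of H x W matrices.
#' @export
load_nifti_slices <- function(path, axis = 3L, normalize = TRUE) {
  vol <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("load_nifti_slices: not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  arr <- as.array(vol)
  if (length(dim(arr)) != 3) stop("load_nifti_slices: expected a 3-D volume")
  idx <- lapply(dim(arr), seq_len)
  lapply(seq_len(dim(arr)[axis]), function(s) {
    ix <- idx; ix[[axis]] <- s
    sl <- do.call(`[`, c(list(arr), ix, list(drop = TRUE)))
    sl <- as.matrix(sl)
    if (normalize) {
      rng <- range(sl)
      if (rng[2] > rng[1]) sl <- (sl - rng[1]) / (rng[2] - rng[1])
      else sl <- sl * 0
    }
    sl
  })
}

#' Reconstruct images with a trained generator
#'
#' Undersamples each image with the given mask (retrospective simulation)
#' or accepts already zero-filled inputs, then applies the generator and
#' clamps to \[0, 1\].
#'
#' @param fit A `csmri_fit` (or a bare generator layer).
#' @param images List of H x W matrices.
#' @param mask Optional `sampling_mask` applied to every image; when
#'   `NULL`, the images are taken to be zero-filled inputs already.
#' @return List of reconstructed H x W matrices.
#' @export
reconstruct_images <- function(fit, images, mask = NULL) {
  gen <- if (inherits(fit, "csmri_fit")) fit$generator else fit
  lapply(images, function(im) {
    xu <- if (is.null(mask)) im else zero_fill_recon(im, mask)
    pmin(pmax(generator_forward(gen, xu), 0), 1)
  })
}
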