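#' Conditional GAN training configuration
#'
#' Hyperparameters of the pix2pix-style translator. The defaults are the
#' full-scale study profile: 130 epochs, batch size 128, Adam with learning
#' rate 2e-4, beta1 0.5, beta2 0.999, 128x128 slices, 64 base channels, and
#' an L1 reconstruction weight of 100 (the canonical pix2pix default; the
#' adversarial term uses the least-squares formulation).
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size even minibatch size >= 2 (half positive-case, half
#'   negative-case slices).
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam momentum parameters.
#' @param lambda_l1 weight of the L1 reconstruction loss.
#' @param image_size slice size in pixels; a power of 2, >= 32.
#' @param base_channels channels of the first encoder stage; deeper stages
#'   double up to a cap of `8 * base_channels`.
#' @param brain_fraction_min slice-retention threshold (see
#'   [extract_slices()]).
#' @param seed integer seed governing weight initialization, batch shuffling
#'   and dropout.
#'
#' @return A `gan_config` list.
#' @export
gan_config <- function(epochs = 130L, batch_size = 128L,
                       learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       lambda_l1 = 100, image_size = 128L,
                       base_channels = 64L, brain_fraction_min = 0.01,
                       seed = 1L) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  image_size <- as.integer(image_size)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 2 || batch_size %% 2 != 0) {
    stop("batch_size must be even and >= 2", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("beta1 and beta2 must be in [0, 1)", call. = FALSE)
  }
  if (image_size < 32 || bitwAnd(image_size, image_size - 1L) != 0L) {
    stop("image_size must be a power of 2, >= 32", call. = FALSE)
  }
  structure(
    list(epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         lambda_l1 = lambda_l1, image_size = image_size,
         base_channels = as.integer(base_channels),
         brain_fraction_min = brain_fraction_min, seed = as.integer(seed)),
    class = "gan_config"
  )
}

#' Scaled-down GAN configuration
#'
#' The CPU-scale profile used in examples and package tests: 64x64 slices,
#' 30 epochs, batch size 16, 8 base channels. All other settings follow
#' [gan_config()].
#'
#' @param ... overrides passed to [gan_config()].
#' @return A `gan_config` list.
#' @export
gan_config_small <- function(...) {
  args <- list(epochs = 30L, batch_size = 16L, image_size = 64L,
               base_channels = 8L)
  args <- utils::modifyList(args, list(...))
  do.call(gan_config, args)
}

#' Build an untrained U-Net generator or PatchGAN discriminator
#'
#' The generator is an encoder-decoder with skip connections:
#' `log2(image_size) - 1` stride-2 4x4 convolution stages (channels doubling
#' up to `8 * base_channels`, leaky-ReLU 0.2, instance normalization except
#' on the first stage), mirrored transposed-convolution stages with skip
#' concatenation and dropout 0.5 on the three innermost decoder stages, one
#' input and one output channel, tanh output. The discriminator is a
#' conditional 70x70 PatchGAN over the channel-concatenated (FDG, amyloid)
#' pair: three stride-2 and two stride-1 4x4 convolution stages emitting a 2D
#' map of patch scores (14x14 for 128x128 input).
#'
#' @param config a [gan_config()].
#'
#' @return A `gan_network` object holding the initial weights.
#' @export
build_generator <- function(config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  w <- gan_init_cpp(config$image_size, config$base_channels, config$seed, "gen")
  structure(list(type = "generator", weights = w, config = config),
            class = "gan_network")
}

#' @rdname build_generator
#' @export
build_discriminator <- function(config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  w <- gan_init_cpp(config$image_size, config$base_channels, config$seed, "disc")
  structure(list(type = "discriminator", weights = w, config = config),
            class = "gan_network")
}

#' @export
print.gan_network <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<gan_network> %s, %d parameter tensors (%s parameters)\n",
              x$type, length(x$weights), format(np, big.mark = ",")))
  invisible(x)
}

#' Apply a generator to 2D slices
#'
#' Runs slices (already scaled to the GAN range) through a generator network;
#' dropout is inactive, so the map is deterministic.
#'
#' @param net a generator `gan_network` or `trained_generator`.
#' @param slices matrix with one flattened `image_size^2` slice per column,
#'   or a single 2D slice.
#'
#' @return Same shape as the input, values in `[-1, 1]`.
#' @export
generator_forward <- function(net, slices) {
  cfg <- net$config
  w <- net$weights
  single <- is.matrix(slices) && all(dim(slices) == cfg$image_size)
  x <- if (single) matrix(as.numeric(slices), ncol = 1) else slices
  if (nrow(x) != cfg$image_size^2) {
    stop("slices do not match the generator image size", call. = FALSE)
  }
  out <- gan_generator_forward_cpp(w, x, cfg$image_size, cfg$base_channels)
  if (single) matrix(out, cfg$image_size, cfg$image_size) else out
}

#' Apply a discriminator to (FDG, amyloid) slice pairs
#'
#' @param net a discriminator `gan_network`.
#' @param fdg,amyloid matrices with one flattened slice per column (or single
#'   2D slices); both modalities in GAN range.
#'
#' @return A list with `scores` (patch-score matrix, one column per pair) and
#'   the patch map dimensions `hp`, `wp`.
#' @export
discriminator_forward <- function(net, fdg, amyloid) {
  cfg <- net$config
  if (is.matrix(fdg) && nrow(fdg) == ncol(fdg)) {
    S <- nrow(fdg)
    fdg <- matrix(as.numeric(fdg), ncol = 1)
    amyloid <- matrix(as.numeric(amyloid), ncol = 1)
  } else {
    S <- as.integer(sqrt(nrow(fdg)))
  }
  gan_disc_forward_cpp(net$weights, fdg, amyloid, S, cfg$base_channels)
}

#' Balanced minibatches over slice samples
#'
#' Emits one epoch's sequence of minibatches in which every batch holds
#' exactly `batch_size / 2` slices from positive cases and `batch_size / 2`
#' from negative cases. Within-class order is shuffled by the seeded RNG; the
#' majority class is exhausted each epoch and the minority class is
#' oversampled with replacement to match.
#'
#' @param samples list of slice samples (from [extract_slices()]), each with
#'   a `status` field.
#' @param batch_size even batch size.
#' @param seed integer seed.
#'
#' @return List of integer index vectors into `samples`, one per batch.
#' @export
make_balanced_minibatches <- function(samples, batch_size, seed = 1L) {
  if (batch_size < 2 || batch_size %% 2 != 0) {
    stop("batch_size must be even and >= 2", call. = FALSE)
  }
  status <- vapply(samples, function(s) s$status, character(1))
  pos <- which(status == "positive")
  neg <- which(status == "negative")
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present among the slices", call. = FALSE)
  }
  half <- batch_size / 2
  n_batches <- ceiling(max(length(pos), length(neg)) / half)
  need <- n_batches * half
  withr::with_seed(as.integer(seed), {
    draw <- function(idx) {
      out <- sample(idx, length(idx))
      if (length(out) < need) {
        out <- c(out, sample(idx, need - length(out), replace = TRUE))
      }
      out[seq_len(need)]
    }
    p <- draw(pos)
    n <- draw(neg)
  })
  lapply(seq_len(n_batches), function(b) {
    sel <- ((b - 1) * half + 1):(b * half)
    c(p[sel], n[sel])
  })
}

#' Train the FDG-to-amyloid translator
#'
#' Trains the pix2pix-style network on paired 2D slices: per batch, the
#' PatchGAN discriminator is updated on the real pair versus the generated
#' pair (least-squares adversarial loss), then the generator on its
#' adversarial loss plus `lambda_l1` times the mean absolute error to the
#' real amyloid slice. Both networks use Adam with the configured
#' parameters. Slices are scaled into `[-1, 1]` using the window
#' `[0, p99.5]` of the pooled training intensities, which is stored with the
#' model. Fully reproducible given `config$seed`.
#'
#' @param samples list of paired slice samples from [extract_slices()]; every
#'   sample must carry an amyloid target.
#' @param config a [gan_config()].
#'
#' @return A `trained_generator` with fields `weights`, `config`,
#'   `intensity_window` and `loss_history` (tibble with one row per epoch:
#'   mean discriminator loss, generator adversarial loss, generator L1 loss).
#' @export
train_translator <- function(samples, config = gan_config_small()) {
  stopifnot(inherits(config, "gan_config"))
  if (length(samples) == 0) stop("no training samples", call. = FALSE)
  if (any(vapply(samples, function(s) is.null(s$amyloid_slice), logical(1)))) {
    stop("all training samples must include an amyloid target", call. = FALSE)
  }
  S <- config$image_size
  if (!all(dim(samples[[1]]$fdg_slice) == S)) {
    stop("slices must match config$image_size (conform volumes first)",
         call. = FALSE)
  }
  n <- length(samples)
  fdg <- vapply(samples, function(s) as.numeric(s$fdg_slice), numeric(S * S))
  amy <- vapply(samples, function(s) as.numeric(s$amyloid_slice), numeric(S * S))
  window <- c(0, as.numeric(quantile(c(fdg, amy), 0.995)))
  fdg_g <- to_gan_range(fdg, window[1], window[2])
  amy_g <- to_gan_range(amy, window[1], window[2])

  batches <- lapply(seq_len(config$epochs), function(ep) {
    make_balanced_minibatches(samples, config$batch_size,
                              seed = config$seed + ep)
  })
  nb <- length(batches[[1]])
  if (n < config$batch_size) {
    stop("need at least batch_size slices after balancing", call. = FALSE)
  }
  idx <- matrix(unlist(batches), nrow = config$batch_size)

  fit <- gan_train_cpp(fdg_g, amy_g, idx, S, nb, config$base_channels,
                       config$learning_rate, config$beta1, config$beta2,
                       config$lambda_l1, config$seed)
  loss <- tibble::tibble(
    epoch = seq_len(config$epochs),
    disc_loss = fit$loss[, 1],
    gen_adv_loss = fit$loss[, 2],
    gen_l1_loss = fit$loss[, 3]
  )
  structure(
    list(weights = fit$gen, disc_weights = fit$disc, config = config,
         intensity_window = window, loss_history = loss),
    class = "trained_generator"
  )
}

#' @export
print.trained_generator <- function(x, ...) {
  cat(sprintf(
    "<trained_generator> %dx%d slices, %d epochs, final L1 loss %.4f\n",
    x$config$image_size, x$config$image_size, nrow(x$loss_history),
    x$loss_history$gen_l1_loss[nrow(x$loss_history)]
  ))
  invisible(x)
}

#' @describeIn train_translator broom-style per-epoch loss table.
#' @param x,object a `trained_generator`.
#' @param ... unused.
#' @method tidy trained_generator
#' @export
tidy.trained_generator <- function(x, ...) x$loss_history

#' @describeIn train_translator broom-style one-row model summary.
#' @method glance trained_generator
#' @export
glance.trained_generator <- function(x, ...) {
  n <- nrow(x$loss_history)
  tibble::tibble(
    epochs = n, image_size = x$config$image_size,
    base_channels = x$config$base_channels,
    window_lo = x$intensity_window[1], window_hi = x$intensity_window[2],
    final_l1 = x$loss_history$gen_l1_loss[n],
    final_disc = x$loss_history$disc_loss[n]
  )
}

#' Synthesize an amyloid volume from an FDG volume
#'
#' Passes each retained axial slice (brain fraction >=
#' `brain_fraction_min`, per the atlas) through the trained generator
#' independently, inverse-scales via the stored intensity window, and
#' restacks; non-retained slices are zero-filled. Output intensities lie in
#' `[0, intensity_window[2]]`.
#'
#' @param gen a `trained_generator` from [train_translator()].
#' @param fdg FDG [pet_volume()] conformed to the generator grid.
#' @param atlas a [label_atlas()] on the same grid.
#' @param brain_fraction_min slice-retention threshold (defaults to the
#'   trained configuration's value).
#'
#' @return A synthetic amyloid [pet_volume()] of the same shape as `fdg`.
#' @export
synthesize_volume <- function(gen, fdg, atlas,
                              brain_fraction_min = gen$config$brain_fraction_min) {
  stopifnot(inherits(gen, "trained_generator"), inherits(fdg, "pet_volume"))
  S <- gen$config$image_size
  d <- dim(fdg$data)
  if (d[1] != S || d[2] != S) {
    stop("FDG volume does not match the generator image size", call. = FALSE)
  }
  frac <- apply(atlas$labels != 0L, 3, mean)
  keep <- which(frac >= brain_fraction_min)
  out <- array(0, dim = d)
  if (length(keep) > 0) {
    w <- gen$intensity_window
    x <- vapply(keep, function(z) {
      to_gan_range(as.numeric(fdg$data[, , z]), w[1], w[2])
    }, numeric(S * S))
    y <- gan_generator_forward_cpp(gen$weights, x, S, gen$config$base_channels)
    y <- from_gan_range(y, w[1], w[2])
    for (i in seq_along(keep)) out[, , keep[i]] <- y[, i]
  }
  pet_volume(out, spacing = fdg$spacing, subject_id = fdg$subject_id)
}

#' Save or load a trained generator checkpoint
#'
#' Single-file archive (schema version 1) holding the learned parameters, the
#' training configuration and the intensity window.
#'
#' @param gen a `trained_generator`.
#' @param path checkpoint file path.
#'
#' @return `write_generator()`: `path`, invisibly; `read_generator()`: the
#'   restored `trained_generator`.
#' @export
write_generator <- function(gen, path) {
  stopifnot(inherits(gen, "trained_generator"))
  obj <- list(schema = 1L, weights = gen$weights, config = gen$config,
              intensity_window = gen$intensity_window,
              loss_history = gen$loss_history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L)) {
    stop("unsupported checkpoint schema: ", obj$schema, call. = FALSE)
  }
  structure(
    list(weights = obj$weights, disc_weights = NULL, config = obj$config,
         intensity_window = obj$intensity_window,
         loss_history = obj$loss_history),
    class = "trained_generator"
  )
}
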