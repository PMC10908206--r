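# Conditional GAN: generator maps a multi-omic latent vector (optionally plus
# a noise vector) to a 3D volume; discriminator scores (volume, condition)
# pairs. Trained with the least-squares adversarial objective (real target 1,
# fake target 0, generator target 1) under the reference hyperparameter
# defaults: batch 2, generator lr 2.5e-5, discriminator lr 1e-5, MSE loss,
# 1200 epochs, leaky slope 0.2.

#' cGAN configuration
#'
#' Defaults are the reference training settings (batch size 2, generator
#' learning rate 2.5e-5, discriminator learning rate 1e-5, least-squares
#' (MSE) adversarial loss, 1200 epochs, leaky-ReLU slope 0.2). `noise_dim`
#' defaults to 0: generation is a pure deterministic map from the latent
#' vector, matching inference from the patient's 1 x 17 tensor alone.
#'
#' @param volume_shape (depth, height, width); every entry must be a
#'   multiple of 8 (three 2x upsampling stages), e.g. 8x32x32 or 32x128x128.
#' @param cond_dim conditioning dimension (default 17).
#' @param noise_dim optional noise input dimension (default 0).
#' @param batch_size minibatch size (default 2).
#' @param lr_generator generator Adam learning rate (default 2.5e-5).
#' @param lr_discriminator discriminator Adam learning rate (default 1e-5).
#' @param adversarial_loss `"MSE"` (least-squares GAN), `"BCE"` or `"L1"`.
#' @param epochs training epochs (default 1200).
#' @param leaky_slope leaky-ReLU negative slope in (0, 1) (default 0.2).
#' @param base_channels channel width multiplier (default 16).
#' @param instance_noise_sd initial sd of Gaussian noise added to both real
#'   and generated volumes entering the discriminator during training (on
#'   the tanh \[-1, 1\] scale; default 0.1), annealed linearly to zero over
#'   the first three quarters of training. It stops the discriminator from
#'   winning on the texture cue alone early in training (a deterministic
#'   generator cannot reproduce i.i.d. voxel noise), which would collapse
#'   the conditioning gradient.
#' @param d_dropout dropout probability in the discriminator head during
#'   training (default 0.25; dropout is part of the adversarial training
#'   recipe and keeps the discriminator from overpowering the generator).
#' @param rec_weight weight of the paired reconstruction term in the
#'   generator objective, `rec_weight * mean((G(c_i) - v_i)^2)` (default
#'   10). Training pairs each latent with its own volume, so the standard
#'   paired conditional-GAN objective (adversarial + reconstruction) is
#'   used; set to 0 for a purely adversarial generator.
#' @param seed integer seed covering parameter init, shuffling and noise.
#' @return An object of class `cgan_config`.
#' @export
cgan_config <- function(volume_shape,
                        cond_dim = 17L,
                        noise_dim = 0L,
                        batch_size = 2L,
                        lr_generator = 2.5e-5,
                        lr_discriminator = 1e-5,
                        adversarial_loss = c("MSE", "BCE", "L1"),
                        epochs = 1200L,
                        leaky_slope = 0.2,
                        base_channels = 16L,
                        instance_noise_sd = 0.1,
                        d_dropout = 0.25,
                        rec_weight = 10,
                        seed = 1L) {
  adversarial_loss <- match.arg(adversarial_loss)
  if (length(volume_shape) != 3L) stop("cgan_config: `volume_shape` needs 3 entries")
  if (any(volume_shape %% 8L != 0L) || any(volume_shape < 8L)) {
    stop("cgan_config: each volume_shape entry must be a positive multiple of 8 ",
         "(admissible: 8, 16, 24, 32, ... per axis), got ",
         paste(volume_shape, collapse = "x"))
  }
  if (lr_generator <= 0 || lr_discriminator <= 0) {
    stop("cgan_config: learning rates must be > 0")
  }
  if (epochs < 1L) stop("cgan_config: `epochs` must be >= 1")
  if (leaky_slope <= 0 || leaky_slope >= 1) {
    stop("cgan_config: `leaky_slope` must be in (0, 1)")
  }
  if (noise_dim < 0L) stop("cgan_config: `noise_dim` must be >= 0")
  if (instance_noise_sd < 0) stop("cgan_config: `instance_noise_sd` must be >= 0")
  if (d_dropout < 0 || d_dropout >= 1) stop("cgan_config: `d_dropout` must be in [0, 1)")
  if (rec_weight < 0) stop("cgan_config: `rec_weight` must be >= 0")
  structure(list(volume_shape = as.integer(volume_shape),
                 cond_dim = as.integer(cond_dim),
                 noise_dim = as.integer(noise_dim),
                 batch_size = as.integer(batch_size),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 adversarial_loss = adversarial_loss,
                 epochs = as.integer(epochs),
                 leaky_slope = leaky_slope,
                 base_channels = as.integer(base_channels),
                 instance_noise_sd = instance_noise_sd,
                 d_dropout = d_dropout,
                 rec_weight = rec_weight,
                 seed = as.integer(seed)),
            class = "cgan_config")
}

#' Build the generator network
#'
#' Fully-connected projection of the condition (+ optional noise) vector to a
#' coarse (depth/8 x height/8 x width/8) grid, then three 3D transposed-conv
#' upsampling blocks with instance normalization and leaky activations, and a
#' tanh output in \[-1, 1\].
#'
#' @param config a [cgan_config()]. Parameter init consumes the current RNG
#'   stream (seed it for reproducibility; [train_cgan()] does).
#' @return Generator network object.
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "cgan_config"))
  sp <- config$volume_shape
  coarse <- sp %/% 8L
  b <- config$base_channels
  d_in <- config$cond_dim + config$noise_dim
  sl <- config$leaky_slope
  layers <- list(
    nn_dense(d_in, prod(coarse) * 4L * b),
    nn_reshape(c(coarse, 4L * b)),
    nn_lrelu(sl),
    nn_convt3(4L * b, 2L * b),
    nn_instnorm(2L * b),
    nn_lrelu(sl),
    nn_convt3(2L * b, b),
    nn_instnorm(b),
    nn_lrelu(sl),
    # full-resolution stage: non-overlapping 2x2x2 expansion (k = stride)
    # keeps the im2col working set small on a single CPU
    nn_convt3(b, 1L, k = 2L, stride = 2L, pad = 0L, init_sd = 0.05),
    nn_tanh()
  )
  structure(list(layers = layers, config = config, role = "generator"),
            class = "cgan_net")
}

#' Build the discriminator network
#'
#' Three strided 3D conv + leaky-ReLU blocks over the volume, then the
#' condition vector is broadcast-concatenated to the coarsest feature map
#' as `cond_dim` constant channels, followed by a small dense head with a
#' leaky hidden layer (so realness can depend on interactions between image
#' features and the condition) producing one score per item. All hidden
#' activations are leaky with slope `leaky_slope`.
#'
#' @param config a [cgan_config()].
#' @return Discriminator object (class `cgan_disc`) with `$pre` and `$post`
#'   sub-networks around the condition injection point.
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "cgan_config"))
  sp <- config$volume_shape
  b <- config$base_channels
  sl <- config$leaky_slope
  coarse <- sp %/% 8L
  pre <- structure(list(layers = list(
    # non-overlapping 2x2x2 patch convs (k = stride): a hierarchical patch
    # trunk that keeps the single-CPU working set small
    nn_conv3(1L, b, k = 2L, stride = 2L, pad = 0L),
    nn_lrelu(sl),
    nn_conv3(b, 2L * b, k = 2L, stride = 2L, pad = 0L),
    nn_lrelu(sl),
    nn_conv3(2L * b, 4L * b, k = 2L, stride = 2L, pad = 0L),
    nn_lrelu(sl)
  )), class = "cgan_net")
  post <- structure(list(layers = list(
    nn_flatten(),
    nn_dense(prod(coarse) * (4L * b + config$cond_dim), 8L * b),
    nn_lrelu(sl),
    nn_dropout(config$d_dropout),
    nn_dense(8L * b, 1L, init_sd = 0.02)
  )), class = "cgan_net")
  structure(list(pre = pre, post = post, config = config,
                 role = "discriminator"),
            class = "cgan_disc")
}

# Broadcast condition vectors (n x k) over a feature map (d,h,w,C,n) as k
# extra constant channels.
broadcast_concat <- function(feat, conds) {
  fd <- dim(feat)
  svox <- prod(fd[1:3])
  n <- fd[5]
  k <- ncol(conds)
  out <- array(0, c(fd[1:3], fd[4] + k, n))
  out[, , , seq_len(fd[4]), ] <- feat
  cc <- aperm(array(t(conds), c(k, 1, n)), c(2L, 1L, 3L))  # 1 x k x n
  out[, , , fd[4] + seq_len(k), ] <- rep(cc, each = svox)
  out
}

# Discriminator forward: volumes (D,H,W,1,N) + conditions (N x cond_dim) ->
# scores (1 x N).
disc_forward <- function(disc, vols, conds, training = FALSE) {
  if (!all(dim(vols)[1:3] == disc$config$volume_shape)) {
    stop("disc_forward: volume shape ",
         paste(dim(vols)[1:3], collapse = "x"),
         " does not match config ",
         paste(disc$config$volume_shape, collapse = "x"))
  }
  f1 <- nn_forward(disc$pre, vols, training = training)
  mid <- broadcast_concat(f1$y, conds)
  f2 <- nn_forward(disc$post, mid, training = training)
  list(y = f2$y, caches = list(pre = f1$caches, post = f2$caches,
                               n_feat = dim(f1$y)[4]))
}

# Discriminator backward; returns gradient wrt the input volumes (unless
# skipped) and gradients for both sub-networks.
disc_backward <- function(disc, caches, gscore, skip_input_grad = FALSE) {
  b2 <- nn_backward(disc$post, caches$post, gscore)
  gmid <- b2$gx[, , , seq_len(caches$n_feat), , drop = FALSE]
  b1 <- nn_backward(disc$pre, caches$pre, gmid,
                    skip_input_grad = skip_input_grad)
  list(gvol = b1$gx, grads_pre = b1$grads, grads_post = b2$grads)
}

#' Score (volume, condition) pairs with a discriminator
#'
#' @param disc a discriminator from [build_discriminator()].
#' @param volumes list of [volume3d()] (rescaled internally to \[-1, 1\]).
#' @param conds n x cond_dim condition matrix.
#' @return Numeric vector of realness scores, one per pair.
#' @export
discriminator_score <- function(disc, volumes, conds) {
  stopifnot(inherits(disc, "cgan_disc"))
  if (is.null(dim(conds))) conds <- matrix(conds, nrow = 1L)
  vols <- stack_volumes(volumes, disc$config$volume_shape)
  drop(disc_forward(disc, vols, conds)$y)
}

# Generator forward for a matrix of inputs (n x d_in); returns (D,H,W,1,N).
gen_forward <- function(gen, z, training = FALSE) {
  nn_forward(gen, t(z), training = training)
}

# Least-squares adversarial loss and its gradient wrt scores.
lsgan_loss <- function(scores, target) {
  n <- length(scores)
  list(loss = mean((scores - target)^2), grad = 2 * (scores - target) / n)
}

bce_loss <- function(scores, target) {
  # scores are logits; numerically stable binary cross-entropy
  n <- length(scores)
  p <- stats::plogis(scores)
  loss <- mean(ifelse(target > 0.5, -log(pmax(p, 1e-12)), -log(pmax(1 - p, 1e-12))))
  list(loss = loss, grad = (p - target) / n)
}

l1_loss <- function(scores, target) {
  n <- length(scores)
  list(loss = mean(abs(scores - target)), grad = sign(scores - target) / n)
}

adv_loss_fn <- function(kind) {
  switch(kind, MSE = lsgan_loss, BCE = bce_loss, L1 = l1_loss)
}

#' Train a conditional GAN on a cohort
#'
#' Alternating one discriminator step and one generator step per minibatch
#' under the configured adversarial objective, Adam optimizers at the
#' configured learning rates, fully seeded (parameter init, shuffling,
#' noise). Real volumes are rescaled from their declared range to the
#' generator's tanh range \[-1, 1\].
#'
#' @param records list of patient records, each with >= 1 volume and a
#'   latent of length `cond_dim`.
#' @param config a [cgan_config()].
#' @param verbose print loss every `verbose` epochs (0 = silent).
#' @return A `cgan_checkpoint`: generator, discriminator, config, epochs
#'   completed and per-epoch loss history.
#' @export
train_cgan <- function(records, config, verbose = 0L) {
  stopifnot(inherits(config, "cgan_config"))
  cases <- expand_cases(records)
  if (length(cases) == 0L) stop("train_cgan: empty dataset")
  for (r in cases) {
    if (length(r$latent) != config$cond_dim) {
      stop("train_cgan: latent dimension ", length(r$latent),
           " does not match cond_dim ", config$cond_dim)
    }
  }
  sp <- config$volume_shape
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gen <- build_generator(config)
  disc <- build_discriminator(config)
  opt_g <- adam_init(gen)
  opt_d_pre <- adam_init(disc$pre)
  opt_d_post <- adam_init(disc$post)
  lossf <- adv_loss_fn(config$adversarial_loss)
  n <- length(cases)
  reals <- array(0, c(sp, 1L, n))
  for (i in seq_len(n)) reals[, , , 1L, i] <- volume_rescale(cases[[i]]$volumes[[1]])
  conds <- cohort_latents(cases)
  bs <- min(config$batch_size, n)
  g_hist <- numeric(config$epochs)
  d_hist <- numeric(config$epochs)
  rec_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    g_acc <- 0; d_acc <- 0; rec_acc <- 0; nb <- 0L
    # instance noise annealed to zero at 75% of training
    inoise <- config$instance_noise_sd *
      max(0, 1 - (ep - 1) / max(1, 0.75 * config$epochs))
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      m <- length(idx)
      cond_b <- conds[idx, , drop = FALSE]
      z <- if (config$noise_dim > 0) {
        cbind(cond_b, matrix(stats::rnorm(m * config$noise_dim), m))
      } else cond_b
      real_b <- reals[, , , , idx, drop = FALSE]

      # --- discriminator step (generator frozen); real and fake halves are
      # scored in one pass ---
      gfwd <- gen_forward(gen, z, training = TRUE)
      fake_b <- gfwd$y
      both <- array(c(real_b, fake_b), c(sp, 1L, 2L * m))
      if (inoise > 0) {
        both <- both + stats::rnorm(length(both), 0, inoise)
      }
      fb <- disc_forward(disc, both, rbind(cond_b, cond_b), training = TRUE)
      sc <- drop(fb$y)
      lr_ <- lossf(sc[seq_len(m)], 1)
      lf_ <- lossf(sc[m + seq_len(m)], 0)
      d_loss <- 0.5 * (lr_$loss + lf_$loss)
      gd <- disc_backward(disc, fb$caches,
                          matrix(0.5 * c(lr_$grad, lf_$grad), nrow = 1L),
                          skip_input_grad = TRUE)
      st <- adam_step(disc$pre, gd$grads_pre, opt_d_pre,
                      config$lr_discriminator)
      disc$pre <- st$net; opt_d_pre <- st$state
      st <- adam_step(disc$post, gd$grads_post, opt_d_post,
                      config$lr_discriminator)
      disc$post <- st$net; opt_d_post <- st$state

      # --- generator step (discriminator frozen, gradient through D) ---
      # generator parameters were not touched by the D step, so the cached
      # generator forward pass is still valid; instance noise is additive so
      # the generator gradient passes through it unchanged
      fake_n <- fake_b
      if (inoise > 0) {
        fake_n <- fake_n + stats::rnorm(length(fake_n), 0, inoise)
      }
      ff <- disc_forward(disc, fake_n, cond_b, training = TRUE)
      lg_ <- lossf(drop(ff$y), 1)
      back_d <- disc_backward(disc, ff$caches, matrix(lg_$grad, nrow = 1L))
      gvol <- back_d$gvol
      rec_loss <- 0
      if (config$rec_weight > 0) {
        resid <- fake_b - real_b
        rec_loss <- mean(resid^2)
        gvol <- gvol + config$rec_weight * 2 * resid / length(resid)
      }
      back_g <- nn_backward(gen, gfwd$caches, gvol)
      st <- adam_step(gen, back_g$grads, opt_g, config$lr_generator)
      gen <- st$net; opt_g <- st$state

      if (!is.finite(d_loss) || !is.finite(lg_$loss)) {
        stop("train_cgan: non-finite loss at epoch ", ep)
      }
      g_acc <- g_acc + lg_$loss; d_acc <- d_acc + d_loss
      rec_acc <- rec_acc + rec_loss; nb <- nb + 1L
    }
    g_hist[ep] <- g_acc / nb
    d_hist[ep] <- d_acc / nb
    rec_hist[ep] <- rec_acc / nb
    if (verbose > 0 && ep %% verbose == 0L) {
      message(sprintf("epoch %d/%d  G %.4f  D %.4f", ep, config$epochs,
                      g_hist[ep], d_hist[ep]))
    }
  }
  structure(list(generator = gen, discriminator = disc, config = config,
                 epoch = config$epochs,
                 loss_history = data.frame(epoch = seq_len(config$epochs),
                                           g_loss = g_hist, d_loss = d_hist,
                                           g_rec = rec_hist)),
            class = "cgan_checkpoint")
}

# Element-wise sum of two parallel gradient structures.
combine_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

#' Generate volumes from latent vectors
#'
#' One volume per latent row, deterministic given (checkpoint, latents,
#' seed); with `noise_dim = 0` (the default) the seed is irrelevant and the
#' map is purely latent -> image.
#'
#' @param checkpoint a `cgan_checkpoint` (or a bare generator network with a
#'   `config`).
#' @param latents n x cond_dim matrix.
#' @param seed seed for the optional noise draw.
#' @param batch generation batch size (memory knob only; no effect on
#'   values).
#' @return List of [volume3d()] with declared range c(-1, 1) and provenance
#'   tag "generated" in the `view` slot untouched.
#' @export
generate_volumes <- function(checkpoint, latents, seed = 0L, batch = 32L) {
  gen <- if (inherits(checkpoint, "cgan_checkpoint")) checkpoint$generator else checkpoint
  config <- gen$config
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1L)
  if (nrow(latents) == 0L) return(list())
  if (ncol(latents) != config$cond_dim) {
    stop("generate_volumes: latent dimension ", ncol(latents),
         " does not match cond_dim ", config$cond_dim)
  }
  n <- nrow(latents)
  z <- latents
  if (config$noise_dim > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    z <- cbind(z, matrix(stats::rnorm(n * config$noise_dim), n))
  }
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    y <- gen_forward(gen, z[idx, , drop = FALSE], training = FALSE)$y
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- volume3d(array(y[, , , 1L, j], config$volume_shape),
                                range = c(-1, 1))
    }
  }
  out
}

#' Save / load a cGAN checkpoint
#'
#' Self-describing R-native archive (config + parameters + loss history);
#' load restores bit-identical parameters.
#'
#' @param checkpoint a `cgan_checkpoint`.
#' @param path destination `.rds` path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: file does not exist: ", path)
  readRDS(path)
}
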