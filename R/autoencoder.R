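# Conditional-reconstruction baselines: an encoder-decoder trained with mean
# squared reconstruction loss whose bottleneck is regressed onto the
# multi-omic latent vector, so that volumes can be generated from genomic
# information alone (decoder applied to the latent). Two encoder modes:
# trainable, and pretrained_frozen (a fixed-seed frozen volumetric encoder
# standing in for an external pretrained backbone).

#' Baseline autoencoder configuration
#'
#' @param volume_shape (depth, height, width), multiples of 8.
#' @param cond_dim latent/bottleneck dimension (default 17).
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param encoder_mode `"trainable"` or `"pretrained_frozen"`.
#' @param base_channels channel width multiplier.
#' @param batch_size minibatch size.
#' @param bridge_weight weight of the bottleneck-to-latent regression term.
#' @param seed integer seed.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(volume_shape,
                            cond_dim = 17L,
                            epochs = 100L,
                            learning_rate = 1e-3,
                            encoder_mode = c("trainable", "pretrained_frozen"),
                            base_channels = 16L,
                            batch_size = 8L,
                            bridge_weight = 1,
                            seed = 1L) {
  encoder_mode <- match.arg(encoder_mode)
  if (epochs < 1L) stop("baseline_config: `epochs` must be >= 1")
  if (learning_rate <= 0) stop("baseline_config: `learning_rate` must be > 0")
  if (any(volume_shape %% 8L != 0L) || length(volume_shape) != 3L) {
    stop("baseline_config: volume_shape entries must be multiples of 8")
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 cond_dim = as.integer(cond_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 encoder_mode = encoder_mode,
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size),
                 bridge_weight = bridge_weight,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

build_ae_encoder <- function(config) {
  b <- config$base_channels
  coarse <- config$volume_shape %/% 8L
  layers <- list(
    nn_conv3(1L, b, k = 2L, stride = 2L, pad = 0L),
    nn_lrelu(0.2),
    nn_conv3(b, 2L * b, k = 4L, stride = 2L, pad = 1L),
    nn_lrelu(0.2),
    nn_conv3(2L * b, 4L * b, k = 4L, stride = 2L, pad = 1L),
    nn_lrelu(0.2),
    nn_flatten(),
    nn_dense(prod(coarse) * 4L * b, config$cond_dim)
  )
  structure(list(layers = layers), class = "cgan_net")
}

build_ae_decoder <- function(config) {
  gc <- cgan_config(volume_shape = config$volume_shape,
                    cond_dim = config$cond_dim, noise_dim = 0L,
                    base_channels = config$base_channels,
                    seed = config$seed)
  build_generator(gc)
}

#' Train a conditional autoencoder baseline
#'
#' Minimizes `||decode(encode(v)) - v||^2 + bridge_weight * ||encode(v) -
#' latent||^2` over the cohort (volumes rescaled to \[-1, 1\]). With
#' `encoder_mode = "pretrained_frozen"` the convolutional encoder trunk is
#' frozen at its fixed-seed initialization and only its final projection,
#' plus the decoder, are trained. Seeded and reproducible.
#'
#' @param records list of patient records.
#' @param config a [baseline_config()].
#' @param verbose print loss every `verbose` epochs (0 = silent).
#' @return A `baseline_checkpoint` with encoder, decoder, config and
#'   per-epoch loss history.
#' @export
train_baseline <- function(records, config, verbose = 0L) {
  stopifnot(inherits(config, "baseline_config"))
  cases <- expand_cases(records)
  if (length(cases) == 0L) stop("train_baseline: empty dataset")
  sp <- config$volume_shape
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  enc <- build_ae_encoder(config)
  dec <- build_ae_decoder(config)
  frozen <- config$encoder_mode == "pretrained_frozen"
  # index of the encoder's trainable head when the trunk is frozen
  head_idx <- length(enc$layers)
  opt_e <- adam_init(enc)
  opt_d <- adam_init(dec)
  n <- length(cases)
  vols <- array(0, c(sp, 1L, n))
  for (i in seq_len(n)) vols[, , , 1L, i] <- volume_rescale(cases[[i]]$volumes[[1]])
  lat <- cohort_latents(cases)
  bs <- min(config$batch_size, n)
  hist <- numeric(config$epochs)
  svox <- prod(sp)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    acc <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      m <- length(idx)
      vb <- vols[, , , , idx, drop = FALSE]
      lb <- lat[idx, , drop = FALSE]
      ef <- nn_forward(enc, vb, training = TRUE)
      zhat <- ef$y                                   # cond_dim x m
      df <- nn_forward(dec, zhat, training = TRUE)
      resid <- df$y - vb
      recon <- mean(resid^2)
      bres <- zhat - t(lb)
      bridge <- mean(bres^2)
      loss <- recon + config$bridge_weight * bridge
      if (!is.finite(loss)) stop("train_baseline: non-finite loss at epoch ", ep)
      g_dec <- nn_backward(dec, df$caches, 2 * resid / length(resid))
      gz <- g_dec$gx + config$bridge_weight * 2 * bres / length(bres)
      g_enc <- nn_backward(enc, ef$caches, gz)
      if (frozen) {
        for (i in seq_len(head_idx - 1L)) g_enc$grads[i] <- list(NULL)
      }
      st <- adam_step(dec, g_dec$grads, opt_d, config$learning_rate)
      dec <- st$net; opt_d <- st$state
      st <- adam_step(enc, g_enc$grads, opt_e, config$learning_rate)
      enc <- st$net; opt_e <- st$state
      acc <- acc + loss; nb <- nb + 1L
    }
    hist[ep] <- acc / nb
    if (verbose > 0 && ep %% verbose == 0L) {
      message(sprintf("epoch %d/%d  loss %.5f", ep, config$epochs, hist[ep]))
    }
  }
  structure(list(encoder = enc, decoder = dec, config = config,
                 epoch = config$epochs,
                 loss_history = data.frame(epoch = seq_len(config$epochs),
                                           loss = hist)),
            class = "baseline_checkpoint")
}

#' Generate volumes from latents with a trained baseline
#'
#' Applies the decoder to latent vectors directly (the bottleneck was
#' regressed onto the latent during training, so this is the baseline's
#' genomic-only generation path). Deterministic.
#'
#' @param checkpoint a `baseline_checkpoint`.
#' @param latents n x cond_dim matrix.
#' @return List of [volume3d()] with declared range c(-1, 1).
#' @export
baseline_generate <- function(checkpoint, latents) {
  stopifnot(inherits(checkpoint, "baseline_checkpoint"))
  generate_volumes(checkpoint$decoder, latents)
}
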