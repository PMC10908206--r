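# Frechet distance between Gaussian fits to volumetric features of real and
# generated image sets, with a pluggable 3D feature extractor, bootstrap
# uncertainty, and fold-wise cross-validated reporting. The default
# extractor is a frozen, fixed-seed, randomly-initialized small 3D conv net
# (random frozen features); absolute values are therefore on the package's
# own scale, while orderings between models remain meaningful.

#' Create a frozen 3D convolutional feature extractor
#'
#' Three strided 3D conv + leaky-ReLU stages; the feature vector is
#' multi-scale: the per-channel spatial mean and standard deviation of the
#' first-stage maps (fine scale — sensitive to voxel-level texture and
#' sharpness) concatenated with the same statistics of the last-stage maps
#' (coarse scale — sensitive to anatomy-level structure). Deep-feature
#' distances are conventionally computed on layers that respond to both
#' texture and structure; statistics taken only after heavy downsampling
#' are blind to blur, letting over-smoothed reconstructions score as well
#' as sharp ones. `feature_dim` is split evenly between the two scales
#' (must be a multiple of 4). Parameters are drawn once from a fixed seed
#' and never trained; the same volume always maps to the same features.
#' Any user-supplied function `volume -> d-vector` can be used instead
#' wherever an extractor is accepted.
#'
#' @param volume_shape expected (depth, height, width), multiples of 8.
#' @param feature_dim number of features d (multiple of 4; default 32).
#' @param seed seed for the frozen random parameters.
#' @return An object of class `feature_extractor` with `$feature_dim`.
#' @export
make_feature_extractor <- function(volume_shape, feature_dim = 32L, seed = 7L) {
  if (any(volume_shape %% 8L != 0L)) {
    stop("make_feature_extractor: volume_shape entries must be multiples of 8")
  }
  if (feature_dim %% 4L != 0L) {
    stop("make_feature_extractor: `feature_dim` must be a multiple of 4 ",
         "(mean + sd at two scales)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c1 <- as.integer(feature_dim) %/% 4L    # fine-scale channels
  c3 <- as.integer(feature_dim) %/% 4L    # coarse-scale channels
  net <- structure(list(layers = list(
    nn_conv3(1L, c1, k = 4L, stride = 2L, pad = 1L),
    nn_lrelu(0.2),
    nn_conv3(c1, 2L * c1, k = 4L, stride = 2L, pad = 1L),
    nn_lrelu(0.2),
    nn_conv3(2L * c1, c3, k = 4L, stride = 2L, pad = 1L),
    nn_lrelu(0.2)
  )), class = "cgan_net")
  structure(list(net = net, volume_shape = as.integer(volume_shape),
                 tap_after = 2L,  # layer index whose output is the fine scale
                 feature_dim = as.integer(feature_dim)),
            class = "feature_extractor")
}

#' Extract volumetric features from a set of volumes
#'
#' Volumes are rescaled from their declared range to \[-1, 1\] before the
#' forward pass so real and generated sets are comparable. Deterministic.
#'
#' @param volumes list of [volume3d()] of uniform shape.
#' @param extractor a [make_feature_extractor()] object or a function
#'   `volume3d -> numeric(d)`.
#' @param batch forward batch size (memory knob).
#' @return n x d feature matrix.
#' @export
extract_features <- function(volumes, extractor, batch = 32L) {
  if (length(volumes) < 1L) stop("extract_features: need at least one volume")
  if (is.function(extractor)) {
    return(do.call(rbind, lapply(volumes, extractor)))
  }
  stopifnot(inherits(extractor, "feature_extractor"))
  sp <- extractor$volume_shape
  for (v in volumes) {
    if (!all(dim(v$data) == sp)) {
      stop("extract_features: volume shape ", paste(dim(v$data), collapse = "x"),
           " does not match extractor's expected ", paste(sp, collapse = "x"))
    }
  }
  n <- length(volumes)
  d <- extractor$feature_dim
  # per-channel spatial mean and sd of a (d',h',w',C,m) map, as m x 2C
  map_stats <- function(y) {
    yd <- dim(y)
    m <- matrix(y, prod(yd[1:3]), yd[4] * yd[5])
    mu <- colMeans(m)
    sdv <- sqrt(pmax(colMeans(m * m) - mu^2, 0))
    cbind(t(matrix(mu, yd[4], yd[5])), t(matrix(sdv, yd[4], yd[5])))
  }
  tap <- extractor$tap_after
  out <- matrix(0, n, d)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    xb <- array(0, c(sp, 1L, length(idx)))
    for (j in seq_along(idx)) xb[, , , 1L, j] <- volume_rescale(volumes[[idx[j]]])
    y <- xb
    fine <- NULL
    for (li in seq_along(extractor$net$layers)) {
      y <- layer_forward(extractor$net$layers[[li]], y)$y
      if (li == tap) fine <- y
    }
    out[idx, ] <- cbind(map_stats(fine), map_stats(y))
  }
  out
}

#' Fit Gaussian sufficient statistics to a feature matrix
#'
#' Sample mean and sample covariance (denominator n - 1), symmetry enforced.
#'
#' @param features n x d matrix, n >= 2.
#' @return `gaussian_stats` object: `mean`, `cov`, `n`.
#' @export
fit_gaussian <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("fit_gaussian: need at least 2 feature rows")
  mu <- colMeans(features)
  sig <- stats::cov(features)
  sig <- (sig + t(sig)) / 2
  structure(list(mean = mu, cov = sig, n = nrow(features)),
            class = "gaussian_stats")
}

# Symmetric PSD matrix square root by eigendecomposition, with negative
# eigenvalues (numerical noise) clipped at zero.
psd_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two Gaussian fits
#'
#' `d^2 = |mu_a - mu_b|^2 + Tr(Sa + Sb - 2 (Sa Sb)^{1/2})`, with the matrix
#' square root computed by eigendecomposition of the symmetrized product
#' `sqrt(Sa) Sb sqrt(Sa)`; a jitter of `1e-6 * mean(diag)` is added on
#' numerical failure, and the result is clipped at zero.
#'
#' @param stats_a,stats_b `gaussian_stats` of matching dimension.
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(stats_a, stats_b) {
  stopifnot(inherits(stats_a, "gaussian_stats"), inherits(stats_b, "gaussian_stats"))
  if (length(stats_a$mean) != length(stats_b$mean)) {
    stop("frechet_distance: dimension mismatch (",
         length(stats_a$mean), " vs ", length(stats_b$mean), ")")
  }
  dmu <- sum((stats_a$mean - stats_b$mean)^2)
  sa <- stats_a$cov; sb <- stats_b$cov
  tr_cross <- tryCatch({
    ra <- psd_sqrt(sa)
    m <- ra %*% sb %*% ra
    ev <- pmax(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0)
    sum(sqrt(ev))
  }, error = function(e) {
    eps <- 1e-6 * mean(diag(sa) + diag(sb)) / 2
    ra <- psd_sqrt(sa + eps * diag(nrow(sa)))
    m <- ra %*% (sb + eps * diag(nrow(sb))) %*% ra
    ev <- pmax(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0)
    sum(sqrt(ev))
  })
  max(0, dmu + sum(diag(sa)) + sum(diag(sb)) - 2 * tr_cross)
}

#' FID between two volume sets with bootstrap uncertainty
#'
#' Features are extracted once; the distance is then recomputed on `n_boot`
#' paired with-replacement resamples of both sets. Returns the bootstrap
#' mean and standard deviation (the reported "plus/minus" spread; 0 when
#' `n_boot = 1`).
#'
#' @param real_volumes,fake_volumes lists of >= 2 volumes.
#' @param extractor feature extractor.
#' @param n_boot number of bootstrap resamples (default 20).
#' @param seed integer seed for the resampling.
#' @return `list(mean =, spread =, n_real =, n_fake =, feature_dim =)`.
#' @export
fid_with_uncertainty <- function(real_volumes, fake_volumes, extractor,
                                 n_boot = 20L, seed = 1L) {
  if (length(real_volumes) < 2L || length(fake_volumes) < 2L) {
    stop("fid_with_uncertainty: both sets need >= 2 volumes")
  }
  if (n_boot < 1L) stop("fid_with_uncertainty: `n_boot` must be >= 1")
  fr <- extract_features(real_volumes, extractor)
  ff <- extract_features(fake_volumes, extractor)
  fid_features_boot(fr, ff, n_boot, seed)
}

# Bootstrap FID on precomputed feature matrices (also used directly in
# validation against closed-form Gaussian populations).
fid_features_boot <- function(fr, ff, n_boot = 20L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ir <- sample.int(nrow(fr), replace = TRUE)
    jf <- sample.int(nrow(ff), replace = TRUE)
    vals[b] <- frechet_distance(fit_gaussian(fr[ir, , drop = FALSE]),
                                fit_gaussian(ff[jf, , drop = FALSE]))
  }
  list(mean = mean(vals),
       spread = if (n_boot > 1L) stats::sd(vals) else 0,
       n_real = nrow(fr), n_fake = nrow(ff), feature_dim = ncol(fr))
}

#' Cross-validated FID with best-fold selection
#'
#' For each of `k` folds: train on the remaining folds, generate volumes for
#' the held-out latents, and compute FID against the held-out real volumes.
#' Returns the per-fold table, the argmin (best) fold, and that fold's
#' trained model (the checkpoint retained for cohort-wide generation).
#'
#' @param records list of patient records.
#' @param train_fn `function(records, seed) -> model`.
#' @param generate_fn `function(model, latents) -> list of volumes`.
#' @param extractor feature extractor.
#' @param k number of folds (>= 2; the reference protocol uses 10).
#' @param n_boot bootstrap resamples per fold.
#' @param seed integer seed (fold assignment + per-fold training seeds).
#' @return `list(table = data.frame(fold, fid_mean, fid_spread, n_test),
#'   best_fold =, best_model =)`.
#' @export
crossval_fid <- function(records, train_fn, generate_fn, extractor,
                         k = 10L, n_boot = 20L, seed = 1L) {
  folds <- kfold_indices(length(records), k, seed = seed)
  rows <- vector("list", k)
  models <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train_recs <- records[-test_idx]
    test_recs <- records[test_idx]
    model <- train_fn(train_recs, seed = (seed + 131L * i) %% 2147483647L)
    fake <- generate_fn(model, cohort_latents(test_recs))
    real <- cohort_volumes(test_recs)
    f <- fid_with_uncertainty(real, fake, extractor, n_boot = n_boot,
                              seed = (seed + 977L * i) %% 2147483647L)
    rows[[i]] <- data.frame(fold = i, fid_mean = f$mean, fid_spread = f$spread,
                            n_test = length(test_recs))
    models[[i]] <- model
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$fid_mean)
  list(table = tab, best_fold = best, best_model = models[[best]])
}
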