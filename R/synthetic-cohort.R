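# Synthetic phantom cohorts: paired multi-omic latent vectors, 3D phantom
# volumes whose lesion appearance depends on the latent vector, per-gene
# binary mutation labels and 5-class subtype labels. This is the testbed
# that stands in for a matched TCGA/TCIA-style cohort so the whole pipeline
# (cGAN -> FID -> CNN prediction) can be exercised without any downloads.

#' Construct a volume with a declared intensity range
#'
#' A `volume3d` is a depth x height x width numeric array (slice axis first)
#' plus the declared intensity range of its values. All pipeline stages use
#' the declared range to rescale volumes consistently (e.g. to the
#' generator's tanh range \[-1, 1\]).
#'
#' @param data 3D numeric array, dim (depth, height, width).
#' @param range length-2 numeric, declared (lo, hi) intensity range.
#' @param view optional view tag (e.g. "side" or "top-down"); metadata only.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, range = c(0, 1), view = "side") {
  if (length(dim(data)) != 3L) stop("volume3d: `data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("volume3d: all dimensions must be positive")
  if (length(range) != 2L || range[2] <= range[1]) {
    stop("volume3d: `range` must be (lo, hi) with hi > lo")
  }
  structure(list(data = data, range = as.numeric(range), view = view),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s, range [%g, %g], view %s>\n",
              paste(dim(x$data), collapse = "x"), x$range[1], x$range[2], x$view))
  invisible(x)
}

# Rescale a volume3d's data linearly from its declared range to [lo, hi].
volume_rescale <- function(vol, lo = -1, hi = 1) {
  a <- vol$range[1]; b <- vol$range[2]
  lo + (vol$data - a) / (b - a) * (hi - lo)
}

#' Specify a synthetic phantom cohort
#'
#' Defines the data-generating process of the benchmark cohort: i.i.d.
#' standard-normal latent vectors (a scale-free stand-in for Bayesian tensor
#' factorization scores, whose distribution is not characterized upstream),
#' logistic mutation labels, softmax subtype labels, and phantom volumes with
#' an ellipsoidal breast region plus a single Gaussian lesion whose amplitude
#' and radius grow with `lesion_effect . latent`.
#'
#' Default gene effects and intercepts are calibrated so that marginal
#' mutation prevalences match the reference cohort frequencies
#' (TP53 235/690, PIK3CA 247/690, CDH1 112/690).
#'
#' @param n_patients number of patients (>= 0).
#' @param latent_dim latent feature dimension (default 17).
#' @param volume_shape (depth, height, width) in voxels; default 32x128x128.
#' @param gene_specs list of `list(gene=, effect=, intercept=)`; `effect` is a
#'   `latent_dim` vector, `intercept` a real. `intercept = NA` requests
#'   calibration to `target_prev`.
#' @param subtype_coeffs 5 x latent_dim matrix of softmax coefficients.
#' @param lesion_effect `latent_dim` vector mapping latent to lesion
#'   amplitude/size.
#' @param noise_sd voxel Gaussian noise sd (>= 0).
#' @param volumes_per_patient volumes per patient (default 1; several volumes
#'   per patient are treated downstream as separate cases by default).
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        latent_dim = 17L,
                        volume_shape = c(32L, 128L, 128L),
                        gene_specs = default_gene_specs(latent_dim),
                        subtype_coeffs = default_subtype_coeffs(latent_dim),
                        lesion_effect = c(1, rep(0, latent_dim - 1)),
                        noise_sd = 0.05,
                        volumes_per_patient = 1L,
                        seed = 1L) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0) {
    stop("cohort_spec: `n_patients` must be >= 0")
  }
  if (latent_dim < 1L) stop("cohort_spec: `latent_dim` must be >= 1")
  if (length(volume_shape) != 3L || any(volume_shape < 4L)) {
    stop("cohort_spec: `volume_shape` must be 3 entries, all >= 4")
  }
  if (noise_sd < 0) stop("cohort_spec: `noise_sd` must be >= 0")
  if (length(lesion_effect) != latent_dim) {
    stop("cohort_spec: `lesion_effect` length must equal `latent_dim`")
  }
  if (!is.matrix(subtype_coeffs) || !all(dim(subtype_coeffs) == c(5L, latent_dim))) {
    stop("cohort_spec: `subtype_coeffs` must be a 5 x latent_dim matrix")
  }
  for (gs in gene_specs) {
    if (length(gs$effect) != latent_dim) {
      stop("cohort_spec: effect vector for gene ", gs$gene,
           " must have length ", latent_dim)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 latent_dim = as.integer(latent_dim),
                 volume_shape = as.integer(volume_shape),
                 gene_specs = gene_specs,
                 subtype_coeffs = subtype_coeffs,
                 lesion_effect = lesion_effect,
                 noise_sd = noise_sd,
                 volumes_per_patient = as.integer(volumes_per_patient),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Reference mutation prevalences of the three driver genes (mutated/total).
gene_target_prevalence <- c(TP53 = 235 / 690, PIK3CA = 247 / 690, CDH1 = 112 / 690)

#' Calibrate a logistic intercept for a target marginal prevalence
#'
#' With latent ~ N(0, I) and label ~ Bernoulli(plogis(effect . latent + b)),
#' the marginal prevalence is E\[plogis(b + s Z)\], Z ~ N(0,1), s = ||effect||.
#' Solves for b by numerical integration + root finding.
#'
#' @param target_prev target marginal prevalence in (0, 1).
#' @param effect effect vector (only its norm matters).
#' @return Calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(target_prev, effect) {
  s <- sqrt(sum(effect^2))
  if (s < 1e-12) return(stats::qlogis(target_prev))
  marg <- function(b) {
    stats::integrate(function(z) stats::plogis(b + s * z) * stats::dnorm(z),
                     -8, 8, rel.tol = 1e-10)$value
  }
  stats::uniroot(function(b) marg(b) - target_prev, c(-20, 20), tol = 1e-9)$root
}

#' Default driver-gene label model
#'
#' TP53, PIK3CA and CDH1 load on latent features 1-3 respectively with
#' moderate effect size; intercepts are calibrated so marginal prevalences
#' match the reference cohort (approximately 34%, 36%, 16%).
#'
#' @param latent_dim latent dimension.
#' @param effect_size common effect-vector norm (default 2).
#' @return List of gene specs.
#' @export
default_gene_specs <- function(latent_dim = 17L, effect_size = 2) {
  genes <- names(gene_target_prevalence)
  lapply(seq_along(genes), function(i) {
    eff <- rep(0, latent_dim)
    eff[min(i, latent_dim)] <- effect_size
    list(gene = genes[i], effect = eff,
         intercept = calibrate_intercept(gene_target_prevalence[[i]], eff))
  })
}

#' Default subtype coefficient matrix
#'
#' Five rows (Normal=0, Basal=1, LumA=2, LumB=3, HER2=4) with contrasts on
#' the first two latent features, giving non-degenerate but overlapping
#' subtype classes.
#'
#' @param latent_dim latent dimension.
#' @return 5 x latent_dim matrix.
#' @export
default_subtype_coeffs <- function(latent_dim = 17L) {
  m <- matrix(0, 5L, latent_dim)
  m[2, 1] <- 1.5
  m[3, 1] <- -1.5
  m[4, min(2L, latent_dim)] <- 1.5
  m[5, min(2L, latent_dim)] <- -1.5
  m
}

#' Assign mutation and subtype labels from a latent vector
#'
#' Per gene, label ~ Bernoulli(plogis(effect . latent + intercept)); subtype
#' is a categorical draw from softmax(subtype_coeffs %*% latent), coded
#' Normal=0, Basal=1, LumA=2, LumB=3, HER2=4.
#'
#' @param latent latent feature vector.
#' @param gene_specs list of gene specs (see [cohort_spec()]).
#' @param subtype_coeffs 5 x latent_dim matrix.
#' @param seed integer seed; the draw is deterministic given it.
#' @return `list(mutation_labels = named 0/1 integer vector, subtype = int)`.
#' @export
assign_labels <- function(latent, gene_specs, subtype_coeffs, seed) {
  d <- length(latent)
  for (gs in gene_specs) {
    if (length(gs$effect) != d) {
      stop("assign_labels: effect length for gene ", gs$gene,
           " does not match latent_dim ", d)
    }
  }
  if (ncol(subtype_coeffs) != d) {
    stop("assign_labels: subtype_coeffs has ", ncol(subtype_coeffs),
         " columns but latent_dim is ", d)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  muts <- vapply(gene_specs, function(gs) {
    p <- stats::plogis(sum(gs$effect * latent) + gs$intercept)
    as.integer(stats::runif(1) < p)
  }, integer(1))
  names(muts) <- vapply(gene_specs, `[[`, character(1), "gene")
  sc <- drop(subtype_coeffs %*% latent)
  sc <- sc - max(sc)
  p <- exp(sc) / sum(exp(sc))
  subtype <- sample.int(5L, 1L, prob = p) - 1L
  list(mutation_labels = muts, subtype = subtype)
}

# Save/restore the global RNG state so seeded sub-draws do not perturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Render a phantom breast volume from a latent vector
#'
#' The phantom is an axis-aligned ellipsoidal "breast" of baseline intensity
#' 0.25 on a zero background, plus one smooth Gaussian lesion blob at the
#' ellipsoid centre. Lesion amplitude and radius are strictly increasing
#' bounded (tanh) functions of `s = lesion_effect . latent`, plus i.i.d.
#' Gaussian voxel noise. Intensities are clipped to the declared \[0, 1\]
#' range. Deterministic given (latent, seed).
#'
#' @param latent latent feature vector.
#' @param shape (depth, height, width) voxels.
#' @param lesion_effect vector of length `length(latent)`.
#' @param noise_sd Gaussian voxel noise sd.
#' @param seed integer seed for the noise draw.
#' @return A [volume3d()] with range c(0, 1).
#' @export
render_phantom <- function(latent, shape, lesion_effect, noise_sd = 0, seed = 0L) {
  if (length(shape) != 3L || any(shape < 4L)) {
    stop("render_phantom: `shape` must be 3 entries, all >= 4")
  }
  if (length(lesion_effect) != length(latent)) {
    stop("render_phantom: `lesion_effect` length must match latent")
  }
  s <- sum(lesion_effect * latent)
  amp <- 0.45 + 0.35 * tanh(s / 2)            # lesion amplitude in (0.10, 0.80)
  rad <- 0.16 + 0.05 * tanh(s / 2)            # lesion radius, fraction of extent
  d <- shape[1]; h <- shape[2]; w <- shape[3]
  # normalized coordinates in [-1, 1] per axis
  zd <- (seq_len(d) - (d + 1) / 2) / (d / 2)
  zh <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  zw <- (seq_len(w) - (w + 1) / 2) / (w / 2)
  dd <- array(zd, shape)
  hh <- array(rep(zh, each = d), shape)
  ww <- array(rep(zw, each = d * h), shape)
  ellip <- (dd / 0.9)^2 + (hh / 0.75)^2 + (ww / 0.85)^2
  vol <- ifelse(ellip <= 1, 0.25, 0)
  r2 <- dd^2 + hh^2 + ww^2
  vol <- vol + amp * exp(-r2 / (2 * rad^2))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd), shape)
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  volume3d(vol, range = c(0, 1))
}

# Mask of the central lesion region used by conditioning-faithfulness checks:
# voxels within the baseline lesion radius of the centre.
lesion_mask <- function(shape, radius = 0.16) {
  d <- shape[1]; h <- shape[2]; w <- shape[3]
  zd <- (seq_len(d) - (d + 1) / 2) / (d / 2)
  zh <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  zw <- (seq_len(w) - (w + 1) / 2) / (w / 2)
  dd <- array(zd, shape)
  hh <- array(rep(zh, each = d), shape)
  ww <- array(rep(zw, each = d * h), shape)
  (dd^2 + hh^2 + ww^2) <= radius^2 * 4
}

#' Simulate a full phantom cohort
#'
#' Draws i.i.d. standard-normal latent vectors, assigns labels via
#' [assign_labels()] and renders volumes via [render_phantom()]. The cohort
#' is fully determined by the spec (including its seed): per-patient seeds
#' are derived deterministically from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List of `patient_record` objects; each has fields `patient_id`,
#'   `latent`, `mutation_labels`, `subtype`, `volumes`, `provenance`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (n == 0L) return(list())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lat <- matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim)
  lapply(seq_len(n), function(i) {
    pseed <- (spec$seed + 7919L * i) %% 2147483647L
    lab <- assign_labels(lat[i, ], spec$gene_specs, spec$subtype_coeffs,
                         seed = pseed)
    vols <- lapply(seq_len(spec$volumes_per_patient), function(j) {
      render_phantom(lat[i, ], spec$volume_shape, spec$lesion_effect,
                     noise_sd = spec$noise_sd,
                     seed = (pseed + 104729L * j) %% 2147483647L)
    })
    structure(list(patient_id = sprintf("P%04d", i),
                   latent = lat[i, ],
                   mutation_labels = lab$mutation_labels,
                   subtype = lab$subtype,
                   volumes = vols,
                   provenance = "real"),
              class = "patient_record")
  })
}

# Matrix of latent vectors (n x d) from a list of records.
cohort_latents <- function(records) {
  do.call(rbind, lapply(records, `[[`, "latent"))
}

# All volumes of a cohort flattened to one list; with multiple volumes per
# patient each volume becomes a separate case (record index in attribute).
cohort_volumes <- function(records) {
  unlist(lapply(records, `[[`, "volumes"), recursive = FALSE)
}
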