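# The phantom benchmark used by the end-to-end acceptance checks: n = 200
# patients, 8x32x32 volumes, strong lesion effect and gene effect aligned on
# the first latent feature. Training a cGAN for 200 epochs takes minutes, so
# per-seed artifacts (trained cGAN, generated cohort, classifier AUCs,
# baseline FIDs) are computed once per test run and shared by the
# signal-recovery, null-control and baseline-ordering checks.

bench_shape <- c(8L, 32L, 32L)
bench_n <- 200L
bench_latent_dim <- 17L

bench_spec <- function(seed) {
  d <- bench_latent_dim
  cohort_spec(
    n_patients = bench_n, latent_dim = d, volume_shape = bench_shape,
    gene_specs = list(list(gene = "TP53",
                           effect = c(4, rep(0, d - 1)), intercept = 0)),
    subtype_coeffs = default_subtype_coeffs(d),
    lesion_effect = c(3, rep(0, d - 1)),
    noise_sd = 0.05, seed = seed)
}

bench_cgan_config <- function(seed) {
  cgan_config(volume_shape = bench_shape, cond_dim = bench_latent_dim,
              epochs = 200L, batch_size = 16L,
              lr_generator = 4e-4, lr_discriminator = 1e-4,
              base_channels = 6L, seed = seed)
}

bench_cnn_config <- function(seed) {
  cnn_config(volume_shape = bench_shape, task = "TP53", epochs = 5L,
             batch_size = 16L, learning_rate = 1e-3, seed = seed)
}

.bench_cache <- new.env(parent = emptyenv())

# Train/evaluate everything for one benchmark seed; cached per test run.
bench_artifacts <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])

  cohort <- simulate_cohort(bench_spec(10L + seed))
  spl <- split_train_test(cohort, 0.2, "TP53", seed = 5L + seed)
  ck <- train_cgan(spl$train, bench_cgan_config(seed))

  # cohort-wide generation for classifier experiments
  gen_vols <- generate_volumes(ck, latents_of(cohort))
  gen_cohort <- mapply(function(r, v) {
    r$volumes <- list(v); r$provenance <- "generated"; r
  }, cohort, gen_vols, SIMPLIFY = FALSE)

  eval_auc <- function(records, split_seed, cnn_seed) {
    gspl <- split_train_test(records, 0.2, "TP53", seed = split_seed)
    model <- train_classifier(build_mutation_cnn(bench_cnn_config(cnn_seed)),
                              gspl$train)
    tc <- expand_cases(gspl$test)
    truth <- labels_of(tc, "TP53")
    prob <- predict_proba(model, lapply(tc, function(r) r$volumes[[1]]))
    roc_curve_auc(truth, prob)$auc
  }

  signal_auc <- eval_auc(gen_cohort, split_seed = 6L + seed, cnn_seed = 2L + seed)

  # null control: permute the cohort's labels up front, then run the same
  # split/train/evaluate pipeline against the permuted truth
  perm <- gen_cohort
  old <- radiogan:::.Random.seed_save()
  set.seed(900L + seed)
  pl <- sample(labels_of(perm, "TP53"))
  radiogan:::.Random.seed_restore(old)
  for (i in seq_along(perm)) perm[[i]]$mutation_labels[["TP53"]] <- pl[i]
  null_auc <- eval_auc(perm, split_seed = 6L + seed, cnn_seed = 2L + seed)

  # baselines at matched epoch budget + untrained generator control
  bl <- train_baseline(spl$train, baseline_config(
    volume_shape = bench_shape, cond_dim = bench_latent_dim, epochs = 200L,
    learning_rate = 1e-3, base_channels = 6L, batch_size = 32L,
    seed = 100L + seed))
  untrained <- local({
    o <- radiogan:::.Random.seed_save()
    on.exit(radiogan:::.Random.seed_restore(o))
    set.seed(200L + seed)
    build_generator(bench_cgan_config(seed))
  })
  ex <- make_feature_extractor(bench_shape, feature_dim = 32L, seed = 7L)
  test_real <- all_volumes(spl$test)
  test_lat <- latents_of(spl$test)
  fid_cgan <- fid_with_uncertainty(test_real, generate_volumes(ck, test_lat),
                                   ex, n_boot = 8L, seed = 1L)
  fid_ae <- fid_with_uncertainty(test_real, baseline_generate(bl, test_lat),
                                 ex, n_boot = 8L, seed = 2L)
  fid_untrained <- fid_with_uncertainty(test_real,
                                        generate_volumes(untrained, test_lat),
                                        ex, n_boot = 8L, seed = 3L)

  mask <- radiogan:::lesion_mask(bench_shape)
  gv_te <- generate_volumes(ck, test_lat)
  lesion_rho <- stats::cor(
    vapply(gv_te, function(v) mean(v$data[mask]), numeric(1)),
    drop(test_lat %*% c(3, rep(0, bench_latent_dim - 1))),
    method = "spearman")

  out <- list(checkpoint = ck, signal_auc = signal_auc, null_auc = null_auc,
              fid_cgan = fid_cgan$mean, fid_ae = fid_ae$mean,
              fid_untrained = fid_untrained$mean, lesion_rho = lesion_rho)
  .bench_cache[[key]] <- out
  out
}

bench_seeds <- 1:3
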