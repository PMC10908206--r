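# radiogan

Conditional GAN synthesis of 3D breast MRI volumes from multi-omic latent
features, with downstream mutation-status and molecular-subtype prediction
— a radiogenomic pipeline for the *unpaired data* problem in breast cancer
cohorts, where most patients have molecular profiles but no matched
imaging.

## What it does

Given per-patient latent feature vectors **c** ∈ ℝ¹⁷ (from an upstream
Bayesian tensor factorization of gene expression, copy-number variation
and DNA methylation), the package:

1. **Synthesizes volumes.** A conditional generative adversarial network
   learns G: c → 3D volume (default 32 × 128 × 128) from patients who have
   both omics and MRI. Both players see the condition; training uses the
   least-squares adversarial objective (discriminator target 1 on real /
   0 on generated, generator target 1) plus a paired reconstruction term,
   with the reference hyperparameters as defaults (batch 2, lr_G 2.5e-5,
   lr_D 1e-5, 1200 epochs, leaky slope 0.2).
2. **Scores realism.** Squared Fréchet distance between Gaussian fits to
   volumetric deep features of real vs generated sets,
   d² = |μ_a − μ_b|² + Tr(Σ_a + Σ_b − 2(Σ_a Σ_b)^{1/2}),
   with a pluggable 3D feature extractor (a frozen random multi-scale conv
   net by default), bootstrap uncertainty, and the ten-fold
   cross-validation protocol with best-fold selection.
3. **Predicts from synthetic images.** A 3D CNN (conv channels 32→16→8
   with max-pooling, 128-unit hidden layer, dropout 0.5, sigmoid output)
   classifies *TP53* / *PIK3CA* / *CDH1* mutation status (0 = unaltered,
   1 = altered); the same trunk with five raw outputs classifies subtype
   (Normal=0, Basal=1, LumA=2, LumB=3, HER2=4). Comparison arms: real
   volumes, generated volumes, both combined, and an L1-logistic baseline
   on the raw latents. Metrics: ROC-AUC (Mann–Whitney, ties = ½), PR-AUC
   (step interpolation), macro precision/recall/F1.
4. **Simulates phantom cohorts.** A first-class synthetic-data module
   generates latent vectors, lesion phantoms whose appearance depends on
   the latents, and calibrated mutation/subtype labels, so the entire
   pipeline is testable end-to-end with no downloads.

Everything is seeded and single-threaded deterministic: identical configs
reproduce identical results, byte for byte for the pipeline report.

## Worked example

A miniature end-to-end run (about two minutes on one CPU):

```r
library(radiogan)

# 1. Simulate a phantom cohort: 17-dim multi-omic latents, one 8x32x32
#    volume per patient, TP53/PIK3CA/CDH1 labels at reference prevalences
spec <- cohort_spec(n_patients = 120, volume_shape = c(8, 32, 32),
                    lesion_effect = c(3, rep(0, 16)), seed = 1)
cohort <- simulate_cohort(spec)
spl <- split_train_test(cohort, test_fraction = 0.2, stratify_key = "TP53",
                        seed = 1)

# 2. Train the conditional GAN (toy budget) and generate volumes from
#    latent vectors alone
cfg <- cgan_config(volume_shape = c(8, 32, 32), epochs = 60, batch_size = 16,
                   lr_generator = 4e-4, lr_discriminator = 1e-4,
                   base_channels = 6, seed = 1)
ck <- train_cgan(spl$train, cfg)
fake <- generate_volumes(ck, do.call(rbind, lapply(spl$test, `[[`, "latent")))

# 3. Score realism: Frechet distance on frozen volumetric features
ex <- make_feature_extractor(c(8, 32, 32), feature_dim = 32)
real <- unlist(lapply(spl$test, `[[`, "volumes"), recursive = FALSE)
fid <- fid_with_uncertainty(real, fake, ex, n_boot = 20, seed = 1)
cat(sprintf("FID(generated, real) = %.3f +/- %.3f\n", fid$mean, fid$spread))
#> FID(generated, real) = 0.629 +/- 0.005

# 4. Predict TP53 mutation status from the generated volumes
gen_cohort <- mapply(function(r, v) { r$volumes <- list(v); r },
                     cohort, generate_volumes(ck, do.call(rbind,
                       lapply(cohort, `[[`, "latent"))), SIMPLIFY = FALSE)
gspl <- split_train_test(gen_cohort, 0.2, "TP53", seed = 2)
cnn <- cnn_config(volume_shape = c(8, 32, 32), task = "TP53", epochs = 5,
                  batch_size = 16, seed = 1)
model <- train_classifier(build_mutation_cnn(cnn), gspl$train)
test <- expand_cases(gspl$test)
prob <- predict_proba(model, lapply(test, function(r) r$volumes[[1]]))
truth <- sapply(test, function(r) r$mutation_labels[["TP53"]])
cat(sprintf("held-out ROC-AUC = %.3f  PR-AUC = %.3f\n",
            roc_curve_auc(truth, prob)$auc, pr_curve_auc(truth, prob)$auc))
#> held-out ROC-AUC = 0.828  PR-AUC = 0.686
```

The FID of 0.63 says the 60-epoch generator's feature distribution is
already far closer to the real one than an untrained generator's (which
scores in the hundreds on this scale); the ROC-AUC of 0.83 says a CNN that
has only ever seen *synthetic* volumes recovers the mutation signal that
the simulator planted in the latent-to-lesion map. At the full benchmark
budget (n = 200, 200 epochs; see the methods vignette) the test suite
requires a median signal-recovery AUC of at least 0.8 over three seeds.

The whole study design — cross-validated GAN training with FID-based fold
selection, baselines, all comparison arms, consolidated report — runs from
one YAML config:

```r
run_all("experiment.yaml", "run_dir")   # or validate_config() first
```

or from the shell via `Rscript inst/scripts/radiogan-run.R --config
experiment.yaml --out run_dir`.

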