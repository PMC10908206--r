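---
title: "Conditional GAN synthesis of 3D breast MRI from multi-omic latent features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radiogan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiogenomic studies of breast cancer need three things per patient —
molecular profiles, imaging, and outcomes — but public cohorts rarely have
all three for the same people. Of the TCGA-BRCA patients with complete
multi-omic data (gene expression, copy-number variation, DNA methylation),
only a small fraction have matched DCE-MRI in TCIA. `radiogan` implements a
generative route around this unpaired-data problem: a conditional
generative adversarial network (cGAN) learns the map from a patient's
multi-omic latent feature vector to a 3D MRI-like volume, so that volumes
can be synthesized for the majority of patients who have omics but no
imaging. The synthetic volumes are then scored for realism with a Fréchet
distance on volumetric deep features, and put to work in two downstream
tasks: binary mutation-status prediction for the driver genes *TP53*,
*PIK3CA* and *CDH1*, and five-class molecular subtype classification
(Normal = 0, Basal = 1, LumA = 2, LumB = 3, HER2 = 4).

The 17-dimensional latent features are taken as given: they are the output
of an upstream Bayesian tensor factorization of the patients × genes ×
omic-type tensor and are consumed, not computed, here.

## The synthetic phantom cohort

Nothing in this package downloads data. All end-to-end behavior is
exercised on a synthetic phantom cohort whose data-generating process
mirrors the structure the analysis assumes:

* **Latents.** Each patient has an i.i.d. standard-normal latent vector
  (dimension 17 by default). The upstream factorization's latent
  distribution is not characterized anywhere we could consult, so the
  scale-free factor-model convention is used; this is a stand-in, not a
  claim about the real features.
* **Volumes.** A phantom volume is an axis-aligned ellipsoidal "breast" of
  baseline intensity 0.25 on a zero background plus a single central
  Gaussian lesion blob, plus i.i.d. voxel noise (sd 0.05), clipped to
  [0, 1]. Lesion amplitude and radius are strictly increasing, bounded
  (tanh) functions of the scalar projection `lesion_effect · latent`, so a
  one-dimensional "lesion severity" axis of the latent space controls the
  image phenotype.
* **Labels.** Per gene, mutation status is Bernoulli with logistic link on
  `effect · latent + intercept`; the subtype is a categorical draw from a
  softmax over five linear scores. Default gene effects load on latent
  features 1–3; intercepts are calibrated by numerical integration so the
  marginal prevalences match the reference cohort frequencies
  (TP53 235/690 ≈ 34%, PIK3CA 247/690 ≈ 36%, CDH1 112/690 ≈ 16%).
  With latents i.i.d., the mutated count at any n is exactly binomial
  (n, target), which is what the calibration test checks.

What the phantom deliberately does *not* emulate: anatomy, DCE time
dynamics, scanner artifacts, spatial heterogeneity of real lesions, or any
correlation structure among the 17 latent features. Tests passing on this
cohort demonstrate that the pipeline's machinery — conditioning, training,
metrics, splits, reporting — works as specified; they say nothing about
performance on real MRI.

The default volume geometry is 32 × 128 × 128 voxels (slice axis first),
the grid to which the reference pipeline resizes all images. Tests and the
built-in benchmark use 8 × 32 × 32 so that CPU-only suites finish in
minutes; every network in the package accepts any shape whose entries are
multiples of 8 (three 2× up/down-sampling stages).

## The conditional GAN

`cgan_config()` defaults reproduce the reference training settings: batch
size 2, generator learning rate 2.5e-5, discriminator learning rate 1e-5,
least-squares (MSE) adversarial objective, 1200 epochs, leaky-ReLU slope
0.2. The "MSE loss" is read as the least-squares GAN: the discriminator is
regressed to 1 on real pairs and 0 on generated pairs, the generator to 1.

The network internals are not specified upstream beyond a schematic, so
they are this package's design, chosen as the smallest standard DCGAN-style
pair that trains reliably on one CPU:

* **Generator** — dense projection of the condition (plus optional noise
  input, off by default) to a coarse `shape/8` grid with `4*base_channels`
  channels; two transposed-conv (kernel 4, stride 2) blocks with instance
  normalization and leaky activations; a final non-overlapping 2×2×2
  transposed-conv expansion; tanh output in [−1, 1]. With `noise_dim = 0`
  generation is a pure deterministic function of the latent vector, which
  is how volumes are produced for patients without imaging.
* **Discriminator** — three non-overlapping 2×2×2 strided conv blocks over
  the volume alone, then the condition vector is broadcast-concatenated to
  the coarsest feature map as 17 constant channels, followed by a dense
  head with one leaky hidden layer. The hidden layer matters: a purely
  linear head after concatenation contributes an additive condition term
  that cancels between real and generated pairs sharing the same
  condition, leaving no conditioning gradient at all. The non-overlapping
  kernels keep the im2col working set roughly 8× smaller than overlapping
  kernel-4 convolutions at full resolution, which is what makes
  whole-suite CPU training practical; with a dense interaction head on
  top, the patch trunk loses little discriminative power at phantom scale
  (a freshly trained discriminator of this shape separates real from
  generated volumes essentially perfectly).

Three further training choices are load-bearing, and each was adopted
because its absence demonstrably breaks training at desk scale:

1. **Paired reconstruction term.** The generator objective is
   `adversarial + rec_weight · mean((G(c_i) − v_i)²)` with `rec_weight = 10`
   by default — the standard paired conditional-GAN (pix2pix-style)
   objective, available here because training data are (latent, volume)
   pairs by construction. With the purely adversarial objective the
   lesion-amplitude conditioning never aligns at this scale (rank
   correlation with the latent projection ≈ 0.1 after 200 epochs); with
   the paired term it exceeds 0.9. Setting `rec_weight = 0` recovers the
   purely adversarial game.
2. **Instance noise, annealed.** Gaussian noise (initial sd 0.1 on the
   tanh scale) is added to both real and generated volumes entering the
   discriminator, decaying linearly to zero over the first three quarters
   of training. A deterministic generator cannot reproduce i.i.d. voxel
   noise, so without this the discriminator wins on that single cue within
   a few epochs and the generator receives no usable gradient.
3. **Discriminator dropout** (p = 0.25 in the head). Dropout is part of
   the adversarial training recipe in this model family and keeps the
   discriminator from overpowering the generator between annealing steps.

One discriminator step then one generator step per minibatch; Adam with
default momentum terms for both players; no learning-rate schedules for
the GAN. All randomness (initialization, shuffling, instance noise,
optional noise inputs) flows from the config seed through R's RNG, so a
training run is bit-reproducible on a fixed machine with serial execution.

## Autoencoder baselines

Two conditional-reconstruction baselines mirror the reference comparison:
a conditional autoencoder (encoder–decoder under mean-squared
reconstruction loss) and a variant whose convolutional encoder trunk is
frozen at a fixed-seed random initialization, standing in for an external
pretrained backbone whose weights this package does not ship. A vanilla
autoencoder cannot generate from genomic features alone, so the bottleneck
is regressed onto the latent vector (`bridge_weight = 1`); generation
applies the decoder directly to the latent. The decoder reuses the
generator architecture, so the cGAN-vs-autoencoder comparison isolates the
objective, not the architecture.

## The Fréchet distance

Realism is scored as the squared Fréchet distance between Gaussians fitted
(mean, covariance with denominator n − 1) to deep features of the real and
generated sets:

d² = |μa − μb|² + Tr(Σa + Σb − 2 (Σa Σb)^{1/2}).

The cross term is computed from the eigendecomposition of the symmetrized
product `sqrt(Σa) Σb sqrt(Σa)` with eigenvalues clipped at zero; on
numerical failure a jitter of `1e-6 · mean(diag)` is added; the result is
clipped at zero. A brute-force oracle (eigenvalues of the non-symmetric
product Σa Σb) is kept in the test suite as an independent check; the two
agree to 1e-6 on random 5-dimensional PSD pairs.

The reference implementation extracts features with a pretrained 3D
medical-imaging network. Pretrained weights are external downloads, so the
default extractor here is a frozen, fixed-seed, randomly initialized 3D
conv net; any function mapping a volume to a feature vector can be
supplied instead. Feature design matters more than feature training for
this use: the extractor reports per-channel spatial mean *and* standard
deviation at two depths — after one conv stage (fine scale) and after
three (coarse scale). Mean-only, coarse-only features are blind to
sharpness: a blurred reconstruction and a sharp synthesis can score
identically, which defeats the purpose of the comparison. Because the
features are random rather than pretrained, absolute distances are on the
package's own scale and are not comparable to published values; orderings
between models evaluated with the same extractor are meaningful.

Uncertainty is reported as the standard deviation of the distance over
paired with-replacement resamples of both volume sets (`n_boot = 20` by
default; the upstream "±" is not defined anywhere we could consult, so the
bootstrap convention is this package's choice). `crossval_fid()` runs the
ten-fold protocol: train on nine folds, generate for the held-out latents,
score against the held-out reals, and keep the best (argmin) fold's model
for cohort-wide generation.

## Classifiers

The mutation CNN follows the reference architecture exactly where it is
specified: three 3D conv + max-pool blocks with 32, 16, 8 output channels,
flatten, a 128-unit fully-connected layer, dropout 0.5, and a single
sigmoid output; ReLU elsewhere. Kernel size 3, stride 1 and pool 2 are the
only common defaults compatible with three pool stages on a depth-32
input. Convolutions are 3D (the classifier consumes whole volumes). The
subtype variant removes the sigmoid and emits five raw class scores;
predicted class is the argmax. For numerical stability the sigmoid/softmax
is folded into the loss during training (mathematically identical
objective); `predict_proba()` always returns probabilities for the binary
model.

Training uses the configured optimizer (Adam by default; plain SGD
available), batch size 1 by default per the reference table (tests
override it for speed), binary or categorical cross-entropy, and a
reduce-on-plateau schedule: the learning rate is halved after 10 epochs
without improvement of the epoch training loss, never below 1e-6. Epoch
presets follow the reference budgets — 1300 (CDH1), 1500 (PIK3CA), 2000
(TP53) on generated volumes, 2500 for subtype, 300 for real-MRI models.

The multi-omic baseline is an L1-penalized logistic regression on the
latent features (`glmnet`), with the penalty chosen by internal
cross-validation on deterministic folds.

Evaluation conventions are pinned because hand-checked examples depend on
them: ROC-AUC is the Mann–Whitney concordance probability with half credit
for ties; PR-AUC uses step-wise interpolation (precision held between
achieved recall levels — trapezoidal PR interpolation is biased); macro
precision/recall/F1 average unweighted over classes, and a ratio with zero
denominator scores 0 with a warning. With all scores tied the PR curve
degenerates to a single point and its area equals the positive prevalence.

## Splits, folds, determinism

`split_train_test()` is stratified (default 20% test): per-stratum test
counts are `round(size · fraction)`, reconciled to `round(n · fraction)`
overall; strata with fewer than two members go to training with a warning.
The default splitting unit is the case (image), matching the reference
treatment of multiple MRIs per patient as separate cases;
`group_by_patient = TRUE` removes the patient-identity leak that the
per-case default allows. `kfold_indices()` partitions with fold sizes
differing by at most one. Both are pure functions of their inputs and
seed.

`run_all()` executes the whole design from one config: simulate → split →
k-fold cross-validated cGAN training with FID-based best-fold selection →
baseline training → cohort-wide generation → per-gene mutation experiments
over the real / generated / combined / omic-baseline arms → subtype
experiment over the generated / combined arms → consolidated JSON +
markdown report. One global seed fans out to per-stage seeds through a
fixed affine map, every stage writes its artifacts to files, and the
report contains no timestamps, so rerunning an identical config reproduces
`report.json` byte for byte (single-threaded execution assumed). The
command-line entry point `inst/scripts/radiogan-run.R` is a thin wrapper
over `validate_config()` and `run_all()`.

## Problem sizes and benchmark conditions

The built-in benchmark used by the end-to-end tests and the acceptance
script runs at n = 200 patients, 8 × 32 × 32 volumes, lesion effect 3 and
gene effect 4 aligned on the first latent feature, noise sd 0.05; the cGAN
trains for 200 epochs (batch 16, generator lr 4e-4, discriminator lr 1e-4,
base width 6), the autoencoder for the same 200 epochs, and the mutation
CNN for 5 epochs at batch 16 — the signal is a single intensity axis, so
the classifier converges within a few epochs. These sizes were chosen once
as the smallest configuration on which the scientific orderings
(signal recovery above 0.8 AUC, permutation null at chance, cGAN FID below
the autoencoder's and far below an untrained generator's) are stable
across seeds on a single CPU.

## Known limitations

* The engine is a minimal educational-grade implementation: dense/conv/
  transposed-conv/pool layers with Adam, single-threaded, float64. It is
  validated by finite-difference gradient checks but makes no attempt at
  GPU execution or large-scale performance.
* The phantom world is intentionally low-dimensional; a model family this
  small would not produce diagnostic-quality images, and no claim of that
  kind is made.
* Absolute FID values depend on the frozen random extractor and are not
  comparable across extractors or to published numbers.
* Instance-noise annealing and the paired reconstruction term are
  stabilizers chosen for desk-scale reliability; at full scale with rich
  data other balances may be preferable, and both are exposed as config
  knobs (`instance_noise_sd`, `rec_weight`).
* Bit-reproducibility holds for fixed BLAS and thread count; exact bytes
  may differ across numerics libraries.
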