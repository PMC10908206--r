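# Small shared fixtures, built in code. The minimal GAN-compatible volume
# shape is 8x8x8 (three 2x stages); cohort-level tests use it so training
# exercises run in seconds.

toy_shape <- c(8L, 8L, 8L)

toy_gene_specs <- function(latent_dim = 5L, effect = 2, intercept = 0) {
  list(list(gene = "TP53",
            effect = c(effect, rep(0, latent_dim - 1)),
            intercept = intercept))
}

toy_spec <- function(n = 12L, latent_dim = 5L, shape = toy_shape,
                     noise_sd = 0.05, seed = 42L, ...) {
  cohort_spec(n_patients = n, latent_dim = latent_dim, volume_shape = shape,
              gene_specs = toy_gene_specs(latent_dim),
              subtype_coeffs = default_subtype_coeffs(latent_dim),
              lesion_effect = c(2, rep(0, latent_dim - 1)),
              noise_sd = noise_sd, seed = seed, ...)
}

toy_cohort <- function(n = 12L, ...) simulate_cohort(toy_spec(n = n, ...))

toy_cgan_config <- function(epochs = 3L, seed = 1L, ...) {
  cgan_config(volume_shape = toy_shape, cond_dim = 5L, epochs = epochs,
              batch_size = 4L, lr_generator = 4e-4, lr_discriminator = 1e-4,
              base_channels = 4L, seed = seed, ...)
}

# gather all volumes of a record list
all_volumes <- function(records) {
  unlist(lapply(records, `[[`, "volumes"), recursive = FALSE)
}

latents_of <- function(records) {
  do.call(rbind, lapply(records, `[[`, "latent"))
}

labels_of <- function(records, key) {
  vapply(records, function(r) {
    if (identical(key, "subtype")) r$subtype else r$mutation_labels[[key]]
  }, numeric(1))
}
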