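test_that("simulate_cohort honors size, latent dimension and determinism", {
  expect_length(simulate_cohort(toy_spec(n = 0L)), 0L)

  spec <- cohort_spec(n_patients = 3L, volume_shape = c(8L, 8L, 8L),
                      noise_sd = 0.02, seed = 9L)
  cohort <- simulate_cohort(spec)
  expect_length(cohort, 3L)
  expect_true(all(vapply(cohort, function(r) length(r$latent), integer(1)) == 17L))
  expect_true(all(vapply(cohort, function(r) r$subtype %in% 0:4, logical(1))))
  expect_true(all(unlist(lapply(cohort, function(r) r$mutation_labels)) %in% 0:1))

  # byte-identical serialization for identical specs
  again <- simulate_cohort(cohort_spec(n_patients = 3L,
                                       volume_shape = c(8L, 8L, 8L),
                                       noise_sd = 0.02, seed = 9L))
  expect_identical(serialize(cohort, NULL), serialize(again, NULL))
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_patients = -1L), "n_patients")
  expect_error(cohort_spec(n_patients = 2L, volume_shape = c(2L, 8L, 8L)),
               "volume_shape")
  expect_error(cohort_spec(n_patients = 2L, noise_sd = -0.1), "noise_sd")
  expect_error(cohort_spec(n_patients = 2L, latent_dim = 4L,
                           lesion_effect = c(1, 0)), "length")
})

test_that("calibrated intercepts reproduce the target mutation prevalences", {
  # TP53 default: marginal prevalence 235/690 at n = 690, with nonzero
  # effects the count is still binomial(n, target) in distribution
  spec <- cohort_spec(n_patients = 690L, volume_shape = c(8L, 8L, 8L),
                      seed = 31L)
  cohort <- simulate_cohort(spec)
  counts <- colSums(do.call(rbind, lapply(cohort, `[[`, "mutation_labels")))
  targets <- round(690 * radiogan:::gene_target_prevalence)
  for (g in names(targets)) {
    band <- qbinom(c(0.005, 0.995), 690, radiogan:::gene_target_prevalence[[g]])
    expect_gte(counts[[g]], band[1])
    expect_lte(counts[[g]], band[2])
  }
})

test_that("assign_labels follows the logistic / softmax model", {
  d <- 5L
  zero_specs <- list(list(gene = "G1", effect = rep(0, d), intercept = 0))
  zero_coeffs <- matrix(0, 5, d)

  draws <- vapply(1:10000, function(i) {
    assign_labels(rnorm(d), zero_specs, zero_coeffs, seed = i)$mutation_labels[["G1"]]
  }, integer(1))
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)

  # saturated logistic: intercept -50 forces label 0
  sat <- list(list(gene = "G1", effect = rep(0, d), intercept = -50))
  expect_true(all(vapply(1:50, function(i) {
    assign_labels(rnorm(d), sat, zero_coeffs, seed = i)$mutation_labels[["G1"]]
  }, integer(1)) == 0L))

  # zero subtype coefficients: uniform over the 5 classes
  subs <- vapply(1:10000, function(i) {
    assign_labels(rnorm(d), zero_specs, zero_coeffs, seed = i)$subtype
  }, integer(1))
  freqs <- tabulate(subs + 1L, 5L) / 10000
  expect_true(all(abs(freqs - 0.2) < 3 * sqrt(0.2 * 0.8 / 10000) + 0.01))

  expect_error(assign_labels(rnorm(3), zero_specs, zero_coeffs, seed = 1),
               "latent_dim")
})

test_that("calibrate_intercept solves the marginal prevalence equation", {
  eff <- c(2, 0, 0)
  b <- calibrate_intercept(0.34, eff)
  sims <- plogis(b + sqrt(sum(eff^2)) * qnorm((1:20000 - 0.5) / 20000))
  expect_lt(abs(mean(sims) - 0.34), 1e-3)
  expect_equal(calibrate_intercept(0.25, c(0, 0)), qlogis(0.25))
})

test_that("render_phantom is deterministic and shape/range clean", {
  z <- rep(0, 5)
  eff <- c(1, rep(0, 4))
  v1 <- render_phantom(z, c(8L, 16L, 16L), eff, noise_sd = 0, seed = 1L)
  v2 <- render_phantom(z, c(8L, 16L, 16L), eff, noise_sd = 0, seed = 99L)
  expect_identical(v1$data, v2$data)   # zero noise: seed irrelevant
  expect_equal(dim(v1), c(8L, 16L, 16L))
  expect_true(all(v1$data >= 0 & v1$data <= 1))

  n1 <- render_phantom(z, c(8L, 16L, 16L), eff, noise_sd = 0.1, seed = 5L)
  n2 <- render_phantom(z, c(8L, 16L, 16L), eff, noise_sd = 0.1, seed = 5L)
  expect_identical(n1$data, n2$data)   # bit-identical under a fixed seed
})

test_that("lesion intensity increases monotonically with the latent projection", {
  eff <- c(1, rep(0, 4))
  mask <- radiogan:::lesion_mask(c(8L, 16L, 16L))
  means <- vapply(c(-2, 0, 2), function(x1) {
    v <- render_phantom(c(x1, rep(0, 4)), c(8L, 16L, 16L), eff,
                        noise_sd = 0, seed = 1L)
    mean(v$data[mask])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
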