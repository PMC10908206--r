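# Independent oracle: the trace of the matrix square root of Sa %*% Sb via a
# brute-force eigendecomposition of the (non-symmetric) product, kept apart
# from the package's symmetrized implementation path.
frechet_oracle <- function(mu_a, sig_a, mu_b, sig_b) {
  ev <- eigen(sig_a %*% sig_b, only.values = TRUE)$values
  tr_cross <- sum(sqrt(pmax(Re(ev), 0)))
  sum((mu_a - mu_b)^2) + sum(diag(sig_a)) + sum(diag(sig_b)) - 2 * tr_cross
}

rand_psd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.1
}

gstats <- function(mu, sig) {
  structure(list(mean = mu, cov = sig, n = 100L), class = "gaussian_stats")
}

test_that("fit_gaussian computes mean and n-1 covariance with symmetry", {
  f <- fit_gaussian(rbind(c(0, 0), c(2, 2)))
  expect_equal(f$mean, c(1, 1))
  expect_equal(f$cov, matrix(2, 2, 2))
  same <- fit_gaussian(matrix(3, 4, 2))
  expect_true(all(same$cov == 0))
  expect_error(fit_gaussian(matrix(1, 1, 2)), "at least 2")
})

test_that("frechet_distance matches hand cases and the identity", {
  s <- fit_gaussian(matrix(rnorm(50 * 3), 50))
  expect_lt(frechet_distance(s, s), 1e-8)
  # univariate, means 0 vs 1, unit variances: distance 1
  expect_equal(frechet_distance(gstats(0, matrix(1)), gstats(1, matrix(1))),
               1.0, tolerance = 1e-12)
  # commuting case: equal means, I vs 4I in d=2 -> Tr(I + 4I - 2*2I) = 2
  expect_equal(frechet_distance(gstats(c(0, 0), diag(2)),
                                gstats(c(0, 0), 4 * diag(2))),
               2.0, tolerance = 1e-12)
  expect_error(frechet_distance(gstats(0, matrix(1)),
                                gstats(c(0, 0), diag(2))), "dimension")
})

test_that("frechet_distance agrees with the eigendecomposition oracle on random 5-dim pairs", {
  set.seed(99)
  for (i in 1:100) {
    sa <- rand_psd(5); sb <- rand_psd(5)
    ma <- rnorm(5); mb <- rnorm(5)
    got <- frechet_distance(gstats(ma, sa), gstats(mb, sb))
    want <- frechet_oracle(ma, sa, mb, sb)
    expect_lt(abs(got - want), 1e-6)
  }
})

test_that("frechet_distance is symmetric and increases with mean separation", {
  set.seed(7)
  sa <- rand_psd(4); sb <- rand_psd(4)
  ma <- rnorm(4); mb <- rnorm(4)
  expect_lt(abs(frechet_distance(gstats(ma, sa), gstats(mb, sb)) -
                frechet_distance(gstats(mb, sb), gstats(ma, sa))), 1e-8)
  dists <- vapply(c(0, 1, 2, 4), function(s) {
    frechet_distance(gstats(ma, sa), gstats(ma + s, sa))
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("extract_features is deterministic with the documented shape", {
  ex <- make_feature_extractor(toy_shape, feature_dim = 16L, seed = 3L)
  cohort <- toy_cohort(n = 5L)
  f <- extract_features(all_volumes(cohort), ex)
  expect_equal(dim(f), c(5L, 16L))
  dup <- extract_features(rep(all_volumes(cohort)[1], 3), ex)
  expect_true(all(dup[1, ] == dup[2, ]) && all(dup[2, ] == dup[3, ]))
  zeros <- replicate(3, volume3d(array(0, toy_shape)), simplify = FALSE)
  fz <- extract_features(zeros, ex)
  expect_true(all(fz[1, ] == fz[2, ]))
  wrong <- list(volume3d(array(0, c(16, 8, 8))))
  expect_error(extract_features(wrong, ex), "does not match")
  # custom function extractors are accepted
  ff <- extract_features(all_volumes(cohort), function(v) c(mean(v$data), sd(v$data)))
  expect_equal(dim(ff), c(5L, 2L))
})

test_that("fid_with_uncertainty behaves at the identity and degenerate n_boot", {
  cohort <- toy_cohort(n = 10L)
  vols <- all_volumes(cohort)
  ex <- make_feature_extractor(toy_shape, feature_dim = 16L, seed = 3L)
  same <- fid_with_uncertainty(vols, vols, ex, n_boot = 20L, seed = 1L)
  other <- fid_with_uncertainty(vols, lapply(vols, function(v) {
    volume3d(1 - v$data, v$range)
  }), ex, n_boot = 20L, seed = 1L)
  expect_gte(same$mean, 0)
  expect_lt(same$mean, 0.05 * other$mean)
  one <- fid_with_uncertainty(vols[1:5], vols[6:10], ex, n_boot = 1L, seed = 2L)
  expect_equal(one$spread, 0)
  expect_error(fid_with_uncertainty(vols[1], vols, ex), ">= 2")
})

test_that("bootstrap FID recovers the closed-form distance for Gaussian features", {
  set.seed(11)
  d <- 3L
  mu_a <- c(0, 0, 0); mu_b <- c(1, 0.5, 0)
  sig_a <- diag(d); sig_b <- 2 * diag(d)
  closed <- frechet_oracle(mu_a, sig_a, mu_b, sig_b)
  fa <- matrix(rnorm(400 * d), ncol = d)
  fb <- sweep(matrix(rnorm(400 * d, sd = sqrt(2)), ncol = d), 2, mu_b, `+`)
  boot <- radiogan:::fid_features_boot(fa, fb, n_boot = 40L, seed = 4L)
  se <- boot$spread / sqrt(40)
  # bootstrap mean is biased upward by sampling noise at finite n; allow the
  # closed form to sit within 3 bootstrap sd of the estimate
  expect_lt(abs(boot$mean - closed), 3 * boot$spread + 0.05 * closed)
})

test_that("crossval_fid trains per fold, tables results and retains the best model", {
  cohort <- toy_cohort(n = 12L)
  ex <- make_feature_extractor(toy_shape, feature_dim = 16L, seed = 3L)
  cv <- crossval_fid(
    cohort,
    train_fn = function(recs, seed) train_cgan(recs, toy_cgan_config(epochs = 2L, seed = seed)),
    generate_fn = function(m, lat) generate_volumes(m, lat),
    extractor = ex, k = 3L, n_boot = 3L, seed = 21L)
  expect_equal(nrow(cv$table), 3L)
  expect_equal(cv$best_fold, which.min(cv$table$fid_mean))
  expect_s3_class(cv$best_model, "cgan_checkpoint")
  cv2 <- crossval_fid(
    cohort,
    train_fn = function(recs, seed) train_cgan(recs, toy_cgan_config(epochs = 2L, seed = seed)),
    generate_fn = function(m, lat) generate_volumes(m, lat),
    extractor = ex, k = 3L, n_boot = 3L, seed = 21L)
  expect_identical(cv$table, cv2$table)
})
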