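test_that("mutation CNN exposes the reference architecture", {
  cfg <- cnn_config(volume_shape = c(8L, 32L, 32L), task = "TP53")
  model <- local({ set.seed(1); build_mutation_cnn(cfg) })
  expect_equal(cfg$conv_channels, c(32L, 16L, 8L))
  expect_equal(cfg$fc_hidden, 128L)
  expect_equal(cfg$dropout_p, 0.5)
  expect_equal(cfg$batch_size, 1L)
  expect_equal(cfg$optimizer, "Adam")
  expect_identical(model$head, "sigmoid")
  conv_layers <- Filter(function(l) l$type == "conv3", model$net$layers)
  expect_equal(vapply(conv_layers, function(l) dim(l$par$w)[5], integer(1)),
               c(32L, 16L, 8L))
  dense_layers <- Filter(function(l) l$type == "dense", model$net$layers)
  expect_equal(nrow(dense_layers[[1]]$par$w), 128L)
  expect_equal(nrow(dense_layers[[2]]$par$w), 1L)
  drop_layers <- Filter(function(l) l$type == "dropout", model$net$layers)
  expect_equal(drop_layers[[1]]$p, 0.5)
})

test_that("per-task epoch presets match the reference budgets", {
  expect_equal(cnn_epoch_presets[["CDH1"]], 1300L)
  expect_equal(cnn_epoch_presets[["PIK3CA"]], 1500L)
  expect_equal(cnn_epoch_presets[["TP53"]], 2000L)
  expect_equal(cnn_epoch_presets[["subtype"]], 2500L)
  expect_equal(cnn_epoch_presets[["real"]], 300L)
  expect_equal(cnn_config(volume_shape = c(8L, 32L, 32L), task = "PIK3CA")$epochs,
               1500L)
  expect_equal(cnn_config(volume_shape = c(8L, 32L, 32L), task = "subtype")$n_outputs,
               5L)
})

test_that("binary forward pass yields probabilities strictly inside (0, 1)", {
  cfg <- cnn_config(volume_shape = toy_shape, task = "TP53", epochs = 1L)
  model <- local({ set.seed(2); build_mutation_cnn(cfg) })
  zero <- list(volume3d(array(0, toy_shape)))
  p <- predict_proba(model, zero)
  expect_true(p > 0 && p < 1)
  cohort <- toy_cohort(n = 4L)
  p1 <- predict_proba(model, all_volumes(cohort))
  p2 <- predict_proba(model, all_volumes(cohort))
  expect_identical(p1, p2)  # dropout disabled at evaluation
  expect_length(p1, 4L)
})

test_that("subtype CNN emits five raw scores with argmax in the subtype coding", {
  cfg <- cnn_config(volume_shape = toy_shape, task = "subtype", epochs = 1L)
  model <- local({ set.seed(3); build_subtype_cnn(cfg) })
  expect_identical(model$head, "linear")
  cohort <- toy_cohort(n = 6L)
  s <- predict_proba(model, all_volumes(cohort))
  expect_equal(dim(s), c(6L, 5L))
  expect_true(all(is.finite(s)))
  expect_true(all((max.col(s) - 1L) %in% 0:4))
  # permuting the batch permutes outputs identically
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  s2 <- predict_proba(model, all_volumes(cohort)[perm])
  expect_equal(s2, s[perm, ])
})

test_that("volume shapes too small for three poolings are rejected with the minimum", {
  expect_error(cnn_config(volume_shape = c(4L, 32L, 32L), task = "TP53"),
               "minimum shape")
})

test_that("classifier training is seeded-deterministic with finite losses", {
  cohort <- toy_cohort(n = 16L)
  cfg <- cnn_config(volume_shape = toy_shape, task = "TP53", epochs = 3L,
                    batch_size = 4L, learning_rate = 1e-3, seed = 4L)
  m1 <- train_classifier(build_mutation_cnn(cfg), cohort)
  m2 <- train_classifier(build_mutation_cnn(cfg), cohort)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(lapply(m1$net$layers, `[[`, "par"),
                   lapply(m2$net$layers, `[[`, "par"))
  expect_true(all(is.finite(m1$loss_history$loss)))

  single <- lapply(cohort, function(r) { r$mutation_labels[["TP53"]] <- 1L; r })
  expect_error(train_classifier(build_mutation_cnn(cfg), single),
               "single class")
})

test_that("subtype training with categorical cross-entropy runs and converges sanely", {
  cohort <- toy_cohort(n = 20L, seed = 23L)
  cfg <- cnn_config(volume_shape = toy_shape, task = "subtype", epochs = 4L,
                    batch_size = 4L, learning_rate = 1e-3, seed = 5L)
  m <- train_classifier(build_subtype_cnn(cfg), cohort)
  expect_true(all(is.finite(m$loss_history$loss)))
  expect_lte(m$loss_history$loss[4], m$loss_history$loss[1] + 0.5)
})

test_that("L1 logistic baseline: separable, null and zero-variance behavior", {
  set.seed(6)
  n <- 400
  x <- cbind(rnorm(n), rnorm(n), 0)   # third feature has zero variance
  y_sep <- as.integer(x[, 1] > 0)
  fit <- logistic_l1_baseline(x, y_sep, test_split = 0.2, seed = 1L)
  expect_equal(roc_curve_auc(fit$test$truth, fit$test$prob)$auc, 1.0)
  expect_equal(unname(fit$coefficients["V3"]), 0)

  y_null <- sample(y_sep)
  fit0 <- logistic_l1_baseline(x, y_null, test_split = 0.2, seed = 2L)
  auc0 <- roc_curve_auc(fit0$test$truth, fit0$test$prob)$auc
  expect_gte(auc0, 0.35)
  expect_lte(auc0, 0.65)

  expect_error(logistic_l1_baseline(x, rep(1, n)), "single class")
})
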