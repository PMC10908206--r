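test_that("volume round-trips losslessly through NIfTI and rds", {
  dir <- withr::local_tempdir()
  set.seed(1)
  v <- volume3d(array(runif(8 * 32 * 32), c(8, 32, 32)), range = c(0, 1))
  for (ext in c("nii", "nii.gz", "rds")) {
    p <- file.path(dir, paste0("vol.", ext))
    write_volume(v, p)
    r <- read_volume(p)
    expect_equal(dim(r), c(8L, 32L, 32L))
    expect_lt(max(abs(r$data - v$data)), 1e-6)
    expect_equal(r$range, c(0, 1))
  }
  # zero volume at full study resolution
  z <- volume3d(array(0, c(32, 128, 128)))
  p <- file.path(dir, "zero.nii.gz")
  write_volume(z, p)
  expect_true(all(read_volume(p)$data == 0))
})

test_that("read_volume errors name the offending path", {
  bad <- file.path(tempdir(), "does-not-exist.nii.gz")
  expect_error(read_volume(bad), "does-not-exist")
  expect_error(write_volume(volume3d(array(0, c(4, 4, 4))), "vol.xyz"),
               "unsupported")
})

test_that("resize_volume matches the identity / constant / target-shape contracts", {
  set.seed(2)
  v <- volume3d(array(runif(32 * 128 * 128), c(32, 128, 128)))
  same <- resize_volume(v, c(32L, 128L, 128L))
  expect_identical(same$data, v$data)

  big <- volume3d(array(runif(64 * 256 * 256), c(64, 256, 256)))
  small <- resize_volume(big)
  expect_equal(dim(small), c(32L, 128L, 128L))

  const <- resize_volume(volume3d(array(0.7, c(10, 20, 30))), c(7L, 13L, 40L))
  expect_lt(max(abs(const$data - 0.7)), 1e-6)
})

test_that("resize then resize back recovers a smooth phantom within 5% of range", {
  v <- render_phantom(c(1, 0, 0), c(16L, 32L, 32L), c(1, 0, 0),
                      noise_sd = 0, seed = 1L)
  down_up <- resize_volume(resize_volume(v, c(8L, 16L, 16L)), c(16L, 32L, 32L))
  expect_lt(mean(abs(down_up$data - v$data)), 0.05)
})

test_that("normalize_intensity maps ranges and degenerate input correctly", {
  v <- volume3d(array(c(0, 5, 10, 0, 5, 10, 0, 10), c(2, 2, 2)),
                range = c(0, 10))
  mm <- normalize_intensity(v, "minmax")
  expect_equal(sort(unique(as.vector(mm$data))), c(0, 0.5, 1))
  th <- normalize_intensity(v, "tanh")
  expect_equal(sort(unique(as.vector(th$data))), c(-1, 0, 1))
  flat <- normalize_intensity(volume3d(array(3, c(2, 2, 2)), c(0, 10)), "minmax")
  expect_true(all(flat$data == 0.5))
})

test_that("stratified 20% split of n=690 gives 138 test cases with matched prevalence", {
  spec <- cohort_spec(n_patients = 690L, volume_shape = c(8L, 8L, 8L),
                      seed = 77L)
  cohort <- simulate_cohort(spec)
  spl <- split_train_test(cohort, 0.2, stratify_key = "TP53", seed = 3L)
  expect_length(spl$test, 138L)
  expect_length(spl$train, 690L - 138L)
  expect_length(intersect(vapply(spl$test, `[[`, character(1), "patient_id"),
                          vapply(spl$train, `[[`, character(1), "patient_id")),
                0L)
  prev_all <- mean(labels_of(cohort, "TP53"))
  prev_test <- mean(labels_of(spl$test, "TP53"))
  expect_lte(abs(prev_test - prev_all), 1 / 138 + 1e-12)

  again <- split_train_test(cohort, 0.2, stratify_key = "TP53", seed = 3L)
  expect_identical(vapply(spl$test, `[[`, character(1), "patient_id"),
                   vapply(again$test, `[[`, character(1), "patient_id"))
})

test_that("strata with fewer than two members are kept in train with a warning", {
  cohort <- toy_cohort(n = 9L)
  for (i in seq_along(cohort)) cohort[[i]]$subtype <- c(rep(0L, 8), 4L)[i]
  expect_warning(spl <- split_train_test(cohort, 0.3, "subtype", seed = 1L),
                 "< 2 members")
  expect_false(any(vapply(spl$test, `[[`, integer(1), "subtype") == 4L))
})

test_that("kfold_indices partitions with near-equal sizes", {
  folds <- kfold_indices(58, 10, seed = 4L)
  sizes <- unname(vapply(folds, length, integer(1)))
  expect_equal(sort(sizes), c(5L, 5L, rep(6L, 8)))
  expect_setequal(unlist(folds), 1:58)

  singletons <- kfold_indices(10, 10, seed = 1L)
  expect_true(all(lengths(singletons) == 1L))

  expect_error(kfold_indices(5, 10, seed = 1L), "must be >=")
  expect_identical(kfold_indices(37, 5, seed = 9L),
                   kfold_indices(37, 5, seed = 9L))
})

test_that("cohort write/read round-trips records, labels and latents", {
  dir <- withr::local_tempdir()
  cohort <- toy_cohort(n = 4L)
  write_cohort(cohort, dir, format = "nii.gz")
  back <- read_cohort(dir)
  expect_length(back, 4L)
  expect_equal(labels_of(back, "TP53"), labels_of(cohort, "TP53"))
  expect_equal(latents_of(back), latents_of(cohort), tolerance = 1e-6)
  expect_lt(max(abs(back[[2]]$volumes[[1]]$data - cohort[[2]]$volumes[[1]]$data)),
            1e-6)
})

test_that("expand_cases treats multiple volumes per patient as separate cases", {
  cohort <- simulate_cohort(toy_spec(n = 3L, volumes_per_patient = 2L))
  cases <- expand_cases(cohort)
  expect_length(cases, 6L)
  expect_true(all(lengths(lapply(cases, `[[`, "volumes")) == 1L))
})
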