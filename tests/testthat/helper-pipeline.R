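# A miniature but complete pipeline configuration (every stage runs) and a
# cached first run shared between the integration test and the determinism
# check, which needs two independent executions of the same config.

tiny_config <- function(seed = 1L) {
  list(
    seed = seed,
    cohort = list(n_patients = 40L, volume_shape = c(8L, 32L, 32L)),
    cgan = list(epochs = 8L, batch_size = 16L, base_channels = 4L),
    baseline = list(epochs = 6L, base_channels = 4L),
    fid = list(k_folds = 2L, n_boot = 4L, feature_dim = 16L),
    classifier = list(epochs = 3L, batch_size = 8L),
    genes = "TP53",
    test_fraction = 0.2
  )
}

.pipeline_cache <- new.env(parent = emptyenv())

cached_tiny_run <- function() {
  if (is.null(.pipeline_cache$run)) {
    dir <- file.path(tempdir(), "radiogan-tiny-run")
    unlink(dir, recursive = TRUE)
    res <- suppressWarnings(suppressMessages(run_all(tiny_config(), dir)))
    .pipeline_cache$run <- list(
      dir = dir, report = res$report,
      json = readBin(file.path(dir, "report.json"),
                     what = "raw",
                     n = file.size(file.path(dir, "report.json"))))
  }
  .pipeline_cache$run
}
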