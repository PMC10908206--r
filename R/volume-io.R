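# Reading, writing, resizing, normalizing and splitting 3D volumes and
# cohort tables. NIfTI I/O goes through RNifti; an R-native serialized
# format (.rds) is supported as the compressed-archive alternative.

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.rds$", path)) "rds"
  else stop("unsupported volume format for path: ", path)
}

#' Write a 3D volume to disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; the declared intensity range
#' is stored in the cal_min/cal_max header fields) and R-native serialized
#' `.rds`. Round-trip write/read preserves data to float storage precision.
#'
#' @param volume a [volume3d()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_volume: directory does not exist: ", dir)
  switch(volume_format(path),
    nifti = {
      img <- RNifti::asNifti(volume$data,
                             cal_min = volume$range[1], cal_max = volume$range[2])
      RNifti::writeNifti(img, path)
    },
    rds = saveRDS(volume, path)
  )
  invisible(path)
}

#' Read a 3D volume from disk
#'
#' @param path path to a `.nii`, `.nii.gz` or `.rds` volume.
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file does not exist: ", path)
  switch(volume_format(path),
    nifti = {
      img <- tryCatch(RNifti::readNifti(path),
                      error = function(e) stop("read_volume: malformed NIfTI at ",
                                               path, ": ", conditionMessage(e)))
      arr <- as.array(img)
      if (length(dim(arr)) != 3L) stop("read_volume: expected a 3D image at ", path)
      hdr <- RNifti::niftiHeader(img)
      rng <- c(hdr$cal_min, hdr$cal_max)
      if (!all(is.finite(rng)) || rng[2] <= rng[1]) rng <- c(0, 1)
      volume3d(arr, range = rng)
    },
    rds = {
      v <- readRDS(path)
      if (!inherits(v, "volume3d")) stop("read_volume: ", path,
                                         " does not contain a volume3d")
      v
    }
  )
}

# 1D linear interpolation along the first axis of a 3D array, pixel-centre
# aligned so identity sizes and constant inputs are preserved exactly.
resize_axis1 <- function(x, t_len) {
  s_len <- dim(x)[1]
  if (t_len == s_len) return(x)
  src <- (seq_len(t_len) - 0.5) * s_len / t_len + 0.5
  lo <- pmax(1L, pmin(s_len, floor(src)))
  hi <- pmin(s_len, lo + 1L)
  w <- pmax(0, pmin(1, src - lo))
  y <- x[lo, , , drop = FALSE] * (1 - w) + x[hi, , , drop = FALSE] * w
  y
}

#' Resize a volume by trilinear interpolation
#'
#' Standardizes volumes to a common grid (the reference pipeline resizes all
#' images to 32 x 128 x 128). Separable linear interpolation per axis;
#' constant volumes map to the same constant and identity targets return the
#' data unchanged.
#'
#' @param volume a [volume3d()].
#' @param target_shape (depth, height, width), all positive.
#' @return Resized [volume3d()] with the same declared range.
#' @export
resize_volume <- function(volume, target_shape = c(32L, 128L, 128L)) {
  stopifnot(inherits(volume, "volume3d"))
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("resize_volume: `target_shape` must be 3 positive entries")
  }
  x <- volume$data
  x <- resize_axis1(x, target_shape[1])
  x <- aperm(resize_axis1(aperm(x, c(2L, 1L, 3L)), target_shape[2]), c(2L, 1L, 3L))
  x <- aperm(resize_axis1(aperm(x, c(3L, 2L, 1L)), target_shape[3]), c(3L, 2L, 1L))
  volume3d(x, range = volume$range, view = volume$view)
}

#' Normalize volume intensities
#'
#' `"minmax"` maps the observed min/max to \[0, 1\]; `"tanh"` maps to
#' \[-1, 1\] (the generator's output range). A constant volume maps to the
#' midpoint of the target range.
#'
#' @param volume a [volume3d()].
#' @param mode `"minmax"` or `"tanh"`.
#' @return Normalized [volume3d()] with the matching declared range.
#' @export
normalize_intensity <- function(volume, mode = c("minmax", "tanh")) {
  mode <- match.arg(mode)
  x <- volume$data
  lo <- min(x); hi <- max(x)
  tgt <- if (mode == "minmax") c(0, 1) else c(-1, 1)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    y <- array(mean(tgt), dim(x))
  } else {
    y <- tgt[1] + (x - lo) / (hi - lo) * (tgt[2] - tgt[1])
  }
  volume3d(y, range = tgt, view = volume$view)
}

# Label of a record under a stratification key ("subtype" or a gene name).
record_label <- function(record, key) {
  if (identical(key, "subtype")) record$subtype
  else if (key %in% names(record$mutation_labels)) record$mutation_labels[[key]]
  else stop("unknown stratification key: ", key)
}

#' Expand multi-volume patients into one case per volume
#'
#' Mirrors the reference treatment of multiple MRIs from the same patient as
#' separate cases.
#'
#' @param records list of patient records.
#' @return List of single-volume records (patient ids preserved).
#' @export
expand_cases <- function(records) {
  out <- list()
  for (r in records) {
    for (v in r$volumes) {
      rr <- r
      rr$volumes <- list(v)
      out[[length(out) + 1L]] <- rr
    }
  }
  out
}

#' Stratified train/test split
#'
#' Per-stratum test counts are `round(stratum_size * fraction)`, adjusted so
#' the total equals `round(n * fraction)`; strata with fewer than 2 members
#' are placed in the training set with a warning. By default the split is
#' per case (per image); set `group_by_patient = TRUE` to split whole
#' patients.
#'
#' @param records list of patient records.
#' @param test_fraction fraction in (0, 1) (default 0.2, the reference
#'   protocol's test share).
#' @param stratify_key `"subtype"` or a gene name present in
#'   `mutation_labels`.
#' @param seed integer seed; membership is a pure function of inputs + seed.
#' @param group_by_patient split patients rather than cases.
#' @return `list(train =, test =)` of record lists (disjoint, exhaustive).
#' @export
split_train_test <- function(records, test_fraction = 0.2, stratify_key,
                             seed = 1L, group_by_patient = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("split_train_test: `test_fraction` must be in (0, 1)")
  }
  units <- if (group_by_patient) records else expand_cases(records)
  n <- length(units)
  labels <- vapply(units, record_label, numeric(1), key = stratify_key)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  strata <- split(seq_len(n), labels)
  total_target <- round(n * test_fraction)
  sizes <- vapply(strata, length, integer(1))
  counts <- round(sizes * test_fraction)
  small <- sizes < 2L
  if (any(small)) {
    warning("split_train_test: strata with < 2 members placed in train: ",
            paste(names(strata)[small], collapse = ", "))
    counts[small] <- 0L
  }
  # reconcile rounding so the overall test size is round(n * fraction)
  adjustable <- which(!small)
  diff <- total_target - sum(counts)
  while (diff != 0 && length(adjustable) > 0) {
    if (diff > 0) {
      room <- adjustable[counts[adjustable] < sizes[adjustable]]
      if (!length(room)) break
      i <- room[which.max(sizes[room] - counts[room])]
      counts[i] <- counts[i] + 1L
      diff <- diff - 1L
    } else {
      room <- adjustable[counts[adjustable] > 0L]
      if (!length(room)) break
      i <- room[which.min(sizes[room] - counts[room])]
      counts[i] <- counts[i] - 1L
      diff <- diff + 1L
    }
  }
  test_idx <- integer(0)
  for (j in seq_along(strata)) {
    if (counts[j] > 0L) {
      test_idx <- c(test_idx, sort(sample(strata[[j]], counts[j])))
    }
  }
  test_idx <- sort(test_idx)
  list(train = units[setdiff(seq_len(n), test_idx)], test = units[test_idx])
}

#' Disjoint k-fold indices
#'
#' Partitions `1..n` into `k` folds with sizes differing by at most one
#' (used by the ten-fold cross-validated FID protocol). Deterministic given
#' the seed.
#'
#' @param n number of items (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of `k` integer vectors partitioning `seq_len(n)`.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k < 2L) stop("kfold_indices: `k` must be >= 2")
  if (n < k) stop("kfold_indices: `n` (", n, ") must be >= `k` (", k, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

#' Write a cohort to a directory (volumes + manifest + latent matrix)
#'
#' Emits one volume file per case, a `manifest.csv` with patient id, subtype,
#' one 0/1 column per gene and the volume path, and a `latents.csv` with
#' `patient_id, latent_0..latent_{d-1}`.
#'
#' @param records list of patient records.
#' @param dir output directory (created if missing).
#' @param format `"nii.gz"`, `"nii"` or `"rds"`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(records, dir, format = "nii.gz") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in records) {
    for (j in seq_along(r$volumes)) {
      fn <- sprintf("%s_v%02d.%s", r$patient_id, j, format)
      write_volume(r$volumes[[j]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = r$patient_id, subtype = r$subtype,
        as.list(r$mutation_labels), provenance = r$provenance,
        volume = fn, check.names = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  lat <- cohort_latents(records)
  colnames(lat) <- paste0("latent_", seq_len(ncol(lat)) - 1L)
  utils::write.csv(data.frame(patient_id = vapply(records, `[[`, character(1), "patient_id"),
                              lat, check.names = FALSE),
                   file.path(dir, "latents.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv` and `latents.csv`.
#' @return List of patient records (one record per patient; volumes grouped).
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("read_cohort: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, check.names = FALSE)
  lat <- utils::read.csv(file.path(dir, "latents.csv"), check.names = FALSE)
  genes <- setdiff(colnames(manifest),
                   c("patient_id", "subtype", "provenance", "volume"))
  ids <- unique(manifest$patient_id)
  lapply(ids, function(id) {
    sub <- manifest[manifest$patient_id == id, , drop = FALSE]
    lrow <- lat[lat$patient_id == id, -1, drop = FALSE]
    structure(list(
      patient_id = id,
      latent = as.numeric(lrow[1, ]),
      mutation_labels = vapply(genes, function(g) as.integer(sub[[g]][1]), integer(1)),
      subtype = as.integer(sub$subtype[1]),
      volumes = lapply(sub$volume, function(f) read_volume(file.path(dir, f))),
      provenance = as.character(sub$provenance[1])),
      class = "patient_record")
  })
}
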