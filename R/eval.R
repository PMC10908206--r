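# ROC/PR curves and AUCs with explicit tie conventions, macro
# precision/recall/F1, and the experiment drivers that reproduce the
# structure of the reference study's comparison tables (per-gene mutation
# arms; subtype arms).

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney concordance probability with ties counted
#' one-half; the curve is threshold-sorted with one point per distinct
#' score.
#'
#' @param truth 0/1 vector (both classes present).
#' @param scores numeric scores, higher = more positive.
#' @return `list(curve = data.frame(threshold, fpr, tpr), auc =)`.
#' @export
roc_curve_auc <- function(truth, scores) {
  truth <- as.numeric(truth)
  if (length(truth) != length(scores)) stop("roc_curve_auc: length mismatch")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_curve_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(threshold = s[last],
                      fpr = fp[last] / n0, tpr = tp[last] / n1)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and AUC
#'
#' One point per distinct threshold; the area uses step-wise interpolation
#' (precision held constant between achieved recall levels), i.e. average
#' precision. With all scores equal the curve degenerates to a single point
#' and the AUC equals the positive prevalence.
#'
#' @param truth 0/1 vector with at least one positive.
#' @param scores numeric scores.
#' @return `list(curve = data.frame(threshold, recall, precision), auc =)`.
#' @export
pr_curve_auc <- function(truth, scores) {
  truth <- as.numeric(truth)
  if (length(truth) != length(scores)) stop("pr_curve_auc: length mismatch")
  n1 <- sum(truth == 1)
  if (n1 == 0L) stop("pr_curve_auc: need at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tp[last] / n1
  precision <- tp[last] / (tp[last] + fp[last])
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[last], recall = recall,
                          precision = precision),
       auc = auc)
}

#' Precision, recall and F1
#'
#' Per class, P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); macro is the
#' unweighted class mean; `"binary"` reports class 1 only. Ratios with zero
#' denominator are scored 0 with a warning.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same label space).
#' @param averaging `"macro"` or `"binary"`.
#' @param labels class label set (default: observed union; pass the full
#'   coding, e.g. `0:4`, to count never-seen classes).
#' @return `c(precision =, recall =, f1 =)`.
#' @export
precision_recall_f1 <- function(truth, predicted,
                                averaging = c("macro", "binary"),
                                labels = NULL) {
  averaging <- match.arg(averaging)
  if (length(truth) != length(predicted)) {
    stop("precision_recall_f1: length mismatch")
  }
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  if (averaging == "binary") labels <- 1
  undef <- character(0)
  per <- vapply(labels, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp + fp == 0) undef <<- c(undef, paste0("precision(", cl, ")"))
    if (tp + fn == 0) undef <<- c(undef, paste0("recall(", cl, ")"))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }, numeric(3))
  if (length(undef)) {
    warning("undefined (zero-denominator) ratios scored 0: ",
            paste(undef, collapse = ", "))
  }
  out <- rowMeans(per)
  names(out) <- c("precision", "recall", "f1")
  out
}

# Bundle of per-arm metrics mirroring the comparison-table rows.
eval_report <- function(task, arm, n_test, seed, ...) {
  structure(c(list(task = task, arm = arm, n_test = n_test, seed = seed),
              list(...)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  extra <- setdiff(names(x), c("task", "arm", "n_test", "seed"))
  vals <- vapply(extra, function(nm) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1) sprintf("%s=%.4f", nm, v) else NULL
  }, character(1))
  cat(sprintf("<eval_report %s | %s | n_test=%d | %s>\n", x$task, x$arm,
              x$n_test, paste(vals, collapse = " ")))
  invisible(x)
}

# Train a CNN on `train` and score it on `test` for a binary gene task.
fit_eval_binary <- function(gene, train, test, volume_shape, epochs,
                            batch_size, learning_rate, seed) {
  cfg <- cnn_config(volume_shape = volume_shape, task = gene, epochs = epochs,
                    batch_size = batch_size, learning_rate = learning_rate,
                    seed = seed)
  model <- build_mutation_cnn(cfg)
  model <- train_classifier(model, train)
  test_cases <- expand_cases(test)
  truth <- vapply(test_cases, record_label, numeric(1), key = gene)
  prob <- predict_proba(model, lapply(test_cases, function(r) r$volumes[[1]]))
  list(model = model, truth = truth, prob = prob)
}

#' Run the per-gene mutation-status experiment across dataset arms
#'
#' For each arm (`real`, `generated`, `combined`): stratified 20% test
#' split, CNN training, ROC-AUC and PR-AUC on the held-out cases; plus the
#' multi-omic L1-logistic baseline arm fit on latent vectors. Epochs follow
#' the per-task presets (`real` arm: 300; others: the gene's preset) unless
#' `epochs` is given. Fully seeded.
#'
#' @param arms named list of record lists; recognised names `real`,
#'   `generated`, `combined`. The omic baseline uses the latents of the
#'   first arm (identical across arms by construction).
#' @param gene `"TP53"`, `"PIK3CA"` or `"CDH1"`.
#' @param test_fraction held-out fraction (default 0.2).
#' @param epochs optional scalar override of the epoch presets.
#' @param batch_size,learning_rate CNN training knobs.
#' @param seed integer seed.
#' @return Named list of `eval_report` (one per arm + `omic-baseline`).
#' @export
run_mutation_experiment <- function(arms, gene, test_fraction = 0.2,
                                    epochs = NULL, batch_size = 8L,
                                    learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(arms) >= 1, !is.null(names(arms)))
  reports <- list()
  i <- 0L
  for (arm in names(arms)) {
    i <- i + 1L
    recs <- arms[[arm]]
    sp <- dim(recs[[1]]$volumes[[1]]$data)
    ep <- epochs %||% unname(
      if (identical(arm, "real")) cnn_epoch_presets[["real"]]
      else cnn_epoch_presets[[gene]])
    spl <- split_train_test(recs, test_fraction, stratify_key = gene,
                            seed = (seed + 17L * i) %% 2147483647L)
    fe <- fit_eval_binary(gene, spl$train, spl$test, sp, ep, batch_size,
                          learning_rate, seed = (seed + 29L * i) %% 2147483647L)
    roc <- roc_curve_auc(fe$truth, fe$prob)
    pr <- pr_curve_auc(fe$truth, fe$prob)
    reports[[arm]] <- eval_report(task = gene, arm = arm,
                                  n_test = length(fe$truth), seed = seed,
                                  roc_auc = roc$auc, pr_auc = pr$auc)
  }
  lat <- cohort_latents(arms[[1]])
  labels <- vapply(arms[[1]], record_label, numeric(1), key = gene)
  lb <- logistic_l1_baseline(lat, labels, test_split = test_fraction,
                             seed = (seed + 401L) %% 2147483647L)
  roc <- roc_curve_auc(lb$test$truth, lb$test$prob)
  pr <- pr_curve_auc(lb$test$truth, lb$test$prob)
  reports[["omic-baseline"]] <- eval_report(task = gene, arm = "omic-baseline",
                                            n_test = nrow(lb$test), seed = seed,
                                            roc_auc = roc$auc, pr_auc = pr$auc)
  reports
}

#' Run the 5-class subtype experiment across dataset arms
#'
#' Analogous to [run_mutation_experiment()] for the subtype task, reporting
#' macro precision/recall/F1 over the coding Normal=0..HER2=4.
#'
#' @param arms named list of record lists (reference protocol: `generated`
#'   and `combined`).
#' @param test_fraction held-out fraction (default 0.2).
#' @param epochs optional override of the 2500-epoch preset.
#' @param batch_size,learning_rate CNN training knobs.
#' @param seed integer seed.
#' @return Named list of `eval_report`.
#' @export
run_subtype_experiment <- function(arms, test_fraction = 0.2, epochs = NULL,
                                   batch_size = 8L, learning_rate = 1e-3,
                                   seed = 1L) {
  stopifnot(length(arms) >= 1, !is.null(names(arms)))
  reports <- list()
  i <- 0L
  for (arm in names(arms)) {
    i <- i + 1L
    recs <- arms[[arm]]
    sp <- dim(recs[[1]]$volumes[[1]]$data)
    ep <- epochs %||% unname(cnn_epoch_presets[["subtype"]])
    spl <- split_train_test(recs, test_fraction, stratify_key = "subtype",
                            seed = (seed + 17L * i) %% 2147483647L)
    cfg <- cnn_config(volume_shape = sp, task = "subtype", epochs = ep,
                      batch_size = batch_size, learning_rate = learning_rate,
                      seed = (seed + 29L * i) %% 2147483647L)
    model <- build_subtype_cnn(cfg)
    model <- train_classifier(model, spl$train)
    test_cases <- expand_cases(spl$test)
    truth <- vapply(test_cases, record_label, numeric(1), key = "subtype")
    scores <- predict_proba(model, lapply(test_cases, function(r) r$volumes[[1]]))
    pred <- max.col(scores) - 1L
    prf <- suppressWarnings(
      precision_recall_f1(truth, pred, averaging = "macro", labels = 0:4))
    reports[[arm]] <- eval_report(task = "subtype", arm = arm,
                                  n_test = length(truth), seed = seed,
                                  precision = prf[["precision"]],
                                  recall = prf[["recall"]], f1 = prf[["f1"]])
  }
  reports
}
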