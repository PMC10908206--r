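# Brute-force oracles: ROC-AUC as the pairwise concordance probability with
# half credit for ties; PR-AUC by exhaustive threshold enumeration with
# step-wise (average-precision) interpolation.
auc_pairwise_oracle <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

pr_auc_oracle <- function(truth, scores) {
  n1 <- sum(truth == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  recall_prev <- 0
  auc <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(truth[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n1
    auc <- auc + (rec - recall_prev) * prec
    recall_prev <- rec
  }
  auc
}

test_that("roc_curve_auc matches hand cases and handles inversions", {
  expect_equal(roc_curve_auc(c(0, 1), c(0.1, 0.9))$auc, 1.0)
  expect_equal(roc_curve_auc(c(0, 1), c(0.9, 0.1))$auc, 0.0)
  r <- roc_curve_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_identical(r$auc, 0.75)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(tail(r$curve$tpr, 1), 1)
  expect_error(roc_curve_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("roc and pr AUCs match brute-force oracles on 200 tied random instances", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.4))        # both classes guaranteed
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_lt(abs(roc_curve_auc(truth, scores)$auc -
                  auc_pairwise_oracle(truth, scores)), 1e-12)
    expect_lt(abs(pr_curve_auc(truth, scores)$auc -
                  pr_auc_oracle(truth, scores)), 1e-9)
  }
})

test_that("pr_curve_auc hand cases: perfect ranking, derived case, all-tied scores", {
  expect_equal(pr_curve_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  want <- pr_auc_oracle(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_lt(abs(pr_curve_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc - want),
            1e-9)
  flat <- pr_curve_auc(c(0, 0, 0, 1), rep(0.5, 4))
  expect_equal(flat$auc, 0.25)  # degenerate single-point curve: prevalence
  expect_error(pr_curve_auc(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("precision_recall_f1 counts and conventions", {
  perfect <- precision_recall_f1(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_equal(unname(perfect), c(1, 1, 1))
  # binary with TP=2, FP=1, FN=1, TN=1
  got <- precision_recall_f1(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0),
                             averaging = "binary")
  expect_equal(unname(got), c(2 / 3, 2 / 3, 2 / 3))
  # a class never predicted and never true contributes zeros with a warning
  expect_warning(
    m <- precision_recall_f1(c(0, 0, 1), c(0, 0, 1), labels = 0:2),
    "undefined")
  expect_equal(unname(m), c(2 / 3, 2 / 3, 2 / 3))
  expect_error(precision_recall_f1(c(0, 1), c(0, 1, 1)), "length")
})

test_that("macro F1 is invariant to class relabeling", {
  set.seed(5)
  truth <- sample(0:4, 60, replace = TRUE)
  pred <- sample(0:4, 60, replace = TRUE)
  base <- suppressWarnings(precision_recall_f1(truth, pred, labels = 0:4))
  perm <- c(3L, 0L, 4L, 2L, 1L)
  relab <- suppressWarnings(
    precision_recall_f1(perm[truth + 1L], perm[pred + 1L], labels = 0:4))
  expect_equal(base, relab)
})

test_that("run_mutation_experiment produces one report per arm plus the omic baseline", {
  cohort <- toy_cohort(n = 40L)
  gen <- lapply(cohort, function(r) { r$provenance <- "generated"; r })
  reports <- suppressWarnings(run_mutation_experiment(
    list(real = cohort, generated = gen, combined = c(cohort, gen)),
    gene = "TP53", epochs = 2L, batch_size = 8L, seed = 31L))
  expect_setequal(names(reports),
                  c("real", "generated", "combined", "omic-baseline"))
  for (r in reports) {
    expect_s3_class(r, "eval_report")
    expect_true(r$roc_auc >= 0 && r$roc_auc <= 1)
    expect_true(r$pr_auc >= 0 && r$pr_auc <= 1)
    expect_gte(r$n_test, 1L)
  }
  again <- suppressWarnings(run_mutation_experiment(
    list(real = cohort, generated = gen, combined = c(cohort, gen)),
    gene = "TP53", epochs = 2L, batch_size = 8L, seed = 31L))
  expect_equal(reports$real$roc_auc, again$real$roc_auc)
  # default test fraction follows the 20% protocol
  expect_equal(reports$real$n_test, round(0.2 * 40))
})

test_that("run_subtype_experiment reports macro metrics for each arm", {
  cohort <- toy_cohort(n = 50L, seed = 13L)
  gen <- lapply(cohort, function(r) { r$provenance <- "generated"; r })
  reports <- suppressWarnings(run_subtype_experiment(
    list(generated = gen, combined = c(cohort, gen)),
    epochs = 2L, batch_size = 8L, seed = 17L))
  expect_setequal(names(reports), c("generated", "combined"))
  for (r in reports) {
    expect_true(all(c(r$precision, r$recall, r$f1) >= 0))
    expect_true(all(c(r$precision, r$recall, r$f1) <= 1))
  }
  again <- suppressWarnings(run_subtype_experiment(
    list(generated = gen, combined = c(cohort, gen)),
    epochs = 2L, batch_size = 8L, seed = 17L))
  expect_equal(reports$generated$f1, again$generated$f1)
})

test_that("ROC-AUC agrees with an independent library implementation", {
  set.seed(88)
  truth <- rbinom(60, 1, 0.4)
  truth[1:2] <- c(0, 1)
  scores <- round(runif(60), 2)
  ours <- roc_curve_auc(truth, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
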