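# O(n^2) pairwise Mann-Whitney oracle for the AUC: probability that a random
# positive outscores a random negative, ties counting one half
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("fold plans partition the data into disjoint train/valid/test roles", {
  plan <- make_cv_folds(10, k = 5, seed = 3)
  expect_equal(lengths(plan$folds), rep(2L, 5))
  for (it in plan$iterations) {
    expect_equal(length(it$train), 6L)
    expect_equal(length(it$valid), 2L)
    expect_equal(length(it$test), 2L)
    expect_equal(sort(c(it$train, it$valid, it$test)), 1:10)
  }
  expect_equal(sort(unlist(lapply(plan$iterations, `[[`, "test"))), 1:10)
  expect_identical(make_cv_folds(10, 5, seed = 3), plan)
  expect_false(identical(make_cv_folds(10, 5, seed = 4), plan))
  expect_error(make_cv_folds(10, k = 2), "at least 3", class = "snn6ma_validation_error")
  expect_error(make_cv_folds(4, k = 5), class = "snn6ma_validation_error")
})

test_that("the benchmark-sized plan yields the 8/1/1 fold split", {
  labels <- rep(c(1L, 0L), each = 880)
  plan <- make_cv_folds(1760, k = 10, seed = 1, labels = labels)
  expect_equal(lengths(plan$folds), rep(176L, 10))
  it <- plan$iterations[[1]]
  expect_equal(length(it$train), 1408L)
  expect_equal(length(it$valid), 176L)
  expect_equal(length(it$test), 176L)
  # stratification keeps each fold balanced
  for (f in plan$folds) expect_equal(sum(labels[f]), 88L)
})

test_that("fold sizes differ by at most one for arbitrary n, k and stratification", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(12:200, 1)
    k <- sample(3:8, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    for (strat in c(TRUE, FALSE)) {
      plan <- make_cv_folds(n, k, seed = rep, labels = if (strat) labels else NULL,
                            stratify = strat)
      sizes <- lengths(plan$folds)
      expect_lte(max(sizes) - min(sizes), 1L)
      expect_equal(sort(unlist(plan$folds)), seq_len(n))
      for (it in plan$iterations) {
        expect_length(intersect(it$train, it$valid), 0)
        expect_length(intersect(it$train, it$test), 0)
        expect_length(intersect(it$valid, it$test), 0)
        expect_equal(sort(c(it$train, it$valid, it$test)), seq_len(n))
      }
    }
  }
})

test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc[c("TP", "FN", "TN", "FP")]), c(TP = 1, FN = 1, TN = 1, FP = 1))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0)
  inverted <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(inverted$TP + inverted$TN, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length",
               class = "snn6ma_validation_error")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), class = "snn6ma_validation_error")
})

test_that("threshold metrics match their closed forms at the anchor cases", {
  m <- compute_metrics(confusion_counts(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5)))
  expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1, specificity = 1, mcc = 1))
  m0 <- compute_metrics(structure(list(TP = 3, TN = 2, FP = 2, FN = 3),
                                  class = "confusion_counts"))
  expect_equal(m0$mcc, 0)
  anti <- compute_metrics(confusion_counts(rep(c(1, 0), each = 5), rep(c(0, 1), each = 5)))
  expect_equal(anti$accuracy, 0)
  expect_equal(anti$mcc, -1)
  # degenerate denominator: all predictions positive
  degen <- compute_metrics(confusion_counts(c(1, 0), c(1, 1)))
  expect_equal(degen$mcc, 0)
})

test_that("MCC equals the Pearson correlation of the binary label vectors", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    truth <- sample(0:1, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.3, 1 - truth, truth)
    m <- compute_metrics(confusion_counts(truth, pred))
    r <- suppressWarnings(cor(truth, pred))
    if (is.finite(r)) expect_equal(m$mcc, r, tolerance = 1e-12)
    expect_equal(m$accuracy, mean(truth == pred))
    if (any(truth == 1)) expect_equal(m$sensitivity, mean(pred[truth == 1] == 1))
    if (any(truth == 0)) expect_equal(m$specificity, mean(pred[truth == 0] == 0))
  }
})

test_that("ROC construction and AUC match the pairwise oracle and pROC", {
  truth <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_and_auc(truth, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))$auc, 1)
  expect_equal(roc_and_auc(truth, rep(0.5, 6))$auc, 0.5)
  expect_equal(roc_and_auc(truth, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))$auc, 0)
  expect_error(roc_and_auc(c(1, 1), c(0.1, 0.2)), "one class",
               class = "snn6ma_validation_error")

  set.seed(66)
  for (i in 1:40) {
    n <- sample(8:60, 1)
    truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2) # rounding forces ties
    ra <- roc_and_auc(truth, scores)
    expect_equal(ra$auc, oracle_auc(truth, scores), tolerance = 1e-12)
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(ra$roc$fpr[nrow(ra$roc)], 1); expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
    # invariance under a strictly monotone score transform
    expect_equal(roc_and_auc(truth, qlogis(scores / 2 + 0.25))$auc, ra$auc)
    # independent library cross-check
    proc_auc <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                               direction = "<")))
    expect_equal(ra$auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("cross-validation reports per-fold and pooled metrics coherently", {
  d <- generate_dataset(30, 30, window_length = 17, motif = "GAGG", seed = 40)
  cv <- run_cross_validation(d, model = tiny_model(), training = tiny_training(seed = 40),
                             k = 3, seed = 40)
  expect_equal(nrow(cv$per_fold), 3L)
  expect_equal(sum(cv$per_fold$n_test), 60L)
  # equal fold sizes: the fold-averaged accuracy equals the pooled accuracy
  expect_equal(unname(cv$mean[["accuracy"]]), cv$pooled$accuracy, tolerance = 1e-12)
  # every sample is tested exactly once
  tests <- unlist(lapply(cv$plan$iterations, `[[`, "test"))
  expect_equal(sort(tests), 1:60)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
})

test_that("cross-species evaluation never updates weights and matches in-sample scoring", {
  train_d <- generate_dataset(30, 30, window_length = 17, motif = "GAGG", seed = 50)
  fit <- snn6ma(train_d, model = tiny_model(), training = tiny_training(seed = 50))
  before <- fit$network$weights
  rep_in <- cross_species_evaluate(fit$network, train_d)
  expect_identical(fit$network$weights, before)
  # evaluating the training set reproduces in-sample metrics
  expect_equal(rep_in$accuracy, mean(classify(fit$fitted) == train_d$label))
  wrong_len <- generate_dataset(5, 5, window_length = 21, seed = 1)
  expect_error(cross_species_evaluate(fit$network, wrong_len), "window length",
               class = "snn6ma_validation_error")
})

test_that("a report writes as TSV plus JSON with an ROC table", {
  rep <- snn6ma:::fold_report(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.2))
  stem <- tempfile()
  paths <- write_metrics_report(rep, stem)
  expect_true(all(file.exists(paths)))
  flat <- read.delim(paths[["tsv"]])
  expect_equal(flat$accuracy, 1)
  expect_equal(jsonlite::read_json(paths[["json"]])$auc, 1)
})
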