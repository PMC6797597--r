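#' Build a k-fold cross-validation plan with a held-out validation fold
#'
#' Randomly partitions \code{n} samples into \code{k} near-equal folds and
#' builds one iteration per fold: fold i is the test set, the cyclically
#' next fold is the validation set (driving the training callbacks), and the
#' remaining k-2 folds form the training set. When \code{labels} are
#' supplied the folds are stratified by class so each fold preserves the
#' overall class balance; pass \code{stratify = FALSE} for a plain random
#' partition.
#'
#' @param n Number of samples.
#' @param k Number of folds; at least 3 (the protocol needs three disjoint
#'   roles).
#' @param seed Integer seed for the random partition.
#' @param labels Optional 0/1 labels of length \code{n} for stratification.
#' @param stratify Whether to stratify when labels are given (default TRUE).
#' @return An object of class \code{fold_plan}: list with \code{k},
#'   \code{seed}, \code{folds} (list of index vectors) and
#'   \code{iterations} (list of lists with \code{train}, \code{valid},
#'   \code{test} index vectors).
#' @examples
#' plan <- make_cv_folds(20, k = 5, seed = 1)
#' lengths(plan$iterations[[1]])
#' @export
make_cv_folds <- function(n, k, seed = 1, labels = NULL, stratify = !is.null(labels)) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  seed <- check_count(seed, "seed", min = 0)
  if (k < 3) stop_validation("k must be at least 3: each iteration needs train, validation and test folds")
  if (n < k) stop_validation("n must be at least k")
  if (!is.null(labels) && length(labels) != n) stop_validation("labels must have length n")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)

  assign_fold <- integer(n)
  if (isTRUE(stratify) && !is.null(labels)) {
    # deal each class round-robin, continuing the rotation across classes so
    # total fold sizes still differ by at most one
    offset <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      assign_fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  } else {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assign_fold[perm] <- rep(seq_len(k), times = sizes)
  }
  folds <- split(seq_len(n), assign_fold)
  names(folds) <- NULL

  iterations <- lapply(seq_len(k), function(i) {
    valid_fold <- (i %% k) + 1L
    list(train = sort(unlist(folds[-c(i, valid_fold)], use.names = FALSE)),
         valid = folds[[valid_fold]],
         test = folds[[i]])
  })
  structure(list(k = k, seed = seed, folds = folds, iterations = iterations),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  n <- sum(lengths(x$folds))
  cat(sprintf("%d-fold cross-validation plan for %d samples (seed %d)\n", x$k, n, x$seed))
  cat(sprintf("  per iteration: %d train / %s valid / %s test samples\n",
              length(x$iterations[[1]]$train),
              length(x$iterations[[1]]$valid),
              length(x$iterations[[1]]$test)))
  invisible(x)
}

#' Confusion counts of a binary prediction
#'
#' @param truth Integer 0/1 vector of true labels (1 = 6mA-positive).
#' @param predicted Integer 0/1 vector of predicted labels.
#' @return An object of class \code{confusion_counts} with elements
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted labels must have equal length")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop_validation("labels must be 0 or 1")
  }
  structure(list(
    TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  |  TN %d  FP %d\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Threshold metrics from confusion counts
#'
#' Computes accuracy \eqn{(TP+TN)/(TP+TN+FP+FN)}, sensitivity
#' \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)} and the Matthews
#' correlation coefficient
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' When any factor of the MCC denominator is zero the coefficient is
#' defined as 0 (the no-information value).
#'
#' @param counts A [confusion_counts()] object with at least one sample.
#' @return A list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} and \code{mcc}.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop_validation("cannot compute metrics from zero samples")
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den) else 0)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped into a single step), producing a curve of
#' (false positive rate, true positive rate) points from (0, 0) to (1, 1),
#' and integrates it by the trapezoidal rule. The resulting AUC equals the
#' probability that a random positive scores above a random negative, with
#' ties counting one half.
#'
#' @param truth Integer 0/1 vector; both classes must be present.
#' @param scores Finite numeric scores, higher meaning more positive.
#' @return A list with \code{roc} (data frame \code{threshold, fpr, tpr})
#'   and \code{auc}.
#' @export
roc_and_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) stop_validation("truth and scores must have equal length")
  if (!all(truth %in% c(0, 1))) stop_validation("labels must be 0 or 1")
  if (!all(is.finite(scores))) stop_validation("scores must be finite")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("AUC is undefined when only one class is present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # one step per distinct score: index of the last element of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

fold_report <- function(truth, probs) {
  counts <- confusion_counts(truth, classify(probs))
  m <- compute_metrics(counts)
  ra <- roc_and_auc(truth, probs)
  list(counts = counts, accuracy = m$accuracy, sensitivity = m$sensitivity,
       specificity = m$specificity, mcc = m$mcc, auc = ra$auc, roc = ra$roc)
}

#' Cross-validate the 6mA classifier on a labeled dataset
#'
#' Runs the full evaluation protocol: the dataset is split into k folds
#' (stratified by label); in each iteration a fresh network is built and
#' trained on k-2 folds with one fold as the validation set driving early
#' stopping, checkpointing and learning-rate reduction, and the
#' checkpointed model is scored on the held-out test fold. Per-fold metrics
#' are averaged arithmetically; test-fold scores are also pooled across
#' iterations for a pooled ROC/AUC.
#'
#' @param dataset A \code{labeled_dataset}.
#' @param scheme Sequence encoding, \code{"onehot"} or \code{"feature"}.
#' @param model A [model_config()].
#' @param training A [train_config()]; its seed also derives the per-fold
#'   model-initialization seeds.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold partition (default: the training seed).
#' @param stratify Stratify folds by label (default TRUE).
#' @return An object of class \code{snn_cv}: list with \code{per_fold}
#'   (data frame of per-iteration metrics), \code{mean} (named vector of
#'   fold-averaged metrics), \code{pooled} (metrics and ROC over pooled
#'   test-fold predictions), \code{plan}, \code{k}, \code{scheme} and the
#'   two configurations.
#' @export
run_cross_validation <- function(dataset, scheme = c("onehot", "feature"),
                                 model = model_config(), training = train_config(),
                                 k = 10, seed = training$seed, stratify = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  scheme <- match.arg(scheme)
  k <- check_count(k, "k")
  enc <- encode_batch(dataset, scheme)
  n <- length(dataset$seq)
  plan <- make_cv_folds(n, k, seed = seed,
                        labels = if (stratify) dataset$label else NULL,
                        stratify = stratify)
  rows <- vector("list", k)
  pooled_truth <- integer(0); pooled_scores <- numeric(0)
  for (i in seq_len(k)) {
    it <- plan$iterations[[i]]
    fold_seed <- (training$seed + i * 1009L) %% .Machine$integer.max
    net <- build_model(model, seed = fold_seed)
    fold_train <- training
    fold_train$seed <- fold_seed
    fit <- train_model(net,
                       list(x = enc$x[, , it$train, drop = FALSE], labels = enc$labels[it$train]),
                       list(x = enc$x[, , it$valid, drop = FALSE], labels = enc$labels[it$valid]),
                       fold_train)
    probs <- predict_probability(fit$model, enc$x[, , it$test, drop = FALSE])
    truth <- enc$labels[it$test]
    rep_i <- fold_report(truth, probs)
    rows[[i]] <- data.frame(fold = i, n_test = length(truth),
                            accuracy = rep_i$accuracy, sensitivity = rep_i$sensitivity,
                            specificity = rep_i$specificity, mcc = rep_i$mcc,
                            auc = rep_i$auc, best_epoch = fit$best_epoch,
                            stopped_epoch = fit$stopped_epoch)
    pooled_truth <- c(pooled_truth, truth)
    pooled_scores <- c(pooled_scores, probs)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "mcc", "auc")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_cols]),
    pooled = fold_report(pooled_truth, pooled_scores),
    plan = plan, k = k, scheme = scheme,
    model_config = model, train_config = training),
    class = "snn_cv")
}

#' @export
print.snn_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%s encoding)\n", x$k, x$scheme))
  print(round(x$per_fold[, c("fold", "accuracy", "sensitivity", "specificity",
                             "mcc", "auc")], digits), row.names = FALSE)
  cat("fold-averaged metrics:\n")
  print(round(x$mean, digits))
  cat(sprintf("pooled test-fold AUC: %.4f\n", x$pooled$auc))
  invisible(x)
}

#' Evaluate a frozen model on an independent dataset
#'
#' Scores a trained network on sequences from another source (for example
#' another species) without any retraining or weight update, and reports the
#' five evaluation metrics.
#'
#' @param model A trained \code{snn_network}.
#' @param external A \code{labeled_dataset} whose window length matches the
#'   model configuration.
#' @param scheme Encoding scheme; defaults to the scheme the model was
#'   trained with when that is recorded.
#' @return A list with \code{counts}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{mcc}, \code{auc} and \code{roc}.
#' @export
cross_species_evaluate <- function(model, external, scheme = NULL) {
  stopifnot(inherits(model, "snn_network"), inherits(external, "labeled_dataset"))
  if (is.null(scheme)) scheme <- model$scheme
  if (is.null(scheme)) scheme <- "onehot"
  if (external$window_length != model$config$window_length) {
    stop_validation(sprintf(
      "external dataset window length (%d) does not match the model (%d)",
      external$window_length, model$config$window_length))
  }
  enc <- encode_batch(external, scheme)
  probs <- predict_probability(model, enc$x)
  fold_report(enc$labels, probs)
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report A metrics report (as returned by [cross_species_evaluate()]
#'   or the \code{pooled} element of [run_cross_validation()]).
#' @param stem Output path stem; writes \code{<stem>.tsv},
#'   \code{<stem>.json} and \code{<stem>_roc.tsv}.
#' @return Invisibly, the written paths.
#' @export
write_metrics_report <- function(report, stem) {
  flat <- data.frame(TP = report$counts$TP, TN = report$counts$TN,
                     FP = report$counts$FP, FN = report$counts$FN,
                     accuracy = report$accuracy, sensitivity = report$sensitivity,
                     specificity = report$specificity, mcc = report$mcc,
                     auc = report$auc)
  paths <- c(tsv = paste0(stem, ".tsv"), json = paste0(stem, ".json"),
             roc = paste0(stem, "_roc.tsv"))
  utils::write.table(flat, paths[["tsv"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(flat), paths[["json"]], auto_unbox = TRUE, digits = NA)
  utils::write.table(report$roc, paths[["roc"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
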