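#' Fit a 6mA site classifier to a labeled sequence dataset
#'
#' The main modelling entry point. Encodes the sequences under the chosen
#' scheme, carves out a stratified validation split to drive the training
#' callbacks (early stopping on validation accuracy, best-epoch checkpoint,
#' learning-rate reduction on validation-loss plateau), builds a fresh
#' network and trains it with SGD with momentum on binary cross-entropy
#' loss. The returned object carries the checkpointed network and supports
#' \code{predict}, \code{print}, \code{summary}, \code{plot}, \code{coef}
#' and \code{residuals}.
#'
#' @param dataset A \code{labeled_dataset} (see [load_benchmark()],
#'   [generate_dataset()]).
#' @param scheme Sequence encoding: \code{"onehot"} (default) or
#'   \code{"feature"}.
#' @param model A [model_config()].
#' @param training A [train_config()]; its seed governs the validation
#'   split, weight initialization, epoch shuffling and dropout.
#' @param valid_fraction Fraction of samples held out (stratified by label)
#'   as the validation set (default 0.1). Ignored when \code{valid} is
#'   given.
#' @param valid Optional explicit validation \code{labeled_dataset}; the
#'   full \code{dataset} is then used for training.
#' @return An object of class \code{snn6ma}.
#' @examples
#' d <- generate_dataset(n_pos = 60, n_neg = 60, seed = 1)
#' fit <- snn6ma(d, training = train_config(max_epochs = 5, seed = 1))
#' head(predict(fit, d))
#' @export
snn6ma <- function(dataset, scheme = c("onehot", "feature"),
                   model = model_config(), training = train_config(),
                   valid_fraction = 0.1, valid = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  scheme <- match.arg(scheme)
  if (dataset$window_length != model$window_length) {
    stop_validation(sprintf("dataset window length (%d) does not match model_config (%d)",
                            dataset$window_length, model$window_length))
  }
  if (is.null(valid)) {
    check_fraction(valid_fraction, "valid_fraction", lo_open = TRUE, hi_open = TRUE)
    n <- length(dataset$seq)
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(training$seed)
    idx_val <- unlist(lapply(split(seq_len(n), dataset$label), function(idx) {
      sample(idx, max(1L, round(length(idx) * valid_fraction)))
    }), use.names = FALSE)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
    train_ds <- dataset[setdiff(seq_len(n), idx_val)]
    valid_ds <- dataset[idx_val]
  } else {
    stopifnot(inherits(valid, "labeled_dataset"))
    train_ds <- dataset
    valid_ds <- valid
  }
  net <- build_model(model, seed = training$seed)
  run <- train_model(net, encode_batch(train_ds, scheme),
                     encode_batch(valid_ds, scheme), training)
  net <- run$model
  net$scheme <- scheme
  fitted_probs <- predict_probability(net, encode_batch(dataset, scheme))
  structure(list(
    network = net, scheme = scheme, history = run$history,
    best_epoch = run$best_epoch, stopped_epoch = run$stopped_epoch,
    model_config = model, train_config = training,
    n_train = length(train_ds$seq), n_valid = length(valid_ds$seq),
    fitted = fitted_probs, labels = dataset$label),
    class = "snn6ma")
}

#' @export
print.snn6ma <- function(x, ...) {
  cat(sprintf("6mA convolutional classifier (%s encoding)\n", x$scheme))
  cat(sprintf("  trained on %d sequences (%d held out for validation)\n",
              x$n_train, x$n_valid))
  cat(sprintf("  stopped after %d epochs; checkpointed epoch %d (validation accuracy %.4f)\n",
              x$stopped_epoch, x$best_epoch, max(x$history$val_acc)))
  invisible(x)
}

#' @export
summary.snn6ma <- function(object, ...) {
  print(object)
  cat("\narchitecture:\n")
  print(summary(object$network))
  counts <- confusion_counts(object$labels, classify(object$fitted))
  m <- compute_metrics(counts)
  cat(sprintf("\nin-sample: accuracy %.4f, sensitivity %.4f, specificity %.4f, MCC %.4f\n",
              m$accuracy, m$sensitivity, m$specificity, m$mcc))
  invisible(object)
}

#' Predict 6mA probabilities or labels for new sequences
#'
#' @param object A fitted \code{snn6ma} model.
#' @param newdata A \code{labeled_dataset}, a character vector of sequences
#'   of the model's window length, or an [encode_batch()] result.
#' @param type \code{"response"} for probabilities, \code{"class"} for 0/1
#'   labels under the strict 0.5 rule.
#' @param ... Ignored.
#' @return Numeric probabilities or integer labels, one per sequence.
#' @export
predict.snn6ma <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.character(newdata)) {
    newdata <- new_labeled_dataset(
      id = sprintf("seq_%d", seq_along(newdata)),
      seq = toupper(newdata), label = rep(0L, length(newdata)),
      window_length = object$model_config$window_length)
    validate_records(data.frame(id = newdata$id, seq = newdata$seq), newdata$window_length)
  }
  x <- if (inherits(newdata, "labeled_dataset")) {
    if (newdata$window_length != object$model_config$window_length) {
      stop_validation("newdata window length does not match the fitted model")
    }
    encode_batch(newdata, object$scheme)$x
  } else if (is.list(newdata) && !is.null(newdata$scheme) &&
             !identical(newdata$scheme, object$scheme)) {
    stop_validation(sprintf("newdata was encoded with scheme '%s' but the model uses '%s'",
                            newdata$scheme, object$scheme))
  } else newdata
  p <- predict_probability(object$network, x)
  if (type == "class") classify(p) else p
}

#' @export
coef.snn6ma <- function(object, ...) coef(object$network)

#' Residuals of a fitted 6mA classifier
#'
#' @param object A fitted \code{snn6ma} model.
#' @param ... Ignored.
#' @return Response residuals: observed label minus fitted probability over
#'   the full fitting dataset.
#' @export
residuals.snn6ma <- function(object, ...) object$labels - object$fitted

#' Plot training curves of a fitted 6mA classifier
#'
#' Draws per-epoch training and validation loss (left axis) and accuracy
#' (right panel), marking the checkpointed epoch.
#'
#' @param x A fitted \code{snn6ma} model.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, \code{x}.
#' @export
plot.snn6ma <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("grey40", "firebrick"), xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$acc, h$val_acc), type = "l", lty = 1,
                    col = c("grey40", "firebrick"), xlab = "epoch", ylab = "accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Save a trained network to a portable weight file
#'
#' Writes the weight arrays to a single JSON file at full precision, with a
#' sidecar \code{<path>.config.json} recording the architecture
#' configuration and encoding scheme so the saved model is self-describing.
#'
#' @param model A trained \code{snn_network} or a fitted \code{snn6ma}
#'   object.
#' @param path Output path for the weight file.
#' @return Invisibly, \code{path}.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path) {
  if (inherits(model, "snn6ma")) model <- model$network
  stopifnot(inherits(model, "snn_network"))
  jsonlite::write_json(lapply(model$weights, function(w) {
    if (is.matrix(w)) list(dim = dim(w), values = as.vector(w)) else list(values = as.vector(w))
  }), path, auto_unbox = FALSE, digits = NA)
  sidecar <- paste0(path, ".config.json")
  jsonlite::write_json(c(unclass(model$config),
                         list(scheme = if (is.null(model$scheme)) "onehot" else model$scheme)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network saved by [save_model()]
#'
#' @param path Path to the weight file; the \code{<path>.config.json}
#'   sidecar must sit alongside it.
#' @return An \code{snn_network} with the stored weights, configuration and
#'   encoding scheme.
#' @export
load_model <- function(path) {
  sidecar <- paste0(path, ".config.json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop_validation(sprintf("model file '%s' or its sidecar '%s' not found", path, sidecar))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scheme <- side$scheme
  side$scheme <- NULL
  cfg <- do.call(model_config, side)
  weights <- lapply(raw, function(w) {
    if (!is.null(w$dim) && length(w$dim) == 2) matrix(w$values, w$dim[1], w$dim[2]) else w$values
  })
  weights$b_out <- as.numeric(weights$b_out)
  net <- structure(list(config = cfg, weights = weights, scheme = scheme,
                        trained = list(loaded_from = path)),
                   class = "snn_network")
  net
}
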