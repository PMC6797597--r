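#' Training configuration
#'
#' The published optimization recipe: stochastic gradient descent with
#' momentum 0.95 and learning rate 0.005, binary cross-entropy loss, at most
#' 100 epochs of batches of 32, early stopping when validation accuracy has
#' not improved for 30 epochs, a checkpoint keeping the weights of the best
#' validation-accuracy epoch, and learning-rate reduction by a factor of 0.1
#' when validation loss has not improved for 20 epochs.
#'
#' @param learning_rate Initial SGD learning rate (default 0.005).
#' @param momentum SGD momentum coefficient (default 0.95; plain, not
#'   Nesterov).
#' @param max_epochs Maximum number of training epochs (default 100).
#' @param batch_size Minibatch size (default 32); a smaller final batch is
#'   used as-is.
#' @param early_stop_patience Epochs without validation-accuracy improvement
#'   before training halts (default 30).
#' @param lr_reduce_factor Multiplier applied to the learning rate on a
#'   validation-loss plateau (default 0.1); must be in (0, 1).
#' @param lr_reduce_patience Epochs without validation-loss improvement
#'   before a reduction (default 20); the counter resets after each
#'   reduction and on every improvement.
#' @param min_lr Lower bound for the learning rate (default 0).
#' @param seed Integer seed governing epoch shuffling and dropout masks.
#' @return An object of class \code{snn_train_config}.
#' @export
train_config <- function(learning_rate = 0.005, momentum = 0.95,
                         max_epochs = 100, batch_size = 32,
                         early_stop_patience = 30, lr_reduce_factor = 0.1,
                         lr_reduce_patience = 20, min_lr = 0, seed = 1) {
  cfg <- list(
    learning_rate = check_fraction(learning_rate, "learning_rate", lo = 0, hi = Inf, lo_open = TRUE),
    momentum = check_fraction(momentum, "momentum", hi = 1, hi_open = TRUE),
    max_epochs = check_count(max_epochs, "max_epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    early_stop_patience = check_count(early_stop_patience, "early_stop_patience"),
    lr_reduce_factor = check_fraction(lr_reduce_factor, "lr_reduce_factor",
                                      lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE),
    lr_reduce_patience = check_count(lr_reduce_patience, "lr_reduce_patience"),
    min_lr = check_fraction(min_lr, "min_lr", lo = 0, hi = Inf),
    seed = check_count(seed, "seed", min = 0))
  structure(cfg, class = "snn_train_config")
}

#' @export
print.snn_train_config <- function(x, ...) {
  cat(sprintf(
    "SGD training configuration: lr %g, momentum %g, <=%d epochs, batch %d\n",
    x$learning_rate, x$momentum, x$max_epochs, x$batch_size))
  cat(sprintf(
    "  early stop: patience %d on validation accuracy; checkpoint best epoch\n",
    x$early_stop_patience))
  cat(sprintf("  reduce LR on plateau: factor %g, patience %d on validation loss\n",
              x$lr_reduce_factor, x$lr_reduce_patience))
  invisible(x)
}

as_xy <- function(batch, what) {
  if (is.list(batch) && !is.null(batch$x)) {
    y <- if (!is.null(batch$labels)) batch$labels else batch$y
    if (is.null(y)) stop_validation(sprintf("'%s' must carry labels", what))
    return(list(x = batch$x, y = as.numeric(y)))
  }
  stop_validation(sprintf("'%s' must be an encode_batch() result (list with x and labels)", what))
}

#' Train a network with SGD, early stopping and best-epoch checkpointing
#'
#' Optimizes the binary cross-entropy loss (plus the configured L2 penalty)
#' by minibatch SGD with momentum. The training set is reshuffled every
#' epoch under the configuration seed. After each epoch the model is scored
#' on the validation set; the weights of the epoch with the highest
#' validation accuracy are kept (checkpoint), training halts once validation
#' accuracy has not improved for \code{early_stop_patience} epochs, and the
#' learning rate is multiplied by \code{lr_reduce_factor} whenever
#' validation loss has not improved for \code{lr_reduce_patience} epochs.
#' The returned model carries the checkpointed (best-epoch) weights, not the
#' final ones.
#'
#' @param model An untrained or trained \code{snn_network} (see
#'   [build_model()]); the passed object is not modified.
#' @param train,valid Disjoint encoded sample sets as returned by
#'   [encode_batch()] (lists with \code{x} and \code{labels}).
#' @param config A [train_config()].
#' @return An object of class \code{snn_training}: list with \code{model}
#'   (the checkpointed network), \code{history} (data frame with per-epoch
#'   \code{epoch, lr, loss, acc, val_loss, val_acc}), \code{best_epoch} and
#'   \code{stopped_epoch}.
#' @export
train_model <- function(model, train, valid, config = train_config()) {
  stopifnot(inherits(model, "snn_network"))
  if (!inherits(config, "snn_train_config")) stop_validation("'config' must be a train_config()")
  tr <- as_xy(train, "train")
  va <- as_xy(valid, "valid")
  tr$x <- as_input_array(tr$x, model$config)
  va$x <- as_input_array(va$x, model$config)
  n <- dim(tr$x)[3L]
  if (n == 0L || length(va$y) == 0L) stop_validation("train and valid sets must be non-empty")
  if (length(tr$y) != n) stop_validation("train labels do not match the number of samples")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  weights <- model$weights
  velocity <- zero_velocity(weights)
  lr <- config$learning_rate
  best_acc <- -Inf; best_weights <- weights; best_epoch <- 0L
  es_wait <- 0L; lr_wait <- 0L; best_val_loss <- Inf
  hist <- vector("list", config$max_epochs)
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    loss_sum <- 0; correct <- 0
    for (b in starts) {
      take <- perm[b:min(b + config$batch_size - 1L, n)]
      xb <- tr$x[, , take, drop = FALSE]
      yb <- tr$y[take]
      fw <- network_forward(weights, model$config, xb, training = TRUE)
      loss_b <- binary_crossentropy(yb, fw$p) + l2_penalty(weights, model$config$l2_rate)
      if (!is.finite(loss_b)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d (lr %g)", epoch, lr))
      }
      loss_sum <- loss_sum + loss_b * length(take)
      correct <- correct + sum(as.integer(fw$p > 0.5) == yb)
      grads <- network_backward(weights, model$config, fw, yb)
      upd <- sgd_step(weights, grads, velocity, lr, config$momentum)
      weights <- upd$weights
      velocity <- upd$velocity
    }
    p_val <- network_forward(weights, model$config, va$x, training = FALSE)$p
    val_loss <- binary_crossentropy(va$y, p_val) + l2_penalty(weights, model$config$l2_rate)
    val_acc <- mean(as.integer(p_val > 0.5) == va$y)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                loss = loss_sum / n, acc = correct / n,
                                val_loss = val_loss, val_acc = val_acc)

    if (val_acc > best_acc) {
      best_acc <- val_acc; best_weights <- weights; best_epoch <- epoch
      es_wait <- 0L
    } else {
      es_wait <- es_wait + 1L
    }
    if (val_loss < best_val_loss) {
      best_val_loss <- val_loss; lr_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L
      if (lr_wait >= config$lr_reduce_patience) {
        lr <- max(lr * config$lr_reduce_factor, config$min_lr)
        lr_wait <- 0L
      }
    }
    if (es_wait >= config$early_stop_patience) {
      stopped <- epoch
      break
    }
  }

  trained <- model
  trained$weights <- best_weights
  trained$trained <- list(best_epoch = best_epoch, stopped_epoch = stopped,
                          best_val_acc = best_acc, train_config = config)
  structure(list(model = trained,
                 history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                 best_epoch = best_epoch, stopped_epoch = stopped),
            class = "snn_training")
}

#' @export
print.snn_training <- function(x, ...) {
  cat(sprintf("Training run: %d epochs (best validation accuracy %.4f at epoch %d)\n",
              x$stopped_epoch, max(x$history$val_acc), x$best_epoch))
  invisible(x)
}

#' Early-stopping decision on a validation-accuracy trace
#'
#' Replays the early-stopping counter over a recorded sequence of per-epoch
#' validation accuracies: the running best updates on strict improvement,
#' and training halts at the first epoch by which \code{patience} epochs
#' have passed without an improvement.
#'
#' @param val_accuracies Numeric vector of per-epoch validation accuracies.
#' @param patience Number of non-improving epochs tolerated.
#' @return The halting epoch index, or \code{NA} if the trace never
#'   triggers the stop.
#' @examples
#' early_stopping_decision(c(0.6, 0.7, rep(0.7, 30)), patience = 30)  # 32
#' @export
early_stopping_decision <- function(val_accuracies, patience) {
  patience <- check_count(patience, "patience")
  best <- -Inf; wait <- 0L
  for (e in seq_along(val_accuracies)) {
    if (val_accuracies[e] > best) {
      best <- val_accuracies[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

#' Learning-rate schedule implied by a validation-loss trace
#'
#' Replays the reduce-on-plateau rule over a recorded sequence of per-epoch
#' validation losses and returns the learning rate in effect at each epoch.
#' The rate is multiplied by \code{factor} whenever \code{patience}
#' consecutive epochs pass without a strict improvement of the running best
#' loss; the plateau counter resets after each reduction and on every
#' improvement, and reductions take effect from the following epoch.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param factor Multiplicative reduction factor in (0, 1).
#' @param patience Plateau length (epochs) that triggers a reduction.
#' @param base_lr Learning rate at epoch 1.
#' @param min_lr Lower bound for the rate (default 0).
#' @return Numeric vector, the learning rate in effect at each epoch.
#' @export
reduce_lr_on_plateau <- function(val_losses, factor, patience, base_lr, min_lr = 0) {
  check_fraction(factor, "factor", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  patience <- check_count(patience, "patience")
  lr <- base_lr
  best <- Inf; wait <- 0L
  out <- numeric(length(val_losses))
  for (e in seq_along(val_losses)) {
    out[e] <- lr
    if (val_losses[e] < best) {
      best <- val_losses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, min_lr)
        wait <- 0L
      }
    }
  }
  out
}

#' Write a per-epoch training log as TSV
#'
#' @param history The \code{history} data frame of an [train_model()] run.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
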