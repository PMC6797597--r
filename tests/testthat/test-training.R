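test_that("early stopping halts exactly patience epochs after the last improvement", {
  expect_equal(early_stopping_decision(c(0.6, 0.7, rep(0.7, 30)), patience = 30), 32L)
  expect_equal(early_stopping_decision(seq(0.5, 0.99, length.out = 100), patience = 30),
               NA_integer_)
  expect_equal(early_stopping_decision(rep(0.5, 10), patience = 20), NA_integer_)
  # improvement resets the counter
  expect_equal(early_stopping_decision(c(0.6, 0.5, 0.5, 0.7, 0.5, 0.5, 0.5), patience = 3), 7L)
})

test_that("reduce-on-plateau reproduces the hand-simulated schedule", {
  lrs <- reduce_lr_on_plateau(rep(1, 100), factor = 0.1, patience = 20, base_lr = 0.005)
  expect_equal(lrs, c(rep(0.005, 21), rep(5e-4, 20), rep(5e-5, 20),
                      rep(5e-6, 20), rep(5e-7, 19)))
  expect_equal(reduce_lr_on_plateau(seq(1, 0.1, length.out = 50), 0.1, 20, 0.005),
               rep(0.005, 50))
  expect_equal(reduce_lr_on_plateau(rep(1, 10), 0.1, 20, 0.005), rep(0.005, 10))
  # the floor binds
  expect_equal(reduce_lr_on_plateau(rep(1, 25), 0.1, 10, 0.005, min_lr = 1e-3)[25], 1e-3)
})

test_that("a degenerate one-epoch schedule returns that epoch's weights", {
  d <- tiny_dataset(16, 16, seed = 6)
  enc <- encode_batch(d, "onehot")
  net <- build_model(tiny_model(), seed = 6)
  run <- train_model(net, enc, enc, train_config(max_epochs = 1, seed = 6))
  expect_equal(nrow(run$history), 1L)
  expect_equal(run$best_epoch, 1L)
  expect_equal(run$stopped_epoch, 1L)
})

test_that("training is reproducible and honors the checkpoint contract", {
  d <- generate_dataset(40, 40, window_length = 17, motif = "GAGG", seed = 13)
  plan <- make_cv_folds(80, k = 4, seed = 13, labels = d$label)
  it <- plan$iterations[[1]]
  enc <- encode_batch(d, "onehot")
  tr <- list(x = enc$x[, , it$train, drop = FALSE], labels = enc$labels[it$train])
  va <- list(x = enc$x[, , it$valid, drop = FALSE], labels = enc$labels[it$valid])
  cfg <- tiny_training(seed = 21)
  run1 <- train_model(build_model(tiny_model(), seed = 21), tr, va, cfg)
  run2 <- train_model(build_model(tiny_model(), seed = 21), tr, va, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(run1$model$weights, run2$model$weights)

  # the returned model carries the best-epoch weights: its validation
  # accuracy equals the maximum of the recorded history
  p_val <- predict_probability(run1$model, va$x)
  expect_equal(mean(classify(p_val) == va$labels), max(run1$history$val_acc))
  expect_equal(run1$best_epoch, which.max(run1$history$val_acc))

  # the in-loop counters agree with the standalone callback replays
  expect_equal(run1$history$lr,
               reduce_lr_on_plateau(run1$history$val_loss, cfg$lr_reduce_factor,
                                    cfg$lr_reduce_patience, cfg$learning_rate))
  stop_replay <- early_stopping_decision(run1$history$val_acc, cfg$early_stop_patience)
  if (run1$stopped_epoch < cfg$max_epochs) {
    expect_equal(run1$stopped_epoch, stop_replay)
  } else {
    expect_true(is.na(stop_replay) || stop_replay == cfg$max_epochs)
  }
})

test_that("the optimized loss is binary cross-entropy plus the L2 penalty", {
  net <- build_model(tiny_model(), seed = 31)
  d <- tiny_dataset(1, 1, seed = 31)
  enc <- encode_batch(d, "onehot")
  p <- predict_probability(net, enc$x)
  bce_hand <- -mean(enc$labels * log(p) + (1 - enc$labels) * log(1 - p))
  w <- coef(net)
  l2_hand <- net$config$l2_rate * (sum(w$W_conv^2) + sum(w$b_conv^2) +
                                   sum(w$W_fc^2) + sum(w$b_fc^2))
  expect_equal(snn6ma:::network_loss(net$weights, net$config, enc$x, enc$labels),
               bce_hand + l2_hand, tolerance = 1e-12)
})

test_that("empty training or validation sets are rejected", {
  d <- tiny_dataset(4, 4, seed = 1)
  enc <- encode_batch(d, "onehot")
  none <- list(x = enc$x[, , integer(0), drop = FALSE], labels = integer(0))
  net <- build_model(tiny_model(), seed = 1)
  expect_error(train_model(net, none, enc, tiny_training()), "non-empty",
               class = "snn6ma_validation_error")
  expect_error(train_model(net, enc, none, tiny_training()), "non-empty",
               class = "snn6ma_validation_error")
})
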