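# closed-form parameter count used as the oracle against the allocated arrays
oracle_param_count <- function(cfg) {
  geo <- list(conv = cfg$window_length - cfg$conv_kernel + 1L)
  geo$pool <- geo$conv %/% cfg$pool_size
  flat <- geo$pool * cfg$conv_filters
  c(conv = cfg$input_channels * cfg$conv_kernel * cfg$conv_filters + cfg$conv_filters,
    gn = 2L * cfg$conv_filters,
    fc = flat * cfg$fc_units + cfg$fc_units,
    out = cfg$fc_units + 1L)
}

# explicit-loop group normalization oracle
oracle_gn <- function(x, groups, gamma, beta, eps) {
  out <- x * 0
  cg <- nrow(x) / groups
  for (g in seq_len(groups)) {
    rows <- ((g - 1) * cg + 1):(g * cg)
    vals <- c()
    for (r in rows) for (p in seq_len(ncol(x))) vals <- c(vals, x[r, p])
    mu <- mean(vals)
    va <- mean((vals - mu)^2)
    for (r in rows) for (p in seq_len(ncol(x))) {
      out[r, p] <- gamma[r] * (x[r, p] - mu) / sqrt(va + eps) + beta[r]
    }
  }
  out
}

test_that("elu matches its closed form", {
  expect_equal(elu(0), 0)
  expect_equal(elu(2.5), 2.5)
  expect_equal(elu(-1), exp(-1) - 1)
  xs <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(elu(xs), ifelse(xs > 0, xs, exp(xs) - 1))
  expect_equal(elu(-2, alpha = 0.5), 0.5 * (exp(-2) - 1))
})

test_that("group_normalize matches a loop-based oracle and standardizes groups", {
  set.seed(11)
  x <- matrix(rnorm(16 * 9, sd = 3), 16, 9)
  gamma <- runif(16, 0.5, 2); beta <- rnorm(16)
  expect_equal(group_normalize(x, 4, gamma, beta, eps = 1e-3),
               oracle_gn(x, 4, gamma, beta, eps = 1e-3))
  # gamma=1, beta=0, negligible eps: every group has mean 0 and variance 1
  y <- group_normalize(x, 4, eps = 1e-12)
  for (g in 1:4) {
    vals <- y[((g - 1) * 4 + 1):(g * 4), ]
    expect_equal(mean(vals), 0, tolerance = 1e-8)
    expect_equal(mean(vals^2), 1, tolerance = 1e-6)
  }
  # constant input: variance degenerates, eps keeps the output finite at 0
  expect_equal(group_normalize(matrix(5, 8, 6), 2), matrix(0, 8, 6))
  # adding a constant to a group leaves the standardized output unchanged
  shifted <- x; shifted[1:4, ] <- shifted[1:4, ] + 100
  expect_equal(group_normalize(shifted, 4, eps = 1e-12), y, tolerance = 1e-6)
  # positive rescaling changes nothing up to the eps term
  expect_equal(group_normalize(x * 7, 4, eps = 1e-12), y, tolerance = 1e-6)
  expect_error(group_normalize(x, 5), "divisible", class = "snn6ma_validation_error")
})

test_that("model configuration enforces its invariants", {
  expect_error(model_config(conv_filters = 10, gn_groups = 4), "divisible",
               class = "snn6ma_validation_error")
  expect_error(model_config(window_length = 6, conv_kernel = 4, pool_size = 4),
               "pool_size", class = "snn6ma_validation_error")
  expect_error(model_config(dropout_rate = 1), class = "snn6ma_validation_error")
  lg <- model_config(large = TRUE)
  expect_equal(lg$conv_filters, 32)
  expect_equal(lg$fc_units, 64)
})

test_that("layer shapes and parameter counts match the closed-form oracle", {
  net <- build_model(model_config(), seed = 1)
  s <- summary(net)
  expect_equal(s$output_shape[s$component == "conv1d (ELU)"], "38 x 16")
  expect_equal(s$output_shape[s$component == "max_pool"], "9 x 16")
  expect_equal(s$output_shape[s$component == "flatten"], "144")
  expect_equal(s$output_shape[s$component == "dense (ELU)"], "32")
  expect_equal(s$output_shape[s$component == "sigmoid"], "1")
  oc <- oracle_param_count(model_config())
  expect_equal(attr(s, "total"), sum(oc))
  expect_equal(attr(s, "total"), 4977L)
  expect_equal(s$parameters[s$component == "conv1d (ELU)"], oc[["conv"]])

  lg <- build_model(model_config(large = TRUE), seed = 1)
  sl <- summary(lg)
  expect_equal(sl$output_shape[sl$component == "flatten"], "288")
  expect_equal(sl$parameters[sl$component == "dense (ELU)"], 288 * 64 + 64)

  # property: arbitrary valid configs over a grid
  for (f in c(8, 16, 32)) for (u in c(16, 64)) for (k in c(2, 6)) {
    cfg <- model_config(conv_filters = f, fc_units = u, conv_kernel = k)
    expect_equal(attr(summary(build_model(cfg, seed = 2)), "total"),
                 sum(oracle_param_count(cfg)))
  }
})

test_that("prediction is a deterministic probability with the zero-weight fixed point", {
  net <- build_model(tiny_model(), seed = 4)
  d <- tiny_dataset(6, 6, seed = 5)
  x <- encode_batch(d, "onehot")$x
  p1 <- predict_probability(net, x)
  expect_length(p1, 12L)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict_probability(net, x))
  expect_equal(predict_probability(net, x[, , integer(0), drop = FALSE]), numeric(0))
  # all-zero weights force the logit to 0 hence probability exactly 0.5
  zero <- net
  zero$weights <- lapply(net$weights, function(w) w * 0)
  expect_equal(predict_probability(zero, x), rep(0.5, 12L))
  expect_error(predict_probability(net, x[1:3, , , drop = FALSE]), "shape",
               class = "snn6ma_validation_error")
})

test_that("the 0.5 decision rule is strict", {
  expect_identical(classify(c(0.51, 0.49, 0.5, 0, 1)), c(1L, 0L, 0L, 0L, 1L))
  expect_identical(classify(numeric(0)), integer(0))
  expect_error(classify(1.2), class = "snn6ma_validation_error")
})
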