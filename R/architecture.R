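#' Network architecture configuration
#'
#' Hyperparameters of the shallow convolutional 6mA classifier. The defaults
#' are the published recipe: 16 convolution filters of length 4 with ELU
#' activation and L2 penalty 1e-4 on weights and bias, group normalization
#' with 4 groups, non-overlapping max pooling of size 4, dropout 0.25, a
#' 32-unit fully connected ELU layer (same L2 penalty), and a single sigmoid
#' output unit. \code{large = TRUE} selects the higher-capacity variant used
#' on the larger benchmark: 32 filters and 64 hidden units.
#'
#' @param window_length Input sequence length in bp (default 41).
#' @param input_channels Rows of the encoded matrix (4 for both encodings).
#' @param conv_filters Number of convolution filters (default 16).
#' @param conv_kernel Filter length in positions (default 4).
#' @param l2_rate L2 regularization rate for convolution and fully connected
#'   weights and biases (default 1e-4).
#' @param gn_groups Number of group-normalization groups (default 4); must
#'   divide \code{conv_filters}.
#' @param pool_size Max-pooling window (and stride; windows do not overlap).
#' @param dropout_rate Fraction of pooled activations dropped during
#'   training (default 0.25); inactive at inference.
#' @param fc_units Hidden units in the fully connected layer (default 32).
#' @param gn_position \code{"after_activation"} applies group normalization
#'   to the ELU output of the convolution (the component order as published:
#'   activation belongs to the convolution component, normalization is the
#'   second component); \code{"before_activation"} is the conventional
#'   alternative.
#' @param gn_eps Variance-stabilizing epsilon of group normalization.
#' @param large If \code{TRUE}, override \code{conv_filters} to 32 and
#'   \code{fc_units} to 64.
#' @return An object of class \code{snn_model_config}.
#' @examples
#' model_config()
#' model_config(large = TRUE)
#' @export
model_config <- function(window_length = 41, input_channels = 4,
                         conv_filters = 16, conv_kernel = 4,
                         l2_rate = 1e-4, gn_groups = 4, pool_size = 4,
                         dropout_rate = 0.25, fc_units = 32,
                         gn_position = c("after_activation", "before_activation"),
                         gn_eps = 1e-3, large = FALSE) {
  if (isTRUE(large)) {
    if (missing(conv_filters)) conv_filters <- 32
    if (missing(fc_units)) fc_units <- 64
  }
  cfg <- list(
    window_length = check_count(window_length, "window_length", min = 2),
    input_channels = check_count(input_channels, "input_channels"),
    conv_filters = check_count(conv_filters, "conv_filters"),
    conv_kernel = check_count(conv_kernel, "conv_kernel"),
    l2_rate = check_fraction(l2_rate, "l2_rate", lo = 0, hi = Inf),
    gn_groups = check_count(gn_groups, "gn_groups"),
    pool_size = check_count(pool_size, "pool_size"),
    dropout_rate = check_fraction(dropout_rate, "dropout_rate", hi = 1, hi_open = TRUE),
    fc_units = check_count(fc_units, "fc_units"),
    gn_position = match.arg(gn_position),
    gn_eps = check_fraction(gn_eps, "gn_eps", lo = 0, hi = 1, lo_open = TRUE))
  if (cfg$conv_filters %% cfg$gn_groups != 0) {
    stop_validation(sprintf("conv_filters (%d) must be divisible by gn_groups (%d)",
                            cfg$conv_filters, cfg$gn_groups))
  }
  if (cfg$conv_kernel > cfg$window_length) {
    stop_validation("conv_kernel cannot exceed window_length")
  }
  conv_len <- cfg$window_length - cfg$conv_kernel + 1L
  if (cfg$pool_size > conv_len) {
    stop_validation(sprintf("pool_size (%d) exceeds convolution output length (%d)",
                            cfg$pool_size, conv_len))
  }
  structure(cfg, class = "snn_model_config")
}

#' @export
print.snn_model_config <- function(x, ...) {
  cat("6mA convolutional network configuration\n")
  cat(sprintf("  input: %d x %d encoded sequence\n", x$input_channels, x$window_length))
  cat(sprintf("  conv: %d filters of length %d, ELU, L2 %g\n",
              x$conv_filters, x$conv_kernel, x$l2_rate))
  cat(sprintf("  group norm: %d groups (%s, eps %g)\n", x$gn_groups, x$gn_position, x$gn_eps))
  cat(sprintf("  max pool: %d | dropout: %g | FC: %d units, ELU, L2 %g | sigmoid output\n",
              x$pool_size, x$dropout_rate, x$fc_units, x$l2_rate))
  invisible(x)
}

#' Exponential linear unit
#'
#' \code{elu(x) = x} for \code{x > 0} and \code{alpha * (exp(x) - 1)}
#' otherwise; continuous at 0 and bounded below by \code{-alpha}.
#'
#' @param x Numeric vector, matrix or array.
#' @param alpha Saturation magnitude for negative inputs (default 1).
#' @return Object of the same shape as \code{x}.
#' @export
elu <- function(x, alpha = 1) {
  ifelse(x > 0, x, alpha * (exp(pmin(x, 0)) - 1))
}

elu_grad <- function(pre) {
  # derivative w.r.t. the pre-activation (alpha = 1): 1 for x > 0, exp(x) otherwise
  ifelse(pre > 0, 1, exp(pmin(pre, 0)))
}

#' Group normalization of a single sample
#'
#' Splits the channels (rows) of a channels x positions activation matrix
#' into \code{groups} contiguous groups and standardizes each group to mean
#' 0 and variance 1 over that group's channels and all positions, then
#' applies a per-channel affine transform. Unlike batch normalization the
#' statistics are per sample, so the operation is insensitive to batch size.
#'
#' @param x Numeric matrix, channels in rows, positions in columns.
#' @param groups Number of contiguous channel groups; must divide
#'   \code{nrow(x)}.
#' @param gamma Per-channel scale (recycled if length 1).
#' @param beta Per-channel shift (recycled if length 1).
#' @param eps Small positive constant added to the variance (default 1e-3).
#' @return A matrix of the same shape as \code{x}.
#' @export
group_normalize <- function(x, groups, gamma = 1, beta = 0, eps = 1e-3) {
  stopifnot(is.matrix(x))
  C <- nrow(x)
  groups <- check_count(groups, "groups")
  if (C %% groups != 0) {
    stop_validation(sprintf("channel count (%d) must be divisible by groups (%d)", C, groups))
  }
  gamma <- rep_len(gamma, C)
  beta <- rep_len(beta, C)
  cg <- C %/% groups
  out <- x
  for (g in seq_len(groups)) {
    rows <- ((g - 1L) * cg + 1L):(g * cg)
    v <- x[rows, , drop = FALSE]
    mu <- mean(v)
    # population variance, matching the normalization layer convention
    va <- mean((v - mu)^2)
    out[rows, ] <- (v - mu) / sqrt(va + eps)
  }
  out * gamma + beta
}

layer_geometry <- function(config) {
  conv_len <- config$window_length - config$conv_kernel + 1L
  pool_len <- conv_len %/% config$pool_size
  flat <- pool_len * config$conv_filters
  list(conv_len = conv_len, pool_len = pool_len, flat = flat)
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Construct an untrained 6mA network
#'
#' Allocates and initializes the weights of the eight-component network
#' described by a [model_config()]: convolution (ELU) -> group
#' normalization -> max pooling -> dropout -> flatten -> fully connected
#' (ELU) -> sigmoid output. Convolution and fully connected weights use
#' Glorot-uniform initialization under the given seed; biases start at zero
#' and the normalization scale/shift at 1/0.
#'
#' @param config A [model_config()].
#' @param seed Integer seed making initialization reproducible
#'   (default 1).
#' @return An object of class \code{snn_network} holding the configuration
#'   and the weight arrays. Its \code{summary()} reports per-component
#'   output shapes and parameter counts.
#' @examples
#' net <- build_model(model_config(), seed = 1)
#' summary(net)
#' @export
build_model <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "snn_model_config"))
  geo <- layer_geometry(config)
  k <- config$conv_kernel; ch <- config$input_channels
  f <- config$conv_filters; u <- config$fc_units
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  weights <- list(
    W_conv = glorot_uniform(f, ch * k, fan_in = ch * k, fan_out = f * k),
    b_conv = numeric(f),
    gamma = rep(1, f),
    beta = numeric(f),
    W_fc = glorot_uniform(u, geo$flat, fan_in = geo$flat, fan_out = u),
    b_fc = numeric(u),
    w_out = glorot_uniform(1, u, fan_in = u, fan_out = 1),
    b_out = 0)
  structure(list(config = config, weights = weights, seed = seed),
            class = "snn_network")
}

#' Per-component shapes and parameter counts of a network
#'
#' @param object An \code{snn_network}.
#' @param ... Ignored.
#' @return A data frame with columns \code{component},
#'   \code{output_shape} and \code{parameters}; total parameters as
#'   attribute \code{"total"} (counted from the allocated weight arrays,
#'   not from a formula).
#' @export
summary.snn_network <- function(object, ...) {
  cfg <- object$config; geo <- layer_geometry(cfg); w <- object$weights
  df <- data.frame(
    component = c("conv1d (ELU)", "group_norm", "max_pool", "dropout",
                  "flatten", "dense (ELU)", "sigmoid"),
    output_shape = c(
      sprintf("%d x %d", geo$conv_len, cfg$conv_filters),
      sprintf("%d x %d", geo$conv_len, cfg$conv_filters),
      sprintf("%d x %d", geo$pool_len, cfg$conv_filters),
      sprintf("%d x %d", geo$pool_len, cfg$conv_filters),
      sprintf("%d", geo$flat),
      sprintf("%d", cfg$fc_units),
      "1"),
    parameters = c(
      length(w$W_conv) + length(w$b_conv),
      length(w$gamma) + length(w$beta),
      0L, 0L, 0L,
      length(w$W_fc) + length(w$b_fc),
      length(w$w_out) + length(w$b_out)),
    stringsAsFactors = FALSE)
  attr(df, "total") <- sum(df$parameters)
  class(df) <- c("snn_layer_summary", "data.frame")
  df
}

#' @export
print.snn_layer_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n", attr(x, "total")))
  invisible(x)
}

#' @export
print.snn_network <- function(x, ...) {
  cat("6mA convolutional network")
  cat(if (is.null(x$trained)) " (untrained)\n" else " (trained)\n")
  print(summary(x))
  invisible(x)
}

#' Extract network weights
#'
#' @param object An \code{snn_network}.
#' @param ... Ignored.
#' @return The named list of weight arrays (convolution, normalization,
#'   fully connected and output parameters).
#' @export
coef.snn_network <- function(object, ...) object$weights

as_input_array <- function(x, config) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop_validation("input must be a 4 x L matrix, a 4 x L x n array, or an encode_batch() result")
  }
  d <- dim(x)
  if (d[1L] != config$input_channels || d[2L] != config$window_length) {
    stop_validation(sprintf(
      "input shape %d x %d does not match the model's expected %d x %d",
      d[1L], d[2L], config$input_channels, config$window_length))
  }
  x
}

#' Predict 6mA probabilities for encoded sequences
#'
#' Runs the forward pass with dropout inactive, yielding one probability per
#' sample that the window's central base is a 6mA site. Deterministic for
#' fixed weights.
#'
#' @param model An \code{snn_network}.
#' @param batch A 4 x L matrix (single sequence), a 4 x L x n array, or the
#'   result of [encode_batch()].
#' @return Numeric vector of probabilities in (0, 1), one per sample.
#' @export
predict_probability <- function(model, batch) {
  stopifnot(inherits(model, "snn_network"))
  x <- as_input_array(batch, model$config)
  if (dim(x)[3L] == 0L) return(numeric(0))
  network_forward(model$weights, model$config, x, training = FALSE)$p
}

#' Apply the 0.5 decision rule to probabilities
#'
#' Labels a sample positive (1) exactly when its predicted probability
#' exceeds 0.5; a probability of exactly 0.5 is assigned to the negative
#' class.
#'
#' @param probabilities Numeric vector in [0, 1].
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities) {
  if (length(probabilities) == 0L) return(integer(0))
  if (!is.numeric(probabilities) || anyNA(probabilities) ||
      any(probabilities < 0 | probabilities > 1)) {
    stop_validation("probabilities must be numeric values in [0, 1]")
  }
  as.integer(probabilities > 0.5)
}
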