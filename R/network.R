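# Internal network engine: vectorized forward and backward passes over a
# batch, the regularized binary cross-entropy loss, and the SGD-with-momentum
# update. Activations for a batch of n sequences are held as F x (P*n)
# matrices (filters in rows; columns are sample-major blocks of P positions),
# so every layer reduces to dense matrix algebra.

BCE_EPS <- 1e-7

im2col_index <- function(config) {
  ch <- config$input_channels
  k <- config$conv_kernel
  P <- config$window_length - k + 1L
  base <- as.vector(outer(seq_len(ch), (seq_len(k) - 1L) * ch, "+"))
  outer(base, (seq_len(P) - 1L) * ch, "+") # (ch*k) x P
}

# reshape helpers between F x (P*n) layout and the per-(group, sample)
# column space used by the normalization statistics
gn_to_groups <- function(v, cg, groups, P, n) {
  dim(v) <- c(cg, groups, P, n)
  matrix(aperm(v, c(1, 3, 2, 4)), cg * P, groups * n)
}

gn_from_groups <- function(M, cg, groups, P, n) {
  arr <- array(M, dim = c(cg, P, groups, n))
  matrix(aperm(arr, c(1, 3, 2, 4)), cg * groups, P * n)
}

gn_forward_batch <- function(v, gamma, beta, groups, eps, P, n) {
  f <- nrow(v)
  cg <- f %/% groups
  M <- gn_to_groups(v, cg, groups, P, n)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = cg * P)
  va <- colMeans(Mc^2)
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- gn_from_groups(Mc * rep(inv_sd, each = cg * P), cg, groups, P, n)
  list(y = xhat * gamma + beta, xhat = xhat, inv_sd = inv_sd)
}

gn_backward_batch <- function(dy, cache, gamma, groups, P, n) {
  f <- nrow(dy)
  cg <- f %/% groups
  m <- cg * P
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  Dh <- gn_to_groups(dy * gamma, cg, groups, P, n)
  Xh <- gn_to_groups(cache$xhat, cg, groups, P, n)
  m1 <- colMeans(Dh)
  m2 <- colMeans(Dh * Xh)
  DxM <- (Dh - rep(m1, each = m) - Xh * rep(m2, each = m)) * rep(cache$inv_sd, each = m)
  list(dx = gn_from_groups(DxM, cg, groups, P, n), dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

network_forward <- function(weights, config, x, training = FALSE) {
  d <- dim(x)
  n <- d[3L]
  ch <- config$input_channels
  L <- config$window_length
  P <- L - config$conv_kernel + 1L
  f <- config$conv_filters
  s <- config$pool_size
  Pp <- P %/% s

  idx <- im2col_index(config)
  xm <- matrix(x, ch * L, n)
  Z <- xm[as.vector(idx), , drop = FALSE]
  dim(Z) <- c(nrow(idx), P * n)

  C <- weights$W_conv %*% Z + weights$b_conv
  if (config$gn_position == "after_activation") {
    A <- elu(C)
    gn <- gn_forward_batch(A, weights$gamma, weights$beta, config$gn_groups,
                           config$gn_eps, P, n)
    G <- gn$y
  } else {
    gn <- gn_forward_batch(C, weights$gamma, weights$beta, config$gn_groups,
                           config$gn_eps, P, n)
    A <- gn$y
    G <- elu(A)
  }

  # non-overlapping max pooling over positions; trailing positions beyond
  # the last full window are discarded (floor semantics)
  arr <- G
  dim(arr) <- c(f, P, n)
  A3 <- arr[, seq_len(s * Pp), , drop = FALSE]
  dim(A3) <- c(f, s, Pp, n)
  pool <- A3[, 1L, , , drop = FALSE]
  dim(pool) <- c(f, Pp, n)
  widx <- array(1L, dim = c(f, Pp, n))
  if (s > 1L) {
    for (j in 2:s) {
      slice <- A3[, j, , , drop = FALSE]
      dim(slice) <- c(f, Pp, n)
      upd <- slice > pool
      pool[upd] <- slice[upd]
      widx[upd] <- j
    }
  }
  flat <- matrix(pool, f * Pp, n)

  mask <- NULL
  if (training && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    mask <- matrix((stats::runif(length(flat)) < keep) / keep, nrow(flat), n)
    flat <- flat * mask
  }

  H <- weights$W_fc %*% flat + weights$b_fc
  Hf <- elu(H)
  zo <- as.vector(weights$w_out %*% Hf) + weights$b_out
  p <- sigmoid(zo)

  list(p = p, Z = Z, C = C, A = A, gn = gn, widx = widx, mask = mask,
       flat = flat, H = H, Hf = Hf, P = P, Pp = Pp, n = n)
}

l2_penalty <- function(weights, l2_rate) {
  l2_rate * (sum(weights$W_conv^2) + sum(weights$b_conv^2) +
             sum(weights$W_fc^2) + sum(weights$b_fc^2))
}

binary_crossentropy <- function(y, p) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

network_loss <- function(weights, config, x, y) {
  p <- network_forward(weights, config, x, training = FALSE)$p
  binary_crossentropy(y, p) + l2_penalty(weights, config$l2_rate)
}

network_backward <- function(weights, config, cache, y) {
  n <- cache$n
  f <- config$conv_filters
  s <- config$pool_size
  P <- cache$P
  Pp <- cache$Pp
  l2 <- config$l2_rate

  dz <- (cache$p - y) / n # d(mean BCE)/d(logit)
  dw_out <- dz %*% t(cache$Hf)
  db_out <- sum(dz)
  dHf <- t(weights$w_out) %*% matrix(dz, 1L, n)
  dH <- dHf * elu_grad(cache$H)
  dW_fc <- dH %*% t(cache$flat) + 2 * l2 * weights$W_fc
  db_fc <- rowSums(dH) + 2 * l2 * weights$b_fc
  dflat <- t(weights$W_fc) %*% dH
  if (!is.null(cache$mask)) dflat <- dflat * cache$mask

  darr <- dflat
  dim(darr) <- c(f, Pp, n)
  dA3 <- array(0, dim = c(f, s, Pp, n))
  for (j in seq_len(s)) {
    sel <- cache$widx == j
    slice <- array(0, dim = c(f, Pp, n))
    slice[sel] <- darr[sel]
    dA3[, j, , ] <- slice
  }
  dG <- array(0, dim = c(f, P, n))
  dim(dA3) <- c(f, s * Pp, n)
  dG[, seq_len(s * Pp), ] <- dA3
  dG <- matrix(dG, f, P * n)

  if (config$gn_position == "after_activation") {
    gnb <- gn_backward_batch(dG, cache$gn, weights$gamma, config$gn_groups, P, n)
    dC <- gnb$dx * elu_grad(cache$C)
  } else {
    dA <- dG * elu_grad(cache$A)
    gnb <- gn_backward_batch(dA, cache$gn, weights$gamma, config$gn_groups, P, n)
    dC <- gnb$dx
  }
  dW_conv <- dC %*% t(cache$Z) + 2 * l2 * weights$W_conv
  db_conv <- rowSums(dC) + 2 * l2 * weights$b_conv

  list(W_conv = dW_conv, b_conv = db_conv,
       gamma = gnb$dgamma, beta = gnb$dbeta,
       W_fc = dW_fc, b_fc = db_fc,
       w_out = dw_out, b_out = db_out)
}

zero_velocity <- function(weights) lapply(weights, function(w) w * 0)

sgd_step <- function(weights, grads, velocity, lr, momentum) {
  for (nm in names(weights)) {
    velocity[[nm]] <- momentum * velocity[[nm]] - lr * grads[[nm]]
    weights[[nm]] <- weights[[nm]] + velocity[[nm]]
  }
  list(weights = weights, velocity = velocity)
}
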