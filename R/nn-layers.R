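# Minimal neural-network engine: layer primitives with hand-derived
# backward passes, operating on batch-major tensors.
#
# Conventions:
#   sequence tensors: 3-D arrays [B, L, C] (batch, time, channels)
#   dense tensors:    matrices   [B, D]
#   every *_fwd returns list(out, cache); the matching *_bwd consumes the
#   cache and the upstream gradient and returns dX plus parameter gradients.
# All initializations draw from the caller's (seeded) RNG stream.

glorot_mat <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

dense_init <- function(nin, nout) list(W = glorot_mat(nin, nout), b = numeric(nout))

dense_fwd <- function(X, W, b) {
  out <- X %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = X)
}

dense_bwd <- function(dY, W, X) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dY, mask) dY * mask

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - p
  mask <- array((stats::runif(length(X)) < keep) / keep, dim = dim(X) %||% length(X))
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- 1-D convolution (same padding) via im2col + BLAS -------------------------

conv1d_init <- function(K, cin, cout) {
  list(W = glorot_mat(K * cin, cout), b = numeric(cout))
}

im2col <- function(X, K) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  pad <- (K - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  cols <- vector("list", K)
  for (k in seq_len(K)) {
    sl <- Xp[, k:(k + L - 1L), , drop = FALSE]
    dim(sl) <- c(B * L, C)
    cols[[k]] <- sl
  }
  do.call(cbind, cols)  # (B*L) x (K*C)
}

conv1d_fwd <- function(X, W, b, K) {
  d <- dim(X); B <- d[1]; L <- d[2]
  Xcol <- im2col(X, K)
  out <- Xcol %*% W
  out <- sweep(out, 2, b, "+")
  dim(out) <- c(B, L, ncol(W))
  list(out = out, cache = list(Xcol = Xcol, dims = d))
}

conv1d_bwd <- function(dY, W, cache, K) {
  d <- cache$dims; B <- d[1]; L <- d[2]; C <- d[3]
  cout <- ncol(W)
  dYm <- dY; dim(dYm) <- c(B * L, cout)
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(W)  # (B*L) x (K*C)
  pad <- (K - 1L) %/% 2L
  dXp <- array(0, c(B, L + 2L * pad, C))
  for (k in seq_len(K)) {
    blk <- dXcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(blk) <- c(B, L, C)
    dXp[, k:(k + L - 1L), ] <- dXp[, k:(k + L - 1L), , drop = FALSE] + blk
  }
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# -- batch normalization over batch and time, per channel ---------------------

bn_init <- function(C) list(g = rep(1, C), b = numeric(C))
bn_state_init <- function(C) list(mean = numeric(C), var = rep(1, C))

bn_fwd <- function(X, g, b, state, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(X); C <- d[3]
  Xm <- X; dim(Xm) <- c(d[1] * d[2], C)
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2, mu)
    v <- colMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(Xm, 2, mu)
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_std, "*")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv_std = inv_std, dims = d),
       state = state)
}

bn_bwd <- function(dY, g, cache) {
  d <- cache$dims; N <- d[1] * d[2]
  dYm <- dY; dim(dYm) <- c(N, d[3])
  xhat <- cache$xhat
  dg <- colSums(dYm * xhat)
  db <- colSums(dYm)
  dxhat <- sweep(dYm, 2, g, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- sweep(dxhat, 2, s1 / N) - sweep(xhat, 2, s2 / N, "*")
  dX <- sweep(dX, 2, cache$inv_std, "*")
  dim(dX) <- d
  list(dX = dX, dg = dg, db = db)
}

# -- max pooling, factor 2 (odd tail dropped; ties keep the left sample) ------

maxpool2_fwd <- function(X) {
  d <- dim(X); Lo <- d[2] %/% 2L
  a <- X[, seq(1L, 2L * Lo, by = 2L), , drop = FALSE]
  b <- X[, seq(2L, 2L * Lo, by = 2L), , drop = FALSE]
  left <- a >= b
  list(out = a * left + b * !left, cache = list(left = left, dims = d))
}

maxpool2_bwd <- function(dY, cache) {
  d <- cache$dims; Lo <- d[2] %/% 2L
  dX <- array(0, d)
  dX[, seq(1L, 2L * Lo, by = 2L), ] <- dY * cache$left
  dX[, seq(2L, 2L * Lo, by = 2L), ] <- dY * !cache$left
  dX
}

# -- nearest-neighbour upsampling, factor 2 -----------------------------------

upsample2_fwd <- function(X) {
  d <- dim(X)
  out <- array(0, c(d[1], 2L * d[2], d[3]))
  out[, seq(1L, 2L * d[2], by = 2L), ] <- X
  out[, seq(2L, 2L * d[2], by = 2L), ] <- X
  out
}

upsample2_bwd <- function(dY) {
  d <- dim(dY)
  dY[, seq(1L, d[2], by = 2L), , drop = FALSE] +
    dY[, seq(2L, d[2], by = 2L), , drop = FALSE]
}

# -- bidirectional LSTM wrapper over the compiled kernels ---------------------

lstm_init <- function(H, input_dim = 1L) {
  s <- sqrt(6 / (input_dim + 4 * H))
  sh <- sqrt(6 / (H + 4 * H))
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = stats::runif(4 * H, -s, s),
       Wh = matrix(stats::runif(H * 4 * H, -sh, sh), H, 4 * H),
       b = b)
}

# X: matrix B x L of the scalar-feature sequence. Returns the concatenated
# final hidden states of the forward and reversed passes (B x 2H).
bilstm_fwd <- function(X, pf, pb) {
  f <- .lstm_forward(X, pf$Wx, pf$Wh, pf$b)
  r <- .lstm_forward(X[, ncol(X):1, drop = FALSE], pb$Wx, pb$Wh, pb$b)
  list(out = cbind(f$h_last, r$h_last), cache = list(f = f$cache, r = r$cache))
}

bilstm_bwd <- function(dH, pf, pb, cache, H) {
  df <- .lstm_backward(cache$f, pf$Wx, pf$Wh, dH[, seq_len(H), drop = FALSE])
  dr <- .lstm_backward(cache$r, pb$Wx, pb$Wh,
                       dH[, H + seq_len(H), drop = FALSE])
  list(dX = df$dx + dr$dx[, ncol(dr$dx):1, drop = FALSE],
       f = list(dWx = df$dWx, dWh = df$dWh, db = df$db),
       r = list(dWx = dr$dWx, dWh = dr$dWh, db = dr$db))
}

# -- losses -------------------------------------------------------------------

# numerically stable binary cross-entropy on logits; y in {0,1}
bce_logits_loss <- function(z, y, pos_weight = 1) {
  w <- ifelse(y == 1, pos_weight, 1)
  l <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  loss <- sum(w * l) / length(z)
  dz <- w * (stats::plogis(z) - y) / length(z)
  list(loss = loss, dz = dz)
}

mse_loss <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d^2), dz = 2 * d / length(d))
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# clip the global gradient norm (stabilizes the recurrent nets early on)
clip_grads <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}
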