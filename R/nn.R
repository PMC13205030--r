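# Minimal neural-network engine for the dual-input detector.
#
# Activations flow as plain matrices; convolutional feature maps over beats
# are kept as (N*L, C) matrices whose row order is sample-index n fastest,
# position l next, so that im2col, pooling and per-beat flattening are all
# cheap reshapes. Every layer has a hand-derived backward pass; correctness
# is pinned by central finite-difference tests.

NN_EPS <- 1e-5

# fast column-wise add / multiply (sweep() is too slow in hot loops)
addc <- function(X, b) X + rep(b, each = nrow(X))
mulc <- function(X, s) X * rep(s, each = nrow(X))

relu <- function(X) cpp_relu(X)
relu_bwd <- function(dY, Y) cpp_relu_bwd(dY, Y)

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(prod(dims), -lim, lim), dims[1], dims[2])
}

# -- conv primitives ---------------------------------------------------------

# A: (N*L, C) matrix, row order n fastest. Returns (N*L, K*C) patch matrix
# for 'same' zero padding (K odd); C++ kernels do the data movement.
im2col <- function(A, N, L, C, K) cpp_im2col(A, N, L, C, K)

col2im <- function(dM, N, L, C, K) cpp_col2im(dM, N, L, C, K)

# conv layers feed straight into batch norm, so they carry no bias
conv_fwd <- function(A, N, L, C, K, W) {
  M <- im2col(A, N, L, C, K)
  list(Z = M %*% W, M = M)
}

conv_bwd <- function(dZ, cache, N, L, C, K, W) {
  dW <- crossprod(cache$M, dZ)
  dA <- col2im(tcrossprod(dZ, W), N, L, C, K)
  list(dA = dA, dW = dW)
}

# -- batch norm --------------------------------------------------------------

bn_fwd <- function(X, g, b, state, key, training, momentum = 0.9) {
  if (training) {
    r <- cpp_bn_fwd(X, g, b, NN_EPS)
    inv <- 1 / sqrt(r$var + NN_EPS)
    state[[paste0(key, "_rm")]] <- momentum * (state[[paste0(key, "_rm")]] %||% r$mu) + (1 - momentum) * r$mu
    state[[paste0(key, "_rv")]] <- momentum * (state[[paste0(key, "_rv")]] %||% r$var) + (1 - momentum) * r$var
  } else {
    mu <- state[[paste0(key, "_rm")]] %||% rep(0, ncol(X))
    v <- state[[paste0(key, "_rv")]] %||% rep(1, ncol(X))
    inv <- 1 / sqrt(v + NN_EPS)
    r <- cpp_bn_apply(X, mu, v, g, b, NN_EPS)
  }
  list(Y = r$Y, cache = list(xh = r$xh, inv = inv, training = training), state = state)
}

bn_bwd <- function(dY, cache, g) {
  if (cache$training) {
    cpp_bn_bwd(dY, cache$xh, g * cache$inv)
  } else {
    list(dX = mulc(dY, g * cache$inv),
         dg = colSums(dY * cache$xh), db = colSums(dY))
  }
}

# -- pooling / dropout -------------------------------------------------------

pool_fwd <- function(X, N, L) cpp_pool_fwd(X, N, L)

pool_bwd <- function(dY, cache, N, L, C) cpp_pool_bwd(dY, cache$mask, N, L)

dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)   # recycled col-major
  list(Y = X * mask, mask = mask)
}

# -- LSTM --------------------------------------------------------------------

lstm_init <- function(D, H) {
  Wx <- glorot(D, 4 * H)
  Wh <- glorot(H, 4 * H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1   # forget-gate bias
  list(Wx = Wx, Wh = Wh, b = b)
}

sigm <- function(x) 1 / (1 + exp(-x))

# xs: list of T matrices (B, D); returns final hidden state and caches.
lstm_fwd <- function(xs, Wx, Wh, b) {
  B <- nrow(xs[[1]]); H <- nrow(Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- addc(xs[[t]] %*% Wx + h %*% Wh, b)
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    caches[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, cc = cc,
                        h_prev = h)
    h <- o * tanh(cc)
  }
  list(h = h, caches = caches)
}

lstm_bwd <- function(dh_T, xs, caches, Wx, Wh) {
  B <- nrow(dh_T); H <- ncol(dh_T); TT <- length(xs)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4 * H)
  dxs <- vector("list", TT)
  dh <- dh_T
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    ch <- caches[[t]]
    tc <- tanh(ch$cc)
    do <- dh * tc
    dc <- dc + dh * ch$o * (1 - tc^2)
    di <- dc * ch$g
    df <- dc * ch$c_prev
    dg <- dc * ch$i
    dz <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do * ch$o * (1 - ch$o))
    dWx <- dWx + crossprod(xs[[t]], dz)
    dWh <- dWh + crossprod(ch$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- tcrossprod(dz, Wx)
    dh <- tcrossprod(dz, Wh)
    dc <- dc * ch$f
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# -- losses ------------------------------------------------------------------

softmax <- function(Z) {
  m <- apply(Z, 1, max)
  e <- exp(Z - m)
  e / rowSums(e)
}

#' Focal loss
#'
#' `FL = -alpha * (1 - p)^gamma * ln(p)` for `p` the predicted probability of
#' the true class, averaged over the batch. `gamma = 0`, `alpha = 1` reduces
#' to cross-entropy. Probabilities are clipped below at 1e-7.
#'
#' @param p probabilities of the true class.
#' @param gamma focusing exponent.
#' @param alpha scalar weight.
#' @return mean loss.
#' @export
focal_loss <- function(p, gamma = 2, alpha = 0.25) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p <- pmax(p, 1e-7)
  mean(-alpha * (1 - p)^gamma * log(p))
}

# Gradient of the mean focal loss wrt the logits. probs: (B, K); y: integer
# class in 1..K.
focal_loss_grad <- function(probs, y, gamma, alpha) {
  B <- nrow(probs)
  pt <- pmax(probs[cbind(seq_len(B), y)], 1e-7)
  # dL/dpt for one sample (before the 1/B mean)
  dlp <- -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  # dpt/dz_j = pt * (1[j = y] - p_j)
  dz <- -probs * (dlp * pt)
  dz[cbind(seq_len(B), y)] <- dz[cbind(seq_len(B), y)] + dlp * pt
  dz / B
}

# -- Adam --------------------------------------------------------------------

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(grads)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * (opt$m[[k]] %||% (g * 0)) + (1 - beta1) * g
    opt$v[[k]] <- beta2 * (opt$v[[k]] %||% (g * 0)) + (1 - beta2) * g^2
    params[[k]] <- params[[k]] - lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
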