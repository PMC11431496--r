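# Numerical kernels for the detector network: 1D convolution (im2col),
# batch normalization, ReLU, LSTM and Adam, each with analytic backward
# passes.  Tensors are R arrays with dims (batch, time, channels).  These
# are internal; the architecture lives in model.R.

# "Same"-style padding: output length ceiling(T / stride); even kernels get
# the extra pad sample on the left so length arithmetic stays exact.
conv_padding <- function(T_in, k, stride) {
  out <- ceiling(T_in / stride)
  pt <- max(0L, (out - 1L) * stride + k - T_in)
  list(out = out, left = pt - pt %/% 2L, right = pt %/% 2L)
}

# The convolution is evaluated as a sum over kernel offsets of shifted
# (B*T, Cin) x (Cin, Cout) products, on a row-major-in-batch flattening of
# the padded input.  For stride 1 each offset is a contiguous row range, so
# no im2col buffer is materialized.
conv_rows <- function(j, base, B) {
  # row indices of the flattened (B * Tp, Cin) matrix for kernel offset j
  if (length(base) == 0L) return(integer(0))
  if (length(base) > 1L && base[2] - base[1] == 1L) {
    ((base[1] + j - 2L) * B + 1L):((base[length(base)] + j - 1L) * B)
  } else {
    rep((base + j - 2L) * B, each = B) + seq_len(B)
  }
}

conv1d_fwd <- function(X, W, b, k, stride = 1L) {
  d <- dim(X); B <- d[1]; T_in <- d[2]; Cin <- d[3]
  Cout <- ncol(W)
  p <- conv_padding(T_in, k, stride)
  To <- p$out
  Tp <- T_in + p$left + p$right
  Xpm <- matrix(0, B * Tp, Cin)
  Xpm[(p$left * B + 1L):((p$left + T_in) * B), ] <- matrix(X, B * T_in, Cin)
  base <- (seq_len(To) - 1L) * stride + 1L
  Y <- matrix(rep(b, each = B * To), B * To, Cout)
  for (j in seq_len(k)) {
    rows <- conv_rows(j, base, B)
    Y <- Y + Xpm[rows, , drop = FALSE] %*%
      W[((j - 1L) * Cin + 1L):(j * Cin), , drop = FALSE]
  }
  list(Y = array(Y, c(B, To, Cout)),
       cache = list(Xpm = Xpm, dims = d, k = k, stride = stride, pad = p,
                    W = W))
}

conv1d_bwd <- function(dY, cache) {
  d <- cache$dims; B <- d[1]; T_in <- d[2]; Cin <- d[3]
  p <- cache$pad; k <- cache$k; stride <- cache$stride
  W <- cache$W
  To <- p$out
  Tp <- T_in + p$left + p$right
  Cout <- dim(dY)[3]
  dYm <- matrix(dY, B * To, Cout)
  db <- colSums(dYm)
  dW <- matrix(0, k * Cin, Cout)
  dXpm <- matrix(0, B * Tp, Cin)
  base <- (seq_len(To) - 1L) * stride + 1L
  for (j in seq_len(k)) {
    rows <- conv_rows(j, base, B)
    cols <- ((j - 1L) * Cin + 1L):(j * Cin)
    dW[cols, ] <- crossprod(cache$Xpm[rows, , drop = FALSE], dYm)
    dXpm[rows, ] <- dXpm[rows, , drop = FALSE] +
      dYm %*% t(W[cols, , drop = FALSE])
  }
  dX <- array(dXpm[(p$left * B + 1L):((p$left + T_in) * B), , drop = FALSE],
              c(B, T_in, Cin))
  list(dX = dX, dW = dW, db = db)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(X, gamma, beta, running, training) {
  d <- dim(X)
  Xm <- matrix(X, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    v <- pmax(v, 0)
    running$mean <- (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu
    running$var <- (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  ivar <- 1 / sqrt(v + BN_EPS)
  xhat <- (Xm - rep(mu, each = nrow(Xm))) * rep(ivar, each = nrow(Xm))
  Y <- xhat * rep(gamma, each = nrow(Xm)) + rep(beta, each = nrow(Xm))
  list(Y = array(Y, d), running = running,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, dims = d,
                    training = training))
}

bn_bwd <- function(dY, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dYm <- matrix(dY, n, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(cache$gamma, each = n)
  if (cache$training) {
    sx <- colSums(dxhat)
    sxx <- colSums(dxhat * cache$xhat)
    dX <- (dxhat - rep(sx / n, each = n) -
             cache$xhat * rep(sxx / n, each = n)) *
      rep(cache$ivar, each = n)
  } else {
    dX <- dxhat * rep(cache$ivar, each = n)
  }
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

relu_bwd <- function(dY, mask) dY * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM forward over (B, T, D) input.  Gate column layout: [i | f | g | o].
lstm_fwd <- function(X, W, U, b, h0 = NULL, c0 = NULL) {
  d <- dim(X); B <- d[1]; Tn <- d[2]
  H <- ncol(U) %/% 4L
  if (is.null(h0)) h0 <- matrix(0, B, H)
  if (is.null(c0)) c0 <- matrix(0, B, H)
  Hs <- array(0, c(B, Tn, H))
  Gi <- Gf <- Gg <- Go <- Cs <- TanhC <- array(0, c(B, Tn, H))
  Hprev <- array(0, c(B, Tn, H))
  Cprev <- array(0, c(B, Tn, H))
  h <- h0; cc <- c0
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B)
    z <- xt %*% W + h %*% U + rep(b, each = B)
    i_g <- sigmoid(z[, ii, drop = FALSE])
    f_g <- sigmoid(z[, fi, drop = FALSE])
    g_g <- tanh(z[, gi, drop = FALSE])
    o_g <- sigmoid(z[, oi, drop = FALSE])
    Hprev[, t, ] <- h
    Cprev[, t, ] <- cc
    cc <- f_g * cc + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    Gi[, t, ] <- i_g; Gf[, t, ] <- f_g; Gg[, t, ] <- g_g; Go[, t, ] <- o_g
    Cs[, t, ] <- cc; TanhC[, t, ] <- tc
    Hs[, t, ] <- h
  }
  list(H = Hs, h_n = h, c_n = cc,
       cache = list(X = X, W = W, U = U, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go,
                    Cs = Cs, TanhC = TanhC, Hprev = Hprev, Cprev = Cprev,
                    dims = d, Hsize = H))
}

lstm_bwd <- function(dH, cache, dh_n = NULL, dc_n = NULL) {
  d <- cache$dims; B <- d[1]; Tn <- d[2]; D <- d[3]
  H <- cache$Hsize
  W <- cache$W; U <- cache$U
  dW <- matrix(0, D, 4L * H); dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, d)
  dh <- if (is.null(dh_n)) matrix(0, B, H) else dh_n
  dc <- if (is.null(dc_n)) matrix(0, B, H) else dc_n
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in rev(seq_len(Tn))) {
    dht <- matrix(dH[, t, ], B) + dh
    o_g <- matrix(cache$Go[, t, ], B); tc <- matrix(cache$TanhC[, t, ], B)
    i_g <- matrix(cache$Gi[, t, ], B); f_g <- matrix(cache$Gf[, t, ], B)
    g_g <- matrix(cache$Gg[, t, ], B)
    c_prev <- matrix(cache$Cprev[, t, ], B)
    dct <- dc + dht * o_g * (1 - tc^2)
    dz <- matrix(0, B, 4L * H)
    dz[, ii] <- dct * g_g * i_g * (1 - i_g)
    dz[, fi] <- dct * c_prev * f_g * (1 - f_g)
    dz[, gi] <- dct * i_g * (1 - g_g^2)
    dz[, oi] <- dht * tc * o_g * (1 - o_g)
    xt <- matrix(cache$X[, t, ], B)
    h_prev <- matrix(cache$Hprev[, t, ], B)
    dW <- dW + crossprod(xt, dz)
    dU <- dU + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(W)
    dh <- dz %*% t(U)
    dc <- dct * f_g
  }
  list(dX = dX, dW = dW, dU = dU, db = db, dh0 = dh, dc0 = dc)
}

# Adam with L2 weight decay folded into the gradient (the lambda of the
# training recipe).  `state` holds first/second moments and the step count.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      weight_decay = 1e-5, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
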