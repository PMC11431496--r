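#' Detector model configuration
#'
#' The network follows the convolutional-recurrent sequence-labeling design
#' adapted to 4 Hz inputs: an inception block of four parallel convolution
#' blocks (convolution, batch normalization, ReLU) with kernel sizes 5, 33,
#' 65 and 129; two residual blocks whose second component downsamples by a
#' stride of 2 (so two blocks map 4 Hz to 1 Hz), with kernel sizes 1, 2, 7
#' and 2; two LSTM layers; and a fully connected head with a sigmoid that
#' emits one arousal probability per second.
#'
#' Channel widths and the recurrent hidden size are free parameters (the
#' architecture fixes only kernels, block counts and the downsampling
#' schedule); the defaults are sized for CPU training.
#'
#' @param n_input_channels Number of input channels (>= 1).
#' @param inception_kernel_sizes Kernel sizes of the four inception
#'   branches.
#' @param inception_filters_per_branch Filters per inception branch.
#' @param residual_kernel_sizes The four residual-block kernel sizes,
#'   interpreted as: component 1 uses (1, 2); component 2 uses (7, 2) with
#'   stride 2 on its first convolution and a stride-2 kernel-1 projection on
#'   its skip path.
#' @param residual_channels Channels carried through the residual blocks.
#' @param n_residual_blocks Must be 2: two stride-2 stages map 4 Hz to 1 Hz.
#' @param lstm_hidden Hidden units per LSTM layer.
#' @param lstm_layers Number of stacked LSTM layers (2).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_input_channels,
                         inception_kernel_sizes = c(5L, 33L, 65L, 129L),
                         inception_filters_per_branch = 16L,
                         residual_kernel_sizes = c(1L, 2L, 7L, 2L),
                         residual_channels = 64L,
                         n_residual_blocks = 2L,
                         lstm_hidden = 64L,
                         lstm_layers = 2L,
                         seed = 1L) {
  if (n_input_channels < 1) stop("n_input_channels must be >= 1")
  if (n_residual_blocks != 2L) {
    stop("n_residual_blocks must be 2: two stride-2 stages map 4 Hz to 1 Hz")
  }
  if (lstm_layers != 2L) stop("lstm_layers must be 2")
  if (length(inception_kernel_sizes) != 4L) {
    stop("inception_kernel_sizes must have 4 entries")
  }
  if (length(residual_kernel_sizes) != 4L) {
    stop("residual_kernel_sizes must have 4 entries")
  }
  structure(list(
    n_input_channels = as.integer(n_input_channels),
    inception_kernel_sizes = as.integer(inception_kernel_sizes),
    inception_filters_per_branch = as.integer(inception_filters_per_branch),
    residual_kernel_sizes = as.integer(residual_kernel_sizes),
    residual_channels = as.integer(residual_channels),
    n_residual_blocks = 2L,
    lstm_hidden = as.integer(lstm_hidden),
    lstm_layers = 2L,
    seed = as.integer(seed)
  ), class = "model_config")
}

conv_init <- function(k, cin, cout) {
  matrix(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), k * cin, cout)
}

#' Build the detector network
#'
#' Allocates and seeds all parameters of the architecture described in
#' [model_config()].  Two builds with the same config (and seed) produce
#' identical parameters.
#'
#' @param config A `model_config`.
#' @return An `arousal_model` holding parameters, batch-normalization
#'   running statistics and the config.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  FPB <- config$inception_filters_per_branch
  C0 <- 4L * FPB
  R <- config$residual_channels
  H <- config$lstm_hidden
  Cin <- config$n_input_channels
  rk <- config$residual_kernel_sizes  # (1, 2, 7, 2)
  params <- list()
  bn <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, "_gamma")]] <<- rep(1, c)
    params[[paste0(name, "_beta")]] <<- rep(0, c)
    bn[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  with_seed(config$seed, {
    for (b in 1:4) {
      k <- config$inception_kernel_sizes[b]
      nm <- paste0("inc", b)
      params[[paste0(nm, "_W")]] <- conv_init(k, Cin, FPB)
      params[[paste0(nm, "_b")]] <- rep(0, FPB)
      add_bn(nm, FPB)
    }
    for (r in 1:2) {
      cin_r <- if (r == 1L) C0 else R
      pre <- paste0("res", r)
      # component 1: conv(k=rk[1]) -> conv(k=rk[2]), identity/projection skip
      params[[paste0(pre, "_c11_W")]] <- conv_init(rk[1], cin_r, R)
      params[[paste0(pre, "_c11_b")]] <- rep(0, R)
      add_bn(paste0(pre, "_c11"), R)
      params[[paste0(pre, "_c12_W")]] <- conv_init(rk[2], R, R)
      params[[paste0(pre, "_c12_b")]] <- rep(0, R)
      add_bn(paste0(pre, "_c12"), R)
      if (cin_r != R) {
        params[[paste0(pre, "_proj1_W")]] <- conv_init(1L, cin_r, R)
        params[[paste0(pre, "_proj1_b")]] <- rep(0, R)
      }
      # component 2: conv(k=rk[3], stride 2) -> conv(k=rk[4]);
      # stride-2 kernel-1 projection skip
      params[[paste0(pre, "_c21_W")]] <- conv_init(rk[3], R, R)
      params[[paste0(pre, "_c21_b")]] <- rep(0, R)
      add_bn(paste0(pre, "_c21"), R)
      params[[paste0(pre, "_c22_W")]] <- conv_init(rk[4], R, R)
      params[[paste0(pre, "_c22_b")]] <- rep(0, R)
      add_bn(paste0(pre, "_c22"), R)
      params[[paste0(pre, "_proj2_W")]] <- conv_init(1L, R, R)
      params[[paste0(pre, "_proj2_b")]] <- rep(0, R)
    }
    for (l in 1:2) {
      D <- if (l == 1L) R else H
      s <- 1 / sqrt(H)
      nm <- paste0("lstm", l)
      params[[paste0(nm, "_W")]] <- matrix(runif(D * 4L * H, -s, s), D, 4L * H)
      params[[paste0(nm, "_U")]] <- matrix(runif(H * 4L * H, -s, s), H, 4L * H)
      bvec <- rep(0, 4L * H)
      bvec[(H + 1L):(2L * H)] <- 1   # forget-gate bias
      params[[paste0(nm, "_b")]] <- bvec
    }
    params[["head_W"]] <- matrix(rnorm(H, sd = sqrt(1 / H)), H, 1L)
    params[["head_b"]] <- 0
  })
  structure(list(config = config, params = params, bn = bn),
            class = "arousal_model")
}

#' @export
print.arousal_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<arousal_model> %d input channel(s), %d parameters (4 Hz -> 1 Hz)\n",
    x$config$n_input_channels, np))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `arousal_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# conv -> BN -> ReLU block.  Returns output, cache, updated bn store.
convblock_fwd <- function(X, params, bn, name, k, stride, training) {
  cv <- conv1d_fwd(X, params[[paste0(name, "_W")]],
                   params[[paste0(name, "_b")]], k, stride)
  bnr <- bn_fwd(cv$Y, params[[paste0(name, "_gamma")]],
                params[[paste0(name, "_beta")]], bn[[name]], training)
  bn[[name]] <- bnr$running
  rl <- relu_fwd(bnr$Y)
  list(Y = rl$Y, bn = bn,
       cache = list(conv = cv$cache, bn = bnr$cache, relu = rl$cache))
}

convblock_bwd <- function(dY, cache, name, grads) {
  dr <- relu_bwd(dY, cache$relu)
  bb <- bn_bwd(dr, cache$bn)
  grads[[paste0(name, "_gamma")]] <- bb$dgamma
  grads[[paste0(name, "_beta")]] <- bb$dbeta
  cb <- conv1d_bwd(bb$dX, cache$conv)
  grads[[paste0(name, "_W")]] <- cb$dW
  grads[[paste0(name, "_b")]] <- cb$db
  list(dX = cb$dX, grads = grads)
}

zero_state <- function(model, batch_size) {
  H <- model$config$lstm_hidden
  list(h1 = matrix(0, batch_size, H), c1 = matrix(0, batch_size, H),
       h2 = matrix(0, batch_size, H), c2 = matrix(0, batch_size, H))
}

# Full forward pass.  X: array (B, 4*T, Cin).  Returns per-second logits
# (B, T), the carried LSTM state, caches for backward (if keep_cache) and
# the updated model (batch-norm running statistics move in training mode).
model_fwd <- function(model, X, training = FALSE, state = NULL,
                      keep_cache = FALSE) {
  p <- model$params
  bn <- model$bn
  cfg <- model$config
  B <- dim(X)[1]
  if (dim(X)[2] %% 4L != 0L) stop("input length must be divisible by 4")
  if (dim(X)[3] != cfg$n_input_channels) {
    stop(sprintf("expected %d input channel(s), got %d",
                 cfg$n_input_channels, dim(X)[3]))
  }
  if (is.null(state)) state <- zero_state(model, B)
  caches <- list()
  rk <- cfg$residual_kernel_sizes

  branches <- vector("list", 4L)
  for (b in 1:4) {
    nm <- paste0("inc", b)
    r <- convblock_fwd(X, p, bn, nm, cfg$inception_kernel_sizes[b], 1L,
                       training)
    bn <- r$bn
    branches[[b]] <- r$Y
    if (keep_cache) caches[[nm]] <- r$cache
  }
  d2 <- dim(branches[[1]])
  cur <- array(0, c(d2[1], d2[2], 4L * cfg$inception_filters_per_branch))
  for (b in 1:4) {
    cur[, , ((b - 1L) * cfg$inception_filters_per_branch + 1L):
              (b * cfg$inception_filters_per_branch)] <- branches[[b]]
  }

  for (r in 1:2) {
    pre <- paste0("res", r)
    # component 1
    a <- convblock_fwd(cur, p, bn, paste0(pre, "_c11"), rk[1], 1L, training)
    bn <- a$bn
    a2 <- convblock_fwd(a$Y, p, bn, paste0(pre, "_c12"), rk[2], 1L, training)
    bn <- a2$bn
    proj1_name <- paste0(pre, "_proj1_W")
    if (!is.null(p[[proj1_name]])) {
      sk <- conv1d_fwd(cur, p[[proj1_name]], p[[paste0(pre, "_proj1_b")]],
                       1L, 1L)
      skip1 <- sk$Y
      if (keep_cache) caches[[paste0(pre, "_proj1")]] <- sk$cache
    } else {
      skip1 <- cur
    }
    out1 <- a2$Y + skip1
    # component 2 (downsampling)
    b1 <- convblock_fwd(out1, p, bn, paste0(pre, "_c21"), rk[3], 2L, training)
    bn <- b1$bn
    b2 <- convblock_fwd(b1$Y, p, bn, paste0(pre, "_c22"), rk[4], 1L, training)
    bn <- b2$bn
    sk2 <- conv1d_fwd(out1, p[[paste0(pre, "_proj2_W")]],
                      p[[paste0(pre, "_proj2_b")]], 1L, 2L)
    if (keep_cache) {
      caches[[paste0(pre, "_c11")]] <- a$cache
      caches[[paste0(pre, "_c12")]] <- a2$cache
      caches[[paste0(pre, "_c21")]] <- b1$cache
      caches[[paste0(pre, "_c22")]] <- b2$cache
      caches[[paste0(pre, "_proj2")]] <- sk2$cache
    }
    cur <- b2$Y + sk2$Y
  }

  l1 <- lstm_fwd(cur, p$lstm1_W, p$lstm1_U, p$lstm1_b, state$h1, state$c1)
  l2 <- lstm_fwd(l1$H, p$lstm2_W, p$lstm2_U, p$lstm2_b, state$h2, state$c2)
  if (keep_cache) {
    caches$lstm1 <- l1$cache
    caches$lstm2 <- l2$cache
  }
  Tn <- dim(cur)[2]
  H2m <- matrix(l2$H, B * Tn, cfg$lstm_hidden)
  logits <- matrix(H2m %*% p$head_W + p$head_b, B, Tn)
  if (keep_cache) caches$head_H <- H2m
  model$bn <- bn
  list(logits = logits,
       state = list(h1 = l1$h_n, c1 = l1$c_n, h2 = l2$h_n, c2 = l2$c_n),
       caches = if (keep_cache) caches else NULL,
       model = model)
}

# Backward pass from d(logits) (B, T) to parameter gradients.
model_bwd <- function(model, caches, dlogits) {
  p <- model$params
  cfg <- model$config
  B <- nrow(dlogits); Tn <- ncol(dlogits)
  H <- cfg$lstm_hidden
  grads <- list()
  dlm <- matrix(as.numeric(dlogits), B * Tn, 1L)
  grads$head_W <- crossprod(caches$head_H, dlm)
  grads$head_b <- sum(dlm)
  dH2 <- array(dlm %*% t(p$head_W), c(B, Tn, H))
  l2b <- lstm_bwd(dH2, caches$lstm2)
  grads$lstm2_W <- l2b$dW; grads$lstm2_U <- l2b$dU; grads$lstm2_b <- l2b$db
  l1b <- lstm_bwd(l2b$dX, caches$lstm1)
  grads$lstm1_W <- l1b$dW; grads$lstm1_U <- l1b$dU; grads$lstm1_b <- l1b$db
  dcur <- l1b$dX

  rk <- cfg$residual_kernel_sizes
  for (r in 2:1) {
    pre <- paste0("res", r)
    # component 2: dcur flows into b2-path and proj2 skip
    pb <- conv1d_bwd(dcur, caches[[paste0(pre, "_proj2")]])
    grads[[paste0(pre, "_proj2_W")]] <- pb$dW
    grads[[paste0(pre, "_proj2_b")]] <- pb$db
    r22 <- convblock_bwd(dcur, caches[[paste0(pre, "_c22")]],
                         paste0(pre, "_c22"), grads)
    grads <- r22$grads
    r21 <- convblock_bwd(r22$dX, caches[[paste0(pre, "_c21")]],
                         paste0(pre, "_c21"), grads)
    grads <- r21$grads
    dout1 <- r21$dX + pb$dX
    # component 1
    r12 <- convblock_bwd(dout1, caches[[paste0(pre, "_c12")]],
                         paste0(pre, "_c12"), grads)
    grads <- r12$grads
    r11 <- convblock_bwd(r12$dX, caches[[paste0(pre, "_c11")]],
                         paste0(pre, "_c11"), grads)
    grads <- r11$grads
    if (!is.null(caches[[paste0(pre, "_proj1")]])) {
      p1 <- conv1d_bwd(dout1, caches[[paste0(pre, "_proj1")]])
      grads[[paste0(pre, "_proj1_W")]] <- p1$dW
      grads[[paste0(pre, "_proj1_b")]] <- p1$db
      dcur <- r11$dX + p1$dX
    } else {
      dcur <- r11$dX + dout1
    }
  }

  FPB <- cfg$inception_filters_per_branch
  dX <- NULL
  for (b in 1:4) {
    nm <- paste0("inc", b)
    dbr <- dcur[, , ((b - 1L) * FPB + 1L):(b * FPB), drop = FALSE]
    rb <- convblock_bwd(dbr, caches[[nm]], nm, grads)
    grads <- rb$grads
    dX <- if (is.null(dX)) rb$dX else dX + rb$dX
  }
  grads$dX <- dX
  grads
}

#' Per-second arousal probabilities for a multichannel 4 Hz input
#'
#' Runs the network in inference mode (batch-normalization running
#' statistics, zero initial recurrent state).  If the input length is not
#' divisible by 4 it is padded by repeating the last sample; the output is
#' truncated to `floor(n_samples / 4)` seconds.
#'
#' @param model An `arousal_model`.
#' @param x Numeric matrix of 4 Hz samples, one column per input channel
#'   (or a vector for a single-channel model).
#' @return Numeric vector of per-second probabilities in (0, 1), of length
#'   `floor(nrow(x) / 4)`.
#' @export
predict_probs <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (ncol(x) != model$config$n_input_channels) {
    stop(sprintf("model expects %d input channel(s), got %d",
                 model$config$n_input_channels, ncol(x)))
  }
  n <- nrow(x)
  n_sec <- n %/% 4L
  if (n_sec < 1L) stop("input must cover at least one second at 4 Hz")
  pad <- (4L - n %% 4L) %% 4L
  if (pad > 0L) x <- rbind(x, x[rep(n, pad), , drop = FALSE])
  X <- array(x, c(1L, nrow(x), ncol(x)))
  out <- model_fwd(model, X, training = FALSE)
  as.numeric(sigmoid(out$logits[1L, seq_len(n_sec)]))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding a versioned list with the config,
#' parameters, batch-normalization statistics and (optionally) the training
#' state, so a run can be resumed or a trained detector reused.
#'
#' @param model An `arousal_model`.
#' @param path File path.
#' @param extra Optional named list stored alongside (e.g. training state).
#' @return `path` (save) or the restored `arousal_model` (load).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(format = "hstarousal-checkpoint-1", config = model$config,
               params = model$params, bn = model$bn, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "hstarousal-checkpoint-1")) {
    stop("not a recognized checkpoint file")
  }
  structure(list(config = ck$config, params = ck$params, bn = ck$bn),
            class = "arousal_model")
}
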