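# Minimal deterministic convolutional-network engine.
#
# Layers are environments holding parameters, gradient accumulators and
# per-batch caches; batches are numeric arrays in [H x W x C x N] layout.
# Convolutions are evaluated by im2col + BLAS matrix multiply; gradients
# are hand-derived. Everything is deterministic under the R RNG.

nn_conv <- function(in_c, out_c, k = 3, stride = 1, pad = 1, bias = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$in_c <- in_c; e$out_c <- out_c
  e$k <- k; e$stride <- stride; e$pad <- pad
  # He (fan-in) initialization
  e$W <- matrix(stats::rnorm(k * k * in_c * out_c, 0,
                             sqrt(2 / (k * k * in_c))),
                k * k * in_c, out_c)
  e$b <- if (bias) numeric(out_c) else NULL
  e$dW <- 0 * e$W; e$db <- if (bias) numeric(out_c) else NULL
  e
}

nn_bn <- function(c_, eps = 1e-5, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$c <- c_; e$eps <- eps; e$momentum <- momentum
  e$gamma <- rep(1, c_); e$beta <- numeric(c_)
  e$run_mean <- numeric(c_); e$run_var <- rep(1, c_)
  e$dgamma <- numeric(c_); e$dbeta <- numeric(c_)
  e
}

nn_dense <- function(in_f, out_f) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$W <- matrix(stats::rnorm(in_f * out_f, 0, sqrt(1 / in_f)), in_f, out_f)
  e$b <- numeric(out_f)
  e$dW <- 0 * e$W; e$db <- numeric(out_f)
  e
}

conv_out_len <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1L

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  cpp_pad_hw(x, d[1], d[2], d[3], d[4], p)
}

conv_forward <- function(L, x, train = FALSE) {
  d <- dim(x)
  stopifnot(d[3] == L$in_c)
  oh <- conv_out_len(d[1], L$k, L$stride, L$pad)
  ow <- conv_out_len(d[2], L$k, L$stride, L$pad)
  xp <- pad_hw(x, L$pad)
  dp <- dim(xp)
  cols <- cpp_im2col(xp, dp[1], dp[2], dp[3], dp[4], L$k, L$stride, oh, ow)
  out_mat <- cols %*% L$W
  if (!is.null(L$b)) out_mat <- sweep(out_mat, 2, L$b, "+")
  out <- cpp_mat2feat(out_mat, oh, ow, L$out_c, d[4])
  if (train) { L$cache_cols <- cols; L$cache_dims <- d }
  out
}

conv_backward <- function(L, dout) {
  d <- dim(dout)                       # (oh, ow, out_c, N)
  dmat <- cpp_feat2mat(dout, d[1], d[2], d[3], d[4])
  L$dW <- L$dW + crossprod(L$cache_cols, dmat)
  if (!is.null(L$b)) L$db <- L$db + colSums(dmat)
  dcols <- tcrossprod(dmat, L$W)
  din <- L$cache_dims
  dxp <- cpp_col2im(dcols, din[1] + 2 * L$pad, din[2] + 2 * L$pad,
                    din[3], din[4], L$k, L$stride, d[1], d[2])
  L$cache_cols <- NULL
  if (L$pad > 0)
    cpp_crop_hw(dxp, din[1] + 2 * L$pad, din[2] + 2 * L$pad,
                din[3], din[4], L$pad)
  else dxp
}

bn_forward <- function(L, x, train = FALSE) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xr <- x; dim(xr) <- c(HW, C, N)
  if (train) {
    mu <- numeric(C); v <- numeric(C)
    for (c_ in seq_len(C)) {
      xc <- xr[, c_, ]
      mu[c_] <- mean(xc)
      v[c_] <- mean((xc - mu[c_])^2)
    }
    L$run_mean <- (1 - L$momentum) * L$run_mean + L$momentum * mu
    L$run_var <- (1 - L$momentum) * L$run_var + L$momentum * v
  } else {
    mu <- L$run_mean; v <- L$run_var
  }
  sd_ <- sqrt(v + L$eps)
  mu_f <- array(rep(mu, each = HW), c(HW, C, N))
  sd_f <- array(rep(sd_, each = HW), c(HW, C, N))
  xhat <- (xr - mu_f) / sd_f
  g_f <- array(rep(L$gamma, each = HW), c(HW, C, N))
  b_f <- array(rep(L$beta, each = HW), c(HW, C, N))
  y <- g_f * xhat + b_f
  dim(y) <- d
  if (train) { L$cache_xhat <- xhat; L$cache_sd <- sd_; L$cache_dims <- d }
  y
}

bn_backward <- function(L, dout) {
  d <- L$cache_dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dy <- dout; dim(dy) <- c(HW, C, N)
  xhat <- L$cache_xhat
  m <- HW * N
  dx <- array(0, c(HW, C, N))
  for (c_ in seq_len(C)) {
    dyc <- dy[, c_, ]; xc <- xhat[, c_, ]
    L$dgamma[c_] <- L$dgamma[c_] + sum(dyc * xc)
    L$dbeta[c_] <- L$dbeta[c_] + sum(dyc)
    dxh <- dyc * L$gamma[c_]
    dx[, c_, ] <- (dxh - mean(dxh) - xc * mean(dxh * xc)) / L$cache_sd[c_]
  }
  dim(dx) <- d
  L$cache_xhat <- NULL
  dx
}

dense_forward <- function(L, f, train = FALSE) {
  # f: [features x N] -> logits [N x out]
  out <- crossprod(f, L$W)
  out <- sweep(out, 2, L$b, "+")
  if (train) L$cache_in <- f
  out
}

dense_backward <- function(L, dout) {
  L$dW <- L$dW + L$cache_in %*% dout
  L$db <- L$db + colSums(dout)
  g <- L$W %*% t(dout)
  L$cache_in <- NULL
  g
}

gap_forward <- function(x) {
  d <- dim(x)
  f <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
  attr(f, "in_dims") <- d
  f
}

gap_backward <- function(df, in_dims) {
  HW <- in_dims[1] * in_dims[2]
  array(rep(as.numeric(df), each = HW) / HW, in_dims)
}

maxpool_forward <- function(x, k = 3, stride = 2, pad = 1, cache = NULL) {
  d <- dim(x)
  oh <- conv_out_len(d[1], k, stride, pad)
  ow <- conv_out_len(d[2], k, stride, pad)
  xp <- pad_hw(x, pad)   # zero padding; inputs are post-ReLU so zeros are neutral
  best <- array(-Inf, c(oh, ow, d[3], d[4]))
  arg <- array(1L, c(oh, ow, d[3], d[4]))
  m <- 0L
  for (j in seq_len(k)) for (i in seq_len(k)) {
    m <- m + 1L
    ri <- seq.int(i, by = stride, length.out = oh)
    cj <- seq.int(j, by = stride, length.out = ow)
    cand <- xp[ri, cj, , , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- m
  }
  list(out = best, arg = arg, in_dims = d, k = k, stride = stride, pad = pad)
}

maxpool_backward <- function(mp, dout) {
  d <- mp$in_dims
  dxp <- array(0, c(d[1] + 2 * mp$pad, d[2] + 2 * mp$pad, d[3], d[4]))
  m <- 0L
  oh <- dim(dout)[1]; ow <- dim(dout)[2]
  for (j in seq_len(mp$k)) for (i in seq_len(mp$k)) {
    m <- m + 1L
    ri <- seq.int(i, by = mp$stride, length.out = oh)
    cj <- seq.int(j, by = mp$stride, length.out = ow)
    sel <- mp$arg == m
    contrib <- array(0, dim(dout)); contrib[sel] <- dout[sel]
    dxp[ri, cj, , ] <- dxp[ri, cj, , ] + contrib
  }
  if (mp$pad > 0)
    dxp[mp$pad + seq_len(d[1]), mp$pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_ce <- function(logits, y) {
  # logits: [N x K], y: integer class in 1..K
  N <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  idx <- cbind(seq_len(N), y)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N, probs = probs)
}

# --- parameter bookkeeping -------------------------------------------------

layer_params <- function(L) {
  switch(L$type,
         conv = if (is.null(L$b)) c("W") else c("W", "b"),
         bn = c("gamma", "beta"),
         dense = c("W", "b"),
         wnet = c("W1", "b1", "W2", "b2"))
}

zero_grads <- function(layers) {
  for (L in layers) for (p in layer_params(L))
    assign(paste0("d", p), get(p, envir = L) * 0, envir = L)
  invisible(NULL)
}

sgd_step <- function(layers, lr, momentum = 0.9, weight_decay = 0) {
  for (L in layers) for (p in layer_params(L)) {
    w <- get(p, envir = L)
    g <- get(paste0("d", p), envir = L)
    if (weight_decay > 0 && p %in% c("W")) g <- g + weight_decay * w
    vname <- paste0("v", p)
    v <- if (exists(vname, envir = L, inherits = FALSE))
      get(vname, envir = L) else 0 * w
    v <- momentum * v + g
    assign(vname, v, envir = L)
    assign(p, w - lr * v, envir = L)
  }
  invisible(NULL)
}

# Deep-copy the parameters of a set of layers (environments are reference
# objects; used for freezing checks and beta=0 equivalence tests).
snapshot_params <- function(layers) {
  lapply(layers, function(L)
    stats::setNames(lapply(layer_params(L), get, envir = L), layer_params(L)))
}

params_hash <- function(layers) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(snapshot_params(layers), f)
  unname(tools::md5sum(f))
}
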