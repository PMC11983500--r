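# Adaptive feature-matching network: per-kernel transfer weights learned by
# small fully connected networks, and a weighted squared distance between
# L2-normalized source/target feature maps at candidate layer pairs.

# extend the generic parameter bookkeeping to weight nets
wnet_params <- c("W1", "b1", "W2", "b2")

#' Weight network for adaptive source-feature selection
#'
#' A small fully connected network `f_phi` for one (source stage, target
#' stage) pair: it receives the spatially pooled source feature map
#' (length = source stage channels) and emits one nonnegative transfer
#' weight per source kernel, normalized to per-sample mean 1.
#'
#' @param c_source number of source-stage channels.
#' @param hidden hidden layer width.
#' @param seed deterministic initialization seed.
#' @return an object of class `weight_net`.
#' @export
weight_net <- function(c_source, hidden = 16, seed = 1L) {
  e <- new.env(parent = emptyenv())
  class(e) <- "weight_net"
  e$type <- "wnet"; e$c_source <- c_source
  with_seed(seed, {
    e$W1 <- matrix(stats::rnorm(c_source * hidden, 0, sqrt(1 / c_source)),
                   c_source, hidden)
    e$b1 <- numeric(hidden)
    e$W2 <- matrix(stats::rnorm(hidden * c_source, 0, sqrt(1 / hidden)),
                   hidden, c_source)
    e$b2 <- numeric(c_source)
  })
  for (p in wnet_params) assign(paste0("d", p), get(p, envir = e) * 0, envir = e)
  e
}

wnet_forward <- function(wn, pooled, train = FALSE) {
  # pooled: [C_s x N]; returns weights [C_s x N], nonnegative, column mean 1
  z1 <- crossprod(wn$W1, pooled) + wn$b1
  h1 <- z1; h1[h1 < 0] <- 0
  a <- crossprod(wn$W2, h1) + wn$b2
  sp <- matrix(softplus(a), nrow(a), ncol(a))
  s <- colSums(sp)
  C <- nrow(sp)
  w <- sweep(sp, 2, s / C, "/")
  if (train) {
    wn$cache <- list(pooled = pooled, z1 = z1, h1 = h1, a = a, sp = sp, s = s)
  }
  w
}

wnet_backward <- function(wn, dw) {
  ca <- wn$cache
  C <- nrow(ca$sp)
  # w = sp * C / S  =>  dsp = C/S * dw - C/S^2 * colSums(dw * sp)
  inner <- colSums(dw * ca$sp)
  dsp <- sweep(dw, 2, C / ca$s, "*") -
    sweep(matrix(1, C, 1) %*% t(inner), 2, C / ca$s^2, "*")
  da <- dsp * sigmoid(ca$a)
  wn$dW2 <- wn$dW2 + ca$h1 %*% t(da)
  wn$db2 <- wn$db2 + rowSums(da)
  dh1 <- wn$W2 %*% da
  dh1[ca$z1 < 0] <- 0
  wn$dW1 <- wn$dW1 + ca$pooled %*% t(dh1)
  wn$db1 <- wn$db1 + rowSums(dh1)
  wn$cache <- NULL
  invisible(NULL)
}

#' Per-kernel transfer weights from a weight network
#'
#' @param wn a [weight_net()].
#' @param source_map source feature map array `[H x W x C_s x N]` (or an
#'   already pooled `[C_s x N]` matrix).
#' @return weight matrix `[N x C_s]`: nonnegative, each row has mean 1.
#' @export
pair_weights <- function(wn, source_map) {
  pooled <- if (is.matrix(source_map)) source_map
            else spatial_channel_means(source_map)
  if (nrow(pooled) != wn$c_source)
    stop_cfg("pair_weights: source map has %d channels, weight net expects %d",
             nrow(pooled), wn$c_source)
  t(wnet_forward(wn, pooled, train = FALSE))
}

#' Candidate source-to-target layer pairing
#'
#' Holds the learnable channel aligner of one (source stage k, target
#' stage d) pair: a 1x1 convolution mapping the target map to the source
#' channel count; the source map is bilinearly resized to the target map's
#' spatial size before comparison.
#'
#' @param c_source,c_target channel counts of the paired stages.
#' @param source_tap,target_tap stage indices (bookkeeping).
#' @param seed deterministic initialization seed.
#' @param init `"random"` or `"identity"` (identity requires equal channel
#'   counts; useful for analytic checks).
#' @return an object of class `match_pair`.
#' @export
match_pair <- function(c_source, c_target, source_tap = 1L, target_tap = 1L,
                       seed = 1L, init = c("random", "identity")) {
  init <- match.arg(init)
  e <- new.env(parent = emptyenv())
  class(e) <- "match_pair"
  e$source_tap <- source_tap; e$target_tap <- target_tap
  e$c_source <- c_source; e$c_target <- c_target
  with_seed(seed, {
    e$P <- nn_conv(c_target, c_source, k = 1, stride = 1, pad = 0)
  })
  if (init == "identity") {
    if (c_source != c_target)
      stop_cfg("match_pair: identity init needs equal channel counts")
    e$P$W <- diag(c_source)
    e$P$b <- numeric(c_source)
  }
  e
}

resize_maps <- function(x, oh, ow) {
  d <- dim(x)
  if (d[1] == oh && d[2] == ow) return(x)
  out <- array(0, c(oh, ow, d[3], d[4]))
  for (n in seq_len(d[4])) for (c_ in seq_len(d[3]))
    out[, , c_, n] <- bilinear_resize(matrix(x[, , c_, n], d[1], d[2]),
                                      oh, ow)
  out
}

# L2-normalize a feature-map array, spatially resized to (ht, wt), into a
# [HW x (C*N)] matrix of unit (or zero) columns. The source side of the
# matching loss is fixed during transfer training, so this is precomputed.
prep_source_norm <- function(source_map, ht, wt) {
  sm <- resize_maps(source_map, ht, wt)
  d <- dim(sm)
  smat <- matrix(sm, ht * wt)       # columns ordered (c, n)
  sn <- sqrt(colSums(smat^2))
  nz <- sn > 0
  smat[, nz] <- sweep(smat[, nz, drop = FALSE], 2, sn[nz], "/")
  smat[, !nz] <- 0
  list(nu = smat, C = d[3], N = d[4])
}

# Core of the weighted matching loss. `nu` holds the normalized source
# columns for the current batch. Returns the scalar loss and (when
# grad = TRUE) the gradient wrt the target map (through the 1x1 aligner,
# whose parameter gradients accumulate in pair$P) and wrt the weights.
matching_core <- function(nu, target_map, pair, w_cn,
                          grad = FALSE, scale = 1) {
  tp <- conv_forward(pair$P, target_map, train = grad)
  C <- dim(tp)[3]; N <- dim(tp)[4]
  if (ncol(nu) != C * N)
    stop_cfg("matching_loss: aligned target has %d channel-maps, source %d",
             C * N, ncol(nu))
  if (!all(dim(w_cn) == c(C, N)))
    stop_cfg("matching_loss: weights shape mismatch")
  HW <- dim(tp)[1] * dim(tp)[2]
  if (nrow(nu) != HW)
    stop_cfg("matching_loss: spatial size mismatch after projection")
  tmat <- matrix(tp, HW)
  tn <- sqrt(colSums(tmat^2))
  tnz <- tn > 0
  nv <- tmat
  nv[, tnz] <- sweep(tmat[, tnz, drop = FALSE], 2, tn[tnz], "/")
  nv[, !tnz] <- 0
  diff <- nu - nv
  d2 <- colSums(diff^2)             # per (c, n)
  wv <- as.numeric(w_cn)
  loss <- sum(wv * d2) / (C * N)
  if (!grad) return(list(loss = loss))
  # d loss / d nv = -2 w diff / (C N); back through v/|v| then the aligner
  dnv <- sweep(diff, 2, -2 * wv / (C * N) * scale, "*")
  proj <- colSums(dnv * nv)
  dv <- dnv - sweep(nv, 2, proj, "*")
  dv[, tnz] <- sweep(dv[, tnz, drop = FALSE], 2, tn[tnz], "/")
  dv[, !tnz] <- 0
  dtp <- array(dv, dim(tp))
  d_target <- conv_backward(pair$P, dtp)
  dLdw <- matrix(d2 / (C * N) * scale, C, N)
  list(loss = loss, d_target = d_target, dLdw = dLdw)
}

#' Weighted feature-matching loss
#'
#' Measures the weighted squared distance between L2-normalized source and
#' target feature maps of one candidate pair:
#' `mean_n sum_c w[c] * || u_c - v_c ||^2 / C`, where `u_c` is the
#' spatially resized source map of kernel `c` (flattened, L2-normalized),
#' `v_c` the target map after the pair's 1x1 channel aligner (likewise
#' normalized) and `C` the source channel count. The loss is zero iff the
#' weighted normalized maps coincide; an all-zero map normalizes to zero.
#'
#' @param source_map source feature map `[H_s x W_s x C_s x N]`.
#' @param target_map target feature map `[H_t x W_t x C_t x N]`.
#' @param pair a [match_pair()] aligning `C_t` to `C_s`.
#' @param weights `[N x C_s]` matrix (as from [pair_weights()]) or a
#'   length-`C_s` vector recycled over the batch.
#' @return scalar loss, `>= 0`.
#' @export
matching_loss <- function(source_map, target_map, pair, weights) {
  N <- dim(source_map)[4]
  C <- dim(source_map)[3]
  w_cn <- if (is.matrix(weights) && all(dim(weights) == c(N, C))) t(weights)
          else if (is.matrix(weights) && all(dim(weights) == c(C, N))) weights
          else if (length(weights) == C) matrix(weights, C, N)
          else stop_cfg("matching_loss: weights must be [N x C_s] or length C_s")
  dt <- dim(target_map)
  pre <- prep_source_norm(source_map, dt[1], dt[2])
  matching_core(pre$nu, target_map, pair, w_cn)$loss
}

#' Transfer training hyperparameters
#'
#' @param beta coefficient of the matching loss (>= 0; `beta = 0` reduces
#'   transfer training to plain target training).
#' @param candidate_pairs list of `c(source_stage, target_stage)` index
#'   pairs; default all pairs with source stage >= target stage
#'   (coarse-to-fine transfer).
#' @param epochs,lr,momentum,batch_size,seed SGD settings as in
#'   [train_hyper()].
#' @param wn_hidden hidden width of the weight networks.
#' @return a list of class `transfer_hyper`.
#' @export
transfer_hyper <- function(beta = 0.5, candidate_pairs = NULL, epochs = 15,
                           lr = 0.02, momentum = 0.9, batch_size = 16,
                           seed = 1L, wn_hidden = 16) {
  if (beta < 0) stop_cfg("configuration error: 'beta' must be >= 0")
  if (is.null(candidate_pairs)) {
    candidate_pairs <- list()
    for (k in 1:4) for (d in 1:4) if (k >= d)
      candidate_pairs[[length(candidate_pairs) + 1L]] <- c(k, d)
  }
  if (length(candidate_pairs) == 0L)
    stop_cfg("configuration error: 'candidate_pairs' must be nonempty")
  structure(list(beta = beta, candidate_pairs = candidate_pairs,
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 wn_hidden = as.integer(wn_hidden)),
            class = "transfer_hyper")
}

#' Custom source of feature maps for transfer experiments
#'
#' Wraps a function producing stage feature maps so it can stand in for a
#' frozen source encoder in [transfer_train()]. Used for controlled
#' experiments where the content of each source channel is known by
#' construction (e.g. half the channels carry class signal and half are
#' noise, to probe whether the learned transfer weights separate them).
#'
#' @param widths channel count of each of the four stages.
#' @param forward `function(x)` returning a list of four feature-map
#'   arrays (entries may be `NULL` for unused stages); must be
#'   deterministic in `x`.
#' @return an object usable as the `source` argument of
#'   [transfer_train()].
#' @export
feature_source <- function(widths, forward) {
  structure(list(vt = list(widths = widths), forward = forward,
                 frozen = TRUE),
            class = "feature_source")
}

source_forward <- function(source, x) {
  if (inherits(source, "encoder"))
    encoder_forward(source, x, train = FALSE)
  else if (inherits(source, "feature_source"))
    list(taps = source$forward(x))
  else stop_cfg("transfer_train: unsupported source object")
}

#' Build the weight nets and channel aligners for a candidate pair set
#'
#' @param source_enc,target_enc the paired encoders.
#' @param hyper a [transfer_hyper()].
#' @return list with one `wn` ([weight_net()]) and one `pair`
#'   ([match_pair()]) per candidate pair.
#' @export
make_transfer_nets <- function(source_enc, target_enc, hyper) {
  sw <- source_enc$vt$widths; tw <- target_enc$vt$widths
  lapply(seq_along(hyper$candidate_pairs), function(i) {
    kd <- hyper$candidate_pairs[[i]]
    list(wn = weight_net(sw[kd[1]], hyper$wn_hidden,
                         seed = hyper$seed + 101L * i),
         pair = match_pair(sw[kd[1]], tw[kd[2]], kd[1], kd[2],
                           seed = hyper$seed + 211L * i))
  })
}

#' Transfer-train the target encoder with adaptive feature matching
#'
#' Minimizes `CE(target logits, labels) + beta * sum_pairs matching_loss`
#' by joint minibatch SGD over the target encoder, the per-pair channel
#' aligners and the weight networks. The frozen source encoder is run in
#' evaluation mode only and its weights are never updated.
#'
#' @param source frozen source encoder (trained by [train_source()]).
#' @param target target encoder from [build_encoder()].
#' @param nets transfer nets from [make_transfer_nets()]; built
#'   automatically when `NULL`.
#' @param x target-domain image batch `[H x W x C x N]`.
#' @param labels per-trial 0/1 labels.
#' @param hyper a [transfer_hyper()].
#' @return list with the trained `target`, the trained `nets`, and
#'   `history` (per-epoch cross-entropy and matching loss).
#' @export
transfer_train <- function(source, target, nets = NULL, x, labels,
                           hyper = transfer_hyper()) {
  stopifnot(inherits(target, "encoder"))
  if (!isTRUE(source$frozen))
    stop_cfg("transfer_train: source encoder must be frozen (train it first)")
  if (hyper$beta < 0) stop_cfg("transfer_train: beta must be >= 0")
  y <- as.integer(labels) + 1L       # 0/1 -> 1/2
  if (length(unique(y)) < 2L)
    stop_cfg("transfer_train: need both classes in the training data")
  if (is.null(nets)) nets <- make_transfer_nets(source, target, hyper)
  use_match <- hyper$beta > 0
  tlayers <- encoder_layers(target)
  aux <- list()
  if (use_match)
    for (nt in nets) aux <- c(aux, list(nt$pair$P, nt$wn))
  n <- dim(x)[4]
  # the frozen source's feature maps are constant: evaluate, resize and
  # normalize them once, then index per batch
  pre <- NULL
  if (use_match) {
    sf <- source_forward(source, x)
    tdims <- stage_output_dims(target$vt, dim(x)[1], dim(x)[2])
    pre <- lapply(nets, function(nt) {
      pn <- prep_source_norm(sf$taps[[nt$pair$source_tap]],
                             tdims[nt$pair$target_tap, 1],
                             tdims[nt$pair$target_tap, 2])
      pn$pooled <- spatial_channel_means(sf$taps[[nt$pair$source_tap]])
      pn
    })
  }
  hist_ce <- numeric(hyper$epochs); hist_match <- numeric(hyper$epochs)
  acc_ce <- 0; acc_match <- 0; acc_n <- 0
  run_sgd_epochs(n, hyper, function(idx, lr, ep) {
    xb <- x[, , , idx, drop = FALSE]
    tf <- encoder_forward(target, xb, train = TRUE)
    ce <- softmax_ce(tf$logits, y[idx])
    zero_grads(tlayers)
    if (use_match) zero_grads(aux)
    dtaps <- vector("list", 4)
    mloss <- 0
    if (use_match) {
      for (pi in seq_along(nets)) {
        nt <- nets[[pi]]; pn <- pre[[pi]]
        d_ <- nt$pair$target_tap
        cols <- as.vector(outer(seq_len(pn$C), (idx - 1L) * pn$C, "+"))
        w_cn <- wnet_forward(nt$wn, pn$pooled[, idx, drop = FALSE],
                             train = TRUE)
        mc <- matching_core(pn$nu[, cols, drop = FALSE], tf$taps[[d_]],
                            nt$pair, w_cn, grad = TRUE, scale = hyper$beta)
        mloss <- mloss + mc$loss
        dtaps[[d_]] <- if (is.null(dtaps[[d_]])) mc$d_target
                       else dtaps[[d_]] + mc$d_target
        wnet_backward(nt$wn, mc$dLdw)
      }
    }
    encoder_backward(target, ce$dlogits, if (use_match) dtaps else NULL)
    sgd_step(tlayers, lr, hyper$momentum)
    if (use_match) sgd_step(aux, lr, hyper$momentum)
    acc_ce <<- acc_ce + ce$loss * length(idx)
    acc_match <<- acc_match + mloss * length(idx)
    acc_n <<- acc_n + length(idx)
  }, epoch_end = function(ep) {
    hist_ce[ep] <<- acc_ce / max(1, acc_n)
    hist_match[ep] <<- acc_match / max(1, acc_n)
    acc_ce <<- 0; acc_match <<- 0; acc_n <<- 0
  })
  list(target = target, nets = nets,
       history = data.frame(epoch = seq_len(hyper$epochs),
                            ce_loss = hist_ce, match_loss = hist_match))
}

#' Per-pair mean learned transfer weights
#'
#' Summarizes, for each candidate pair, the mean learned weight per source
#' kernel over a batch — the interpretable output of the adaptive
#' selection mechanism (higher weight = more useful source kernel).
#'
#' @param source frozen source encoder.
#' @param nets trained transfer nets.
#' @param x image batch.
#' @return list of data frames (one per pair) with columns `kernel`,
#'   `mean_weight`.
#' @export
transfer_report <- function(source, nets, x) {
  sf <- source_forward(source, x)
  lapply(nets, function(nt) {
    w <- pair_weights(nt$wn, sf$taps[[nt$pair$source_tap]])
    data.frame(source_stage = nt$pair$source_tap,
               target_stage = nt$pair$target_tap,
               kernel = seq_len(ncol(w)),
               mean_weight = colMeans(w))
  })
}
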