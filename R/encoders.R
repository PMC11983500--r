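#' Encoder architecture specification
#'
#' Describes a residual convolutional encoder. `resnet34` (deep source
#' model) and `resnet18` (light target model) are the standard
#' architectures with stage widths 64/128/256/512 and a 7x7 stride-2 stem
#' plus max-pool; `tiny34`/`tiny18` are scaled-down variants (widths
#' 8/16/32/64, 3x3 stride-2 stem, no max-pool, 2 resp. 1 basic blocks per
#' stage) intended for desk-scale experiments and tests.
#'
#' @param variant one of `"resnet34"`, `"resnet18"`, `"tiny34"`, `"tiny18"`.
#' @param in_channels number of input image planes.
#' @param n_classes number of output classes (>= 2).
#' @param seed integer seed for deterministic weight initialization.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(variant, in_channels, n_classes = 2, seed = 1L) {
  variants <- c("resnet34", "resnet18", "tiny34", "tiny18")
  if (!variant %in% variants)
    stop_cfg("unknown encoder variant '%s' (known: %s)", variant,
             paste(variants, collapse = ", "))
  check_scalar(in_channels, "in_channels", lower = 1, integer = TRUE)
  check_scalar(n_classes, "n_classes", lower = 2, integer = TRUE)
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 tap_points = paste0("stage", 1:4)),
            class = "encoder_spec")
}

variant_table <- function(variant) {
  switch(variant,
    resnet18 = list(widths = c(64L, 128L, 256L, 512L), blocks = rep(2L, 4),
                    stem_width = 64L, stem_k = 7L, stem_stride = 2L,
                    stem_pad = 3L, maxpool = TRUE),
    resnet34 = list(widths = c(64L, 128L, 256L, 512L), blocks = c(3L, 4L, 6L, 3L),
                    stem_width = 64L, stem_k = 7L, stem_stride = 2L,
                    stem_pad = 3L, maxpool = TRUE),
    tiny18 = list(widths = c(8L, 16L, 32L, 64L), blocks = rep(1L, 4),
                  stem_width = 8L, stem_k = 3L, stem_stride = 2L,
                  stem_pad = 1L, maxpool = FALSE),
    tiny34 = list(widths = c(8L, 16L, 32L, 64L), blocks = rep(2L, 4),
                  stem_width = 8L, stem_k = 3L, stem_stride = 2L,
                  stem_pad = 1L, maxpool = FALSE),
    stop_cfg("unknown encoder variant '%s'", variant))
}

#' Number of per-kernel deep features of an encoder
#'
#' Counts the main-path convolution output channels of the architecture —
#' the stem convolution plus the two 3x3 convolutions of every basic
#' block; 1x1 shortcut (downsample) convolutions are excluded. This is the
#' dimensionality of the per-kernel averaged deep-feature vector: 3904 for
#' `resnet18`.
#'
#' @param spec an [encoder_spec()] or a variant name.
#' @return integer kernel count.
#' @export
count_feature_kernels <- function(spec) {
  variant <- if (inherits(spec, "encoder_spec")) spec$variant else spec
  vt <- variant_table(variant)
  as.integer(vt$stem_width + sum(vt$blocks * 2L * vt$widths))
}

make_block <- function(in_c, out_c, stride) {
  b <- new.env(parent = emptyenv())
  b$conv1 <- nn_conv(in_c, out_c, 3, stride, 1)
  b$bn1 <- nn_bn(out_c)
  b$conv2 <- nn_conv(out_c, out_c, 3, 1, 1)
  b$bn2 <- nn_bn(out_c)
  if (stride != 1 || in_c != out_c) {
    b$down_conv <- nn_conv(in_c, out_c, 1, stride, 0, bias = FALSE)
    b$down_bn <- nn_bn(out_c)
  } else {
    b$down_conv <- NULL; b$down_bn <- NULL
  }
  b
}

#' Build a residual convolutional encoder
#'
#' Constructs the encoder described by `spec` with deterministic
#' (seed-controlled) He initialization. The encoder exposes feature taps
#' at the outputs of its four residual stages.
#'
#' @param spec an [encoder_spec()].
#' @return an object of class `encoder` (an environment holding the layer
#'   parameters; copy semantics do not apply).
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  vt <- variant_table(spec$variant)
  enc <- new.env(parent = emptyenv())
  class(enc) <- "encoder"
  enc$spec <- spec; enc$vt <- vt; enc$frozen <- FALSE
  with_seed(spec$seed, {
    enc$stem_conv <- nn_conv(spec$in_channels, vt$stem_width, vt$stem_k,
                             vt$stem_stride, vt$stem_pad)
    enc$stem_bn <- nn_bn(vt$stem_width)
    enc$stages <- vector("list", 4)
    in_c <- vt$stem_width
    for (s in 1:4) {
      blocks <- vector("list", vt$blocks[s])
      for (bi in seq_len(vt$blocks[s])) {
        stride <- if (s > 1 && bi == 1) 2L else 1L
        blocks[[bi]] <- make_block(in_c, vt$widths[s], stride)
        in_c <- vt$widths[s]
      }
      enc$stages[[s]] <- blocks
    }
    enc$head <- nn_dense(vt$widths[4], spec$n_classes)
  })
  enc
}

#' @export
print.encoder <- function(x, ...) {
  cat(sprintf("encoder %s: in_channels=%d, n_classes=%d, %d feature kernels%s\n",
              x$spec$variant, x$spec$in_channels, x$spec$n_classes,
              count_feature_kernels(x$spec),
              if (isTRUE(x$frozen)) " [frozen]" else ""))
  invisible(x)
}

# spatial size of each residual-stage output for an input of H x W
stage_output_dims <- function(vt, H, W) {
  h <- conv_out_len(H, vt$stem_k, vt$stem_stride, vt$stem_pad)
  w <- conv_out_len(W, vt$stem_k, vt$stem_stride, vt$stem_pad)
  if (vt$maxpool) { h <- conv_out_len(h, 3, 2, 1); w <- conv_out_len(w, 3, 2, 1) }
  out <- matrix(0L, 4, 2)
  for (s in 1:4) {
    if (s > 1) { h <- conv_out_len(h, 3, 2, 1); w <- conv_out_len(w, 3, 2, 1) }
    out[s, ] <- c(h, w)
  }
  out
}

encoder_layers <- function(enc) {
  ls_ <- list(enc$stem_conv, enc$stem_bn)
  for (st in enc$stages) for (b in st) {
    ls_ <- c(ls_, list(b$conv1, b$bn1, b$conv2, b$bn2))
    if (!is.null(b$down_conv)) ls_ <- c(ls_, list(b$down_conv, b$down_bn))
  }
  c(ls_, list(enc$head))
}

spatial_channel_means <- function(a) {
  d <- dim(a)   # (H, W, C, N)
  matrix(colMeans(matrix(a, d[1] * d[2])), d[3], d[4])
}

block_forward <- function(b, x, train = FALSE, collect = FALSE) {
  a_raw <- conv_forward(b$conv1, x, train)
  a <- bn_forward(b$bn1, a_raw, train)
  if (train) b$mask1 <- a > 0
  a <- relu(a)
  c_raw <- conv_forward(b$conv2, a, train)
  cc <- bn_forward(b$bn2, c_raw, train)
  sc <- if (!is.null(b$down_conv))
    bn_forward(b$down_bn, conv_forward(b$down_conv, x, train), train)
  else x
  y <- cc + sc
  if (train) b$mask_out <- y > 0
  y <- relu(y)
  km <- if (collect) list(spatial_channel_means(a_raw),
                          spatial_channel_means(c_raw)) else NULL
  list(out = y, km = km)
}

block_backward <- function(b, dy) {
  dy <- dy * b$mask_out
  d2 <- bn_backward(b$bn2, dy)
  d2 <- conv_backward(b$conv2, d2)
  d2 <- d2 * b$mask1
  d1 <- bn_backward(b$bn1, d2)
  dx <- conv_backward(b$conv1, d1)
  dsc <- if (!is.null(b$down_conv))
    conv_backward(b$down_conv, bn_backward(b$down_bn, dy))
  else dy
  b$mask1 <- NULL; b$mask_out <- NULL
  dx + dsc
}

encoder_forward <- function(enc, x, train = FALSE, collect = FALSE) {
  d <- dim(x)
  if (d[3] != enc$spec$in_channels)
    stop_cfg("encoder: expected %d input channels, got %d",
             enc$spec$in_channels, d[3])
  kms <- list()
  a_raw <- conv_forward(enc$stem_conv, x, train)
  if (collect) kms[[length(kms) + 1L]] <- spatial_channel_means(a_raw)
  a <- bn_forward(enc$stem_bn, a_raw, train)
  if (train) enc$stem_mask <- a > 0
  a <- relu(a)
  if (enc$vt$maxpool) {
    mp <- maxpool_forward(a)
    if (train) enc$mp_cache <- mp
    a <- mp$out
  }
  taps <- vector("list", 4)
  for (s in 1:4) {
    for (b in enc$stages[[s]]) {
      bf <- block_forward(b, a, train, collect)
      a <- bf$out
      if (collect) kms <- c(kms, bf$km)
    }
    taps[[s]] <- a
  }
  f <- gap_forward(a)
  if (train) enc$gap_dims <- attr(f, "in_dims")
  logits <- dense_forward(enc$head, f, train)
  out <- list(logits = logits, taps = taps, tap_ids = enc$spec$tap_points)
  if (collect) out$kernel_means <- do.call(rbind, kms)   # [features x N]
  out
}

encoder_backward <- function(enc, dlogits, dtaps = NULL) {
  df <- dense_backward(enc$head, dlogits)
  dx <- gap_backward(df, enc$gap_dims)
  for (s in 4:1) {
    if (!is.null(dtaps) && !is.null(dtaps[[s]])) dx <- dx + dtaps[[s]]
    for (b in rev(enc$stages[[s]])) dx <- block_backward(b, dx)
  }
  if (enc$vt$maxpool) dx <- maxpool_backward(enc$mp_cache, dx)
  dx <- dx * enc$stem_mask
  dx <- bn_backward(enc$stem_bn, dx)
  dx <- conv_backward(enc$stem_conv, dx)
  enc$stem_mask <- NULL; enc$mp_cache <- NULL
  invisible(dx)
}

#' Forward pass with stage feature taps
#'
#' Runs a batch of time-frequency images through the encoder in evaluation
#' mode and returns both the classification logits and the feature maps at
#' the four residual-stage outputs.
#'
#' @param enc an encoder from [build_encoder()].
#' @param batch numeric array `[H x W x C x N]` (e.g. `x` from
#'   [trials_to_images()]), or a single `time_freq_image`.
#' @return list with `logits` (`N x n_classes`) and `feature_maps` (list
#'   `maps` of four `[H x W x C x N]` arrays plus `tap_ids`).
#' @export
forward_with_taps <- function(enc, batch) {
  stopifnot(inherits(enc, "encoder"))
  if (inherits(batch, "time_freq_image")) {
    p <- aperm(batch$pixels, c(2, 3, 1))
    batch <- array(p, c(dim(p), 1L))
  }
  fw <- encoder_forward(enc, batch, train = FALSE)
  list(logits = fw$logits,
       feature_maps = list(maps = fw$taps, tap_ids = fw$tap_ids))
}

# Shared deterministic SGD epoch driver: shuffling is the only RNG use.
run_sgd_epochs <- function(n, hyper, step_fn, epoch_end = NULL) {
  with_seed(hyper$seed, {
    for (ep in seq_len(hyper$epochs)) {
      lr <- hyper$lr * 0.5 * (1 + cos(pi * (ep - 1) / max(1, hyper$epochs)))
      perm <- sample.int(n)
      starts <- seq(1, n, by = hyper$batch_size)
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + hyper$batch_size - 1, n)]
        step_fn(idx, lr, ep)
      }
      if (!is.null(epoch_end)) epoch_end(ep)
    }
  })
  invisible(NULL)
}

#' Default training hyperparameters
#'
#' @param epochs number of epochs.
#' @param lr initial learning rate (cosine-decayed over epochs).
#' @param momentum SGD momentum.
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling (and nothing else).
#' @return a list of hyperparameters.
#' @export
train_hyper <- function(epochs = 30, lr = 0.01, momentum = 0.9,
                        batch_size = 16, seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

#' Train the source encoder on labeled source-domain images
#'
#' Minimizes the cross-entropy on the source trials by minibatch SGD with
#' momentum and a cosine learning-rate schedule, then freezes the encoder
#' (the frozen source provides the feature maps transferred to the target
#' model).
#'
#' @param enc encoder from [build_encoder()].
#' @param x image batch array `[H x W x C x N]`.
#' @param labels per-trial class labels (any type; converted to factor).
#' @param hyper hyperparameters from [train_hyper()].
#' @return the trained encoder (invisibly modified in place, `frozen`
#'   flag set) with a `history` data frame of per-epoch loss/accuracy.
#' @export
train_source <- function(enc, x, labels, hyper = train_hyper()) {
  stopifnot(inherits(enc, "encoder"))
  y <- as.integer(factor(labels))
  if (length(unique(y)) < 2L)
    stop_cfg("train_source: need at least 2 classes, got %d",
             length(unique(y)))
  if (max(y) > enc$spec$n_classes)
    stop_cfg("train_source: %d classes exceed encoder n_classes=%d",
             max(y), enc$spec$n_classes)
  layers <- encoder_layers(enc)
  n <- dim(x)[4]
  hist_loss <- numeric(hyper$epochs)
  ep_loss <- 0; ep_n <- 0
  run_sgd_epochs(n, hyper, function(idx, lr, ep) {
    xb <- x[, , , idx, drop = FALSE]
    fw <- encoder_forward(enc, xb, train = TRUE)
    ce <- softmax_ce(fw$logits, y[idx])
    zero_grads(layers)
    encoder_backward(enc, ce$dlogits)
    sgd_step(layers, lr, hyper$momentum)
    ep_loss <<- ep_loss + ce$loss * length(idx); ep_n <<- ep_n + length(idx)
  }, epoch_end = function(ep) {
    hist_loss[ep] <<- ep_loss / max(1, ep_n)
    ep_loss <<- 0; ep_n <<- 0
  })
  enc$frozen <- TRUE
  enc$history <- data.frame(epoch = seq_len(hyper$epochs), ce_loss = hist_loss)
  enc$class_levels <- levels(factor(labels))
  invisible(enc)
}

#' Classify a batch with a trained encoder
#'
#' @param enc trained encoder.
#' @param x image batch array.
#' @return list with `logits` and integer `pred` (1-based class index).
#' @export
encoder_predict <- function(enc, x) {
  fw <- encoder_forward(enc, x, train = FALSE)
  list(logits = fw$logits, pred = max.col(fw$logits, ties.method = "first"))
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint is a binary array container (RDS) holding the
#' architecture spec and parameter arrays, with a JSON manifest written
#' alongside it.
#'
#' @param enc encoder.
#' @param path checkpoint file path (`.rds`).
#' @return `save_encoder` returns `path` invisibly; `load_encoder` the
#'   rebuilt encoder.
#' @export
save_encoder <- function(enc, path) {
  layers <- encoder_layers(enc)
  obj <- list(spec = enc$spec, params = snapshot_params(layers),
              running = lapply(layers, function(L)
                if (L$type == "bn") list(m = L$run_mean, v = L$run_var)
                else NULL),
              frozen = enc$frozen)
  saveRDS(obj, path)
  manifest <- list(variant = enc$spec$variant,
                   in_channels = enc$spec$in_channels,
                   n_classes = enc$spec$n_classes,
                   seed = enc$spec$seed,
                   n_kernels = count_feature_kernels(enc$spec),
                   frozen = isTRUE(enc$frozen))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- readRDS(path)
  enc <- build_encoder(obj$spec)
  layers <- encoder_layers(enc)
  for (i in seq_along(layers)) {
    for (p in names(obj$params[[i]]))
      assign(p, obj$params[[i]][[p]], envir = layers[[i]])
    if (!is.null(obj$running[[i]])) {
      layers[[i]]$run_mean <- obj$running[[i]]$m
      layers[[i]]$run_var <- obj$running[[i]]$v
    }
  }
  enc$frozen <- obj$frozen
  enc
}
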