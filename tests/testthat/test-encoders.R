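test_that("kernel counts match the architecture tables", {
  expect_identical(count_feature_kernels("resnet18"), 3904L)
  # 64 + 6*64 + 8*128 + 12*256 + 6*512
  expect_identical(count_feature_kernels("resnet34"), 7616L)
  # 8 + 2*8 + 2*16 + 2*32 + 2*64
  expect_identical(count_feature_kernels("tiny18"), 248L)
  # two blocks per stage: 8 + 4*8 + 4*16 + 4*32 + 4*64
  expect_identical(count_feature_kernels("tiny34"), 488L)
  expect_error(encoder_spec("resnet50", 3), "variant")
})

test_that("seeded builds are identical and forwards are deterministic", {
  sp <- encoder_spec("tiny18", in_channels = 2, n_classes = 2, seed = 21)
  x0 <- array(0, c(16, 16, 2, 1))
  l1 <- forward_with_taps(build_encoder(sp), x0)$logits
  l2 <- forward_with_taps(build_encoder(sp), x0)$logits
  expect_identical(l1, l2)
  expect_equal(dim(l1), c(1L, 2L))
})

test_that("resnet18 forward on a 224x224 image taps maps of widths 64/128/256/512", {
  sp <- encoder_spec("resnet18", in_channels = 3, n_classes = 2, seed = 1)
  enc <- build_encoder(sp)
  x <- make_batch(h = 224, n = 1, c_ = 3)
  fw <- forward_with_taps(enc, x)
  chans <- vapply(fw$feature_maps$maps, function(m) dim(m)[3], integer(1))
  expect_equal(chans, c(64L, 128L, 256L, 512L))
  # standard stride arithmetic: 56, 28, 14, 7
  sizes <- vapply(fw$feature_maps$maps, function(m) dim(m)[1], integer(1))
  expect_equal(sizes, c(56L, 28L, 14L, 7L))
})

test_that("tiny18 tap spatial sizes halve stage to stage", {
  sp <- encoder_spec("tiny18", in_channels = 2, n_classes = 2, seed = 2)
  enc <- build_encoder(sp)
  fw <- forward_with_taps(enc, make_batch(h = 64, n = 2))
  sizes <- vapply(fw$feature_maps$maps, function(m) dim(m)[1], integer(1))
  expect_equal(sizes, c(32L, 16L, 8L, 4L))
  chans <- vapply(fw$feature_maps$maps, function(m) dim(m)[3], integer(1))
  expect_equal(chans, c(8L, 16L, 32L, 64L))
})

test_that("evaluation-mode logits are independent of batch composition", {
  sp <- encoder_spec("tiny18", in_channels = 2, n_classes = 2, seed = 3)
  enc <- build_encoder(sp)
  x1 <- make_batch(h = 16, n = 1, seed = 5)
  x2 <- array(0, c(16, 16, 2, 2))
  x2[, , , 1] <- x1[, , , 1]; x2[, , , 2] <- x1[, , , 1]
  la <- forward_with_taps(enc, x1)$logits
  lb <- forward_with_taps(enc, x2)$logits
  expect_equal(lb[1, ], lb[2, ], tolerance = 1e-10)
  expect_equal(la[1, ], lb[1, ], tolerance = 1e-5)
})

test_that("zeroed classification head yields all-zero logits", {
  sp <- encoder_spec("tiny18", in_channels = 2, n_classes = 3, seed = 4)
  enc <- build_encoder(sp)
  enc$head$W[] <- 0; enc$head$b[] <- 0
  l <- forward_with_taps(enc, make_batch())$logits
  expect_true(all(l == 0))
  expect_equal(ncol(l), 3L)
})

test_that("input channel mismatch is reported with expected/got", {
  enc <- build_encoder(encoder_spec("tiny18", in_channels = 4, seed = 5))
  expect_error(forward_with_taps(enc, make_batch(c_ = 2)), "expected 4.*got 2")
})

test_that("backpropagation matches finite-difference gradients", {
  sp <- encoder_spec("tiny18", in_channels = 2, n_classes = 2, seed = 6)
  enc <- build_encoder(sp)
  layers <- chtlm:::encoder_layers(enc)
  x <- make_batch(h = 8, n = 3, seed = 7)
  y <- c(1L, 2L, 1L)
  loss_at <- function() {
    fw <- chtlm:::encoder_forward(enc, x, train = TRUE)
    chtlm:::softmax_ce(fw$logits, y)$loss
  }
  fw <- chtlm:::encoder_forward(enc, x, train = TRUE)
  ce <- chtlm:::softmax_ce(fw$logits, y)
  chtlm:::zero_grads(layers)
  chtlm:::encoder_backward(enc, ce$dlogits)
  eps <- 1e-5
  # probe a handful of parameters across layer types
  probes <- list(list(enc$stem_conv, "W", 3L),
                 list(enc$stages[[2]][[1]]$conv1, "W", 10L),
                 list(enc$stages[[1]][[1]]$bn1, "gamma", 2L),
                 list(enc$head, "W", 1L),
                 list(enc$stages[[3]][[1]]$down_conv, "W", 4L))
  for (pr in probes) {
    L <- pr[[1]]; nm <- pr[[2]]; i <- pr[[3]]
    w0 <- get(nm, envir = L)
    analytic <- get(paste0("d", nm), envir = L)[i]
    wp <- w0; wp[i] <- w0[i] + eps
    assign(nm, wp, envir = L); lp <- loss_at()
    wm <- w0; wm[i] <- w0[i] - eps
    assign(nm, wm, envir = L); lm <- loss_at()
    assign(nm, w0, envir = L)
    expect_equal(analytic, (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("source training fits strongly separable synthetic EEG", {
  cfg <- synth_config(n_subjects = 1, trials_per_class = 40,
                      effect_amp = 5, noise_sd = 0.2,
                      subject_gain_sd = 0, seed = 31)
  ts <- generate_eeg_subject(cfg, "S1", classes = c("left", "right"))
  im <- trials_to_images(ts, out_size = 24)
  enc <- build_encoder(encoder_spec("tiny34", dim(im$x)[3], 2, seed = 31))
  train_source(enc, im$x, im$labels,
               train_hyper(epochs = 30, batch_size = 28, seed = 31))
  expect_true(enc$frozen)
  pred <- encoder_predict(enc, im$x)$pred
  acc <- mean(pred == as.integer(factor(im$labels)))
  expect_gte(acc, 0.95)
  expect_equal(nrow(enc$history), 30L)
  expect_lt(enc$history$ce_loss[30], enc$history$ce_loss[1])
})

test_that("zero-epoch training leaves weights unchanged; same seed reproduces", {
  x <- make_batch(h = 8, n = 6, seed = 8)
  y <- rep(c(0, 1), 3)
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 9))
  h0 <- chtlm:::params_hash(chtlm:::encoder_layers(enc))
  train_source(enc, x, y, train_hyper(epochs = 0, seed = 1))
  expect_identical(chtlm:::params_hash(chtlm:::encoder_layers(enc)), h0)
  e1 <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 9))
  e2 <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 9))
  train_source(e1, x, y, train_hyper(epochs = 3, seed = 2))
  train_source(e2, x, y, train_hyper(epochs = 3, seed = 2))
  expect_identical(e1$history$ce_loss, e2$history$ce_loss)
  expect_identical(chtlm:::params_hash(chtlm:::encoder_layers(e1)),
                   chtlm:::params_hash(chtlm:::encoder_layers(e2)))
  expect_error(train_source(enc, x, rep(1, 6)), "classes")
})

test_that("encoder checkpoints round-trip through save/load", {
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 10))
  x <- make_batch(h = 8, n = 6, seed = 12)
  train_source(enc, x, rep(c(0, 1), 3), train_hyper(epochs = 2, seed = 3))
  f <- tempfile(fileext = ".rds")
  save_encoder(enc, f)
  expect_true(file.exists(paste0(f, ".json")))
  enc2 <- load_encoder(f)
  xb <- make_batch(h = 8, n = 2, seed = 13)
  expect_equal(forward_with_taps(enc, xb)$logits,
               forward_with_taps(enc2, xb)$logits, tolerance = 1e-12)
})
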