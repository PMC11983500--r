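# Independent oracles used to freeze expected values. These deliberately
# use different algorithms from the implementation they check.

# direct O(n^2) discrete convolution of a boxcar with the canonical HRF
oracle_hrf_boxcar <- function(n, fs, onset_s, dur_s) {
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= onset_s & t < onset_s + dur_s)
  hrf <- chtlm::canonical_hrf(t)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(i)) s <- s + box[j] * hrf[i - j + 1]
    out[i] <- s / fs
  }
  out
}

# exhaustive-enumeration Mann-Whitney: distribution of U_xy over all
# C(n1+n2, n1) rank assignments (tie-free samples only)
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_xy <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u <- min(u_xy, n1 * n2 - u_xy)
  combs <- utils::combn(n1 + n2, n1)
  us <- colSums(combs) - n1 * (n1 + 1) / 2
  list(U = u, p = min(1, 2 * mean(us <= u)))
}

# FISTA (proximal gradient) solver for 1/2||Hb - y||^2 + lambda||b||_1;
# an algorithmically independent check on the coordinate-descent fit
oracle_lasso_fista <- function(H, y, lambda, iters = 5000) {
  L <- ncol(H)
  lip <- max(eigen(crossprod(H), symmetric = TRUE,
                   only.values = TRUE)$values)
  st <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  b <- numeric(L); z <- b; tk <- 1
  for (i in seq_len(iters)) {
    g <- drop(crossprod(H, H %*% z - y))
    bn <- st(z - g / lip, lambda / lip)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + (tk - 1) / tn * (bn - b)
    b <- bn; tk <- tn
  }
  b
}

# trapezoidal ROC integration (threshold sweep), independent of the
# rank-statistic AUC
oracle_auc_trapezoid <- function(y, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(y == 1); nn <- sum(y == 0)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 1) / np,
                     numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 0) / nn,
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# mu-band power linear classifier for synthetic EEG (threshold on the
# difference of class-pattern band power)
oracle_bandpower_acc <- function(ts, classes) {
  stopifnot(length(classes) == 2)
  K <- dim(ts$data)[2]
  blocks <- split(seq_len(K), cut(seq_len(K), 2, labels = FALSE))
  bp <- function(x, fs) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    mean(sp[f >= 8 & f <= 13])
  }
  feat <- vapply(seq_len(dim(ts$data)[1]), function(i) {
    p1 <- mean(vapply(blocks[[1]], function(ch) bp(ts$data[i, ch, ], ts$fs),
                      numeric(1)))
    p2 <- mean(vapply(blocks[[2]], function(ch) bp(ts$data[i, ch, ], ts$fs),
                      numeric(1)))
    log(p1) - log(p2)
  }, numeric(1))
  pred <- ifelse(feat > stats::median(feat), classes[1], classes[2])
  mean(pred == ts$labels)
}

# small deterministic image batch for encoder tests
make_batch <- function(h = 16, n = 2, c_ = 2, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(h * h * c_ * n), c(h, h, c_, n))
}

# controlled half-signal/half-noise source construction: returns the number
# of seeds for which the mean learned transfer weight over the 4
# class-informative source channels exceeds the mean over the 4 noise
# channels after transfer training
half_signal_weight_wins <- function(seeds) {
  wins <- 0L
  for (seed in seeds) {
    set.seed(seed)
    n <- 32L; h <- 16L
    y <- rep(c(0L, 1L), n / 2)
    tA <- outer(stats::dnorm(1:h, 5, 2), stats::dnorm(1:h, 5, 2))
    tB <- outer(stats::dnorm(1:h, 12, 2), stats::dnorm(1:h, 12, 2))
    x <- array(stats::rnorm(h * h * 2 * n, 0, 0.2), c(h, h, 2, n))
    for (i in seq_len(n)) {
      tpl <- if (y[i] == 1L) tA else tB
      x[, , 1, i] <- x[, , 1, i] + tpl / max(tpl)
    }
    src <- chtlm::feature_source(widths = rep(8L, 4), forward = function(xb) {
      nb <- dim(xb)[4]
      tap <- array(0, c(8, 8, 8, nb))
      noise <- chtlm:::with_seed(777, array(stats::rnorm(8 * 8 * 4 * nb),
                                            c(8, 8, 4, nb)))
      for (i in seq_len(nb)) {
        sig <- chtlm:::bilinear_resize(xb[, , 1, i], 8, 8)
        for (cc in 1:4) tap[, , cc, i] <- sig * cc
        tap[, , 5:8, i] <- noise[, , , i]
      }
      list(tap, NULL, NULL, NULL)
    })
    tgt <- chtlm::build_encoder(chtlm::encoder_spec("tiny18", 2, 2,
                                                    seed = seed))
    hy <- chtlm::transfer_hyper(beta = 1, candidate_pairs = list(c(1L, 1L)),
                                epochs = 15, batch_size = 16, seed = seed)
    tt <- chtlm::transfer_train(src, tgt, NULL, x, y, hy)
    w <- chtlm::pair_weights(tt$nets[[1]]$wn, src$forward(x)[[1]])
    if (mean(w[, 1:4]) > mean(w[, 5:8])) wins <- wins + 1L
  }
  wins
}
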