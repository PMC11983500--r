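test_that("hidden layer initialization is seeded and shaped correctly", {
  h1 <- init_hidden(10, 20, seed = 91)
  h2 <- init_hidden(10, 20, seed = 91)
  h3 <- init_hidden(10, 20, seed = 92)
  expect_identical(h1, h2)
  expect_false(identical(h1$W, h3$W))
  expect_equal(dim(h1$W), c(10L, 20L))
  expect_length(h1$b, 20L)
  expect_true(all(h1$W >= -1 & h1$W <= 1))
  expect_error(init_hidden(10, 0), "L")
})

test_that("hidden matrix is the sigmoid of the affine map", {
  m <- sbelm(3, L = 5, seed = 93)
  m$b[] <- 0
  H <- hidden_matrix(m, matrix(0, 4, 3))
  expect_true(all(H == 0.5))
  set.seed(94)
  H2 <- hidden_matrix(m, matrix(stats::rnorm(12), 4, 3))
  expect_true(all(H2 > 0 & H2 < 1))
  expect_error(hidden_matrix(m, matrix(0, 2, 7)), "columns")
})

test_that("coordinate descent solves the hand-checkable one-unit problem", {
  # H = [[1], [-1]], y = [1, -1], lambda = 1:
  # beta = soft_threshold(H'y = 2, 1) / (H'H = 2) = 0.5
  H <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  expect_equal(lasso_cd(H, y, lambda = 1), 0.5, tolerance = 1e-10)
  expect_equal(lasso_cd(H, y, lambda = 0), 1, tolerance = 1e-8)
})

test_that("beta is exactly zero at and above the KKT bound", {
  set.seed(95)
  for (rep in 1:10) {
    H <- matrix(stats::rnorm(30 * 8), 30, 8)
    y <- stats::rnorm(30)
    lam_max <- max(abs(crossprod(H, y)))
    expect_identical(lasso_cd(H, y, lam_max), rep(0, 8))
    expect_identical(lasso_cd(H, y, lam_max * 1.5), rep(0, 8))
    b <- lasso_cd(H, y, lam_max * 0.5)
    expect_gt(sum(b != 0), 0)
  }
})

test_that("coordinate descent matches the independent FISTA solver", {
  set.seed(96)
  for (rep in 1:50) {
    n <- sample(10:40, 1); L <- sample(3:20, 1)
    H <- matrix(stats::rnorm(n * L), n, L)
    y <- stats::rnorm(n)
    lam <- stats::runif(1, 0.05, 2)
    b_cd <- lasso_cd(H, y, lam)
    b_or <- oracle_lasso_fista(H, y, lam)
    expect_lt(abs(chtlm:::lasso_objective(H, y, b_cd, lam) -
                    chtlm:::lasso_objective(H, y, b_or, lam)), 1e-5)
  }
})

test_that("the L1 solution path is monotone in lambda", {
  set.seed(97)
  for (rep in 1:10) {
    H <- matrix(stats::rnorm(25 * 12), 25, 12)
    y <- stats::rnorm(25)
    lams <- sort(stats::runif(6, 0.01, 3))
    l1 <- vapply(lams, function(l) sum(abs(lasso_cd(H, y, l))), numeric(1))
    expect_true(all(diff(l1) <= 1e-6))
  }
})

test_that("near-zero penalty interpolates separable training data", {
  set.seed(98)
  n <- 12
  X <- matrix(stats::rnorm(n * 4), n, 4)
  y <- rep(c(1L, 0L), n / 2)
  m <- sbelm(4, L = 40, seed = 99)   # L >= n: full row rank w.h.p.
  m <- fit(m, X, y, plain = TRUE)
  pr <- predict(m, X)
  expect_equal(pr$labels, y)
  yt <- ifelse(y == 1, 1, -1)
  expect_lt(max(abs(pr$scores - yt)), 1e-3)
})

test_that("prediction follows the sign rule with ties to rest", {
  set.seed(100)
  X <- matrix(stats::rnorm(20), 5, 4)
  m <- sbelm(4, L = 6, seed = 101)
  m <- fit(m, X, c(1, 0, 1, 0, 1))
  m$beta_out[] <- 0
  pr <- predict(m, X)
  expect_true(all(pr$scores == 0))
  expect_true(all(pr$labels == 0L))
  # flipping the sign of beta flips every nonzero-score label
  m2 <- fit(sbelm(4, L = 6, seed = 101), X, c(1, 0, 1, 0, 1))
  p1 <- predict(m2, X)
  m2$beta_out <- -m2$beta_out
  p2 <- predict(m2, X)
  nz <- p1$scores != 0
  expect_equal(p2$labels[nz], 1L - p1$labels[nz])
  un <- sbelm(4, L = 6, seed = 102)
  expect_error(predict(un, X), "not fitted")
})

test_that("fit validates labels and the lambda grid", {
  X <- matrix(stats::rnorm(20), 5, 4)
  m <- sbelm(4, L = 6, seed = 103)
  expect_error(fit(m, X, rep(1L, 5)), "classes")
  expect_error(fit(m, X, c(1, 0, 1, 0, 1), lambda_grid = numeric(0)),
               "grid")
})

test_that("sparse fit generalizes like the dense ablation with fewer weights", {
  sparser <- 0L; acc_ok <- 0L
  for (seed in 1:5) {
    set.seed(200 + seed)
    n <- 60; p <- 20
    signal <- matrix(stats::rnorm(n), n, 1)
    y <- as.integer(signal[, 1] + stats::rnorm(n, 0, 0.4) > 0)
    X <- cbind(signal, matrix(stats::rnorm(n * (p - 1)), n, p - 1))
    tr <- seq_len(40); te <- 41:60
    ms <- fit(sbelm(p, L = 60, seed = seed), X[tr, ], y[tr])
    md <- fit(sbelm(p, L = 60, seed = seed), X[tr, ], y[tr], plain = TRUE)
    acc_s <- mean(predict(ms, X[te, ])$labels == y[te])
    acc_d <- mean(predict(md, X[te, ])$labels == y[te])
    if (acc_s >= acc_d - 0.02) acc_ok <- acc_ok + 1L
    if (sum(ms$beta_out != 0) < sum(md$beta_out != 0))
      sparser <- sparser + 1L
  }
  expect_gte(acc_ok, 4L)
  expect_gte(sparser, 4L)
})

test_that("fitted models survive the save/load round trip", {
  set.seed(104)
  X <- matrix(stats::rnorm(40), 10, 4)
  y <- rep(c(1L, 0L), 5)
  m <- fit(sbelm(4, L = 8, seed = 105), X, y)
  f <- tempfile(fileext = ".rds")
  save_sbelm(m, f)
  m2 <- load_sbelm(f)
  expect_equal(predict(m2, X)$scores, predict(m, X)$scores)
  expect_true(file.exists(paste0(f, ".json")))
})
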