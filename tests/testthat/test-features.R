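test_that("per-kernel features have the architecture's dimensionality", {
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 71))
  x <- make_batch(h = 16, n = 3, c_ = 2, seed = 72)
  ft <- extract_kernel_features(enc, x, labels = c(1, 0, 1))
  expect_equal(ncol(ft$X), 248L)
  expect_equal(nrow(ft$X), 3L)
  expect_equal(nrow(ft$feature_ids), 248L)
  expect_equal(ft$feature_ids$layer[1], "stem")
})

test_that("zero input with zero-bias convolutions yields zero stem features", {
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 73))
  enc$stem_conv$b[] <- 0
  x <- array(0, c(16, 16, 2, 2))
  ft <- extract_kernel_features(enc, x)
  stem_cols <- which(ft$feature_ids$layer == "stem")
  expect_true(all(ft$X[, stem_cols] == 0))
})

test_that("feature extraction is deterministic and batch-invariant", {
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 74))
  x <- make_batch(h = 16, n = 5, c_ = 2, seed = 75)
  a <- extract_kernel_features(enc, x)$X
  b <- extract_kernel_features(enc, x)$X
  expect_identical(a, b)
  single <- extract_kernel_features(enc, x[, , , 2, drop = FALSE])$X
  expect_equal(unname(single[1, ]), unname(a[2, ]), tolerance = 1e-12)
  chunked <- extract_kernel_features(enc, x, chunk = 2L)$X
  expect_equal(chunked, a, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exhaustive enumeration on the spec example", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)        # 2 of the 20 rank assignments
  expect_equal(r$method, "exact")
  o <- oracle_mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, o$U); expect_equal(r$p, o$p)
})

test_that("Mann-Whitney U agrees with enumeration on all small tie-free samples", {
  set.seed(76)
  for (rep in 1:60) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    v <- sample(100, n1 + n2)    # distinct values, no ties
    x <- v[seq_len(n1)]; y <- v[n1 + seq_len(n2)]
    r <- mann_whitney_u(x, y)
    o <- oracle_mwu(x, y)
    expect_equal(r$U, o$U)
    expect_equal(r$p, o$p)
  }
})

test_that("identical samples give the maximal two-sided p", {
  r <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$p, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("exact and normal-approximation p-values agree closely", {
  set.seed(77)
  for (rep in 1:100) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(1000, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[n1 + seq_len(n2)]
    pe <- mann_whitney_u(x, y)$p
    pa <- mann_whitney_u(x, y, exact_max = 0L)$p
    expect_lt(abs(pe - pa), 0.05)
  }
})

test_that("Mann-Whitney agrees with the base R implementation", {
  set.seed(78)
  for (rep in 1:20) {
    x <- stats::rnorm(15); y <- stats::rnorm(12, 0.5)
    r <- mann_whitney_u(x, y)
    w <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(min(r$U, length(x) * length(y) - r$U),
                 min(unname(w$statistic),
                     length(x) * length(y) - unname(w$statistic)))
    expect_equal(r$p, w$p.value, tolerance = 1e-6)
  }
})

test_that("label-correlated features are selected, and alpha = 1 selects all", {
  set.seed(79)
  y <- rep(c(1L, 0L), 10)
  X <- cbind(y + stats::rnorm(20, 0, 0.01), stats::rnorm(20))
  fr <- filter_features(X, alpha = 0.05, labels = y)
  expect_true(fr$selected[1])
  expect_lt(fr$p_values[1], 0.001)
  fr_all <- filter_features(X, alpha = 1.0, labels = y)
  expect_true(all(fr_all$selected))
  expect_error(filter_features(X, labels = rep(1L, 20)), "classes")
})

test_that("type-I error of the filter is near alpha on null features", {
  set.seed(80)
  y <- rep(c(1L, 0L), 10)
  X <- matrix(stats::rnorm(20 * 200), 20, 200)
  fr <- filter_features(X, alpha = 0.05, labels = y)
  rate <- mean(fr$selected)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("empty selection falls back to the smallest-p features", {
  set.seed(81)
  y <- rep(c(1L, 0L), 4)
  X <- matrix(stats::rnorm(8 * 10), 8, 10)
  fr <- filter_features(X, alpha = 1e-12, labels = y, fallback_k = 4L)
  expect_true(fr$fallback)
  expect_equal(sum(fr$selected), 4L)
  expect_true(all(fr$p_values[fr$selected] <= max(fr$p_values)))
})

test_that("feature tables persist to TSV with a JSON sidecar", {
  enc <- build_encoder(encoder_spec("tiny18", 2, 2, seed = 82))
  x <- make_batch(h = 16, n = 4, c_ = 2, seed = 83)
  ft <- extract_kernel_features(enc, x, labels = c(1, 0, 1, 0))
  f <- tempfile(fileext = ".tsv")
  write_feature_table(ft, f, filter_features(ft, alpha = 0.5))
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 4L)
  expect_equal(ncol(tab), 249L)   # label + 248 features
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$n_features, 248L)
  expect_length(side$p_values, 248L)
})
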