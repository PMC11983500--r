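#' Extract per-kernel averaged deep features
#'
#' Runs images through the (trained) target encoder in evaluation mode and
#' records, for every main-path convolution kernel, the spatial mean of
#' its raw activation map (pre-normalization), ordered by network forward
#' order. The result has exactly [count_feature_kernels()] columns — 3904
#' for a `resnet18` target.
#'
#' @param enc trained encoder.
#' @param x image batch `[H x W x C x N]` (e.g. from [trials_to_images()]).
#' @param labels optional per-trial labels carried through.
#' @param subject_id optional per-trial subject identifiers (length 1 or N).
#' @param chunk evaluation chunk size (memory control; results are
#'   independent of chunking).
#' @return a `feature_table`: list with `X` (`n_trials x n_features`
#'   matrix), `feature_ids` (layer/kernel data frame), `labels`,
#'   `subject_id`.
#' @export
extract_kernel_features <- function(enc, x, labels = NULL, subject_id = NULL,
                                    chunk = 32L) {
  stopifnot(inherits(enc, "encoder"))
  N <- dim(x)[4]
  rows <- list()
  for (s0 in seq(1, N, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, N)
    fw <- encoder_forward(enc, x[, , , idx, drop = FALSE],
                          train = FALSE, collect = TRUE)
    rows[[length(rows) + 1L]] <- t(fw$kernel_means)
  }
  X <- do.call(rbind, rows)
  nf <- count_feature_kernels(enc$spec)
  stopifnot(ncol(X) == nf)
  vt <- enc$vt
  layer <- c(rep("stem", vt$stem_width),
             unlist(lapply(1:4, function(s)
               rep(sprintf("stage%d.b%d.conv%d", s,
                           rep(seq_len(vt$blocks[s]), each = 2),
                           rep(1:2, vt$blocks[s])),
                   each = vt$widths[s]))))
  kernel <- unlist(lapply(rle(layer)$lengths, seq_len))
  structure(list(X = X,
                 feature_ids = data.frame(layer = layer, kernel = kernel),
                 labels = labels,
                 subject_id = if (is.null(subject_id)) NULL
                              else rep_len(subject_id, N)),
            class = "feature_table")
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Computes `U_xy = sum over pairs of [x_i > y_j] + 1/2 [x_i == y_j]` and
#' reports the min-side statistic `U = min(U_xy, U_yx)` with a two-sided
#' p-value: exact by complete enumeration of rank assignments when
#' `n1 + n2 <= exact_max` and the pooled sample is tie-free, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_max enumeration threshold on `n1 + n2`.
#' @return list with `U` (min side), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) < 1L || length(y) < 1L)
    stop_cfg("mann_whitney_u: both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_xy <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_yx <- n1 * n2 - u_xy
  u <- min(u_xy, u_yx)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 + n2 <= exact_max) {
    # exact null distribution of U_xy by enumeration of rank assignments
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(combs) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * mean(us <= u))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  tie_tab <- table(c(x, y))
  tie_corr <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
  sig2 <- n1 * n2 / 12 * ((nn + 1) - tie_corr)
  if (sig2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu + 0.5) / sqrt(sig2)   # continuity correction on the min side
  p <- min(1, 2 * stats::pnorm(z))
  list(U = u, p = p, method = "normal")
}

#' Filter deep features by Mann-Whitney U test
#'
#' Tests every feature column for a location difference between the
#' motor-imagery (label 1) and rest (label 0) trials and keeps features
#' with two-sided `p < alpha`. Computed on training rows only; when no
#' feature passes, the `fallback_k` smallest-p features are kept so the
#' downstream classifier always receives input.
#'
#' @param table a `feature_table` (training rows only) with 0/1 `labels`,
#'   or a plain matrix plus `labels`.
#' @param alpha significance level.
#' @param labels labels when `table` is a matrix.
#' @param fallback_k fallback count when no feature is significant.
#' @return a `filter_result`: list with `p_values`, `selected` (logical
#'   mask), `alpha`, `fallback` (logical).
#' @export
filter_features <- function(table, alpha = 0.05, labels = NULL,
                            fallback_k = 32L) {
  X <- if (inherits(table, "feature_table")) table$X else as.matrix(table)
  if (is.null(labels)) labels <- table$labels
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop_cfg("filter_features: both classes must be present")
  if (alpha < 0 || alpha > 1) stop_cfg("filter_features: alpha in [0,1]")
  i1 <- y == 1L; i0 <- !i1
  p <- vapply(seq_len(ncol(X)), function(j)
    mann_whitney_u(X[i1, j], X[i0, j])$p, numeric(1))
  sel <- p < alpha
  fallback <- FALSE
  if (!any(sel)) {
    fallback <- TRUE
    k <- min(fallback_k, length(p))
    sel <- rank(p, ties.method = "first") <= k
  }
  structure(list(p_values = p, selected = sel, alpha = alpha,
                 fallback = fallback),
            class = "filter_result")
}

#' Persist a feature table as TSV plus JSON sidecar
#'
#' @param table a `feature_table`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param filter optional `filter_result` whose p-values go to the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, filter = NULL) {
  df <- as.data.frame(table$X)
  names(df) <- paste0(table$feature_ids$layer, ".k", table$feature_ids$kernel)
  if (!is.null(table$labels)) df <- cbind(label = table$labels, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(n_features = ncol(table$X),
               feature_ids = table$feature_ids)
  if (!is.null(filter))
    side$p_values <- filter$p_values
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
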