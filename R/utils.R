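#' @keywords internal
#' @useDynLib chtlm, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers shared across modules.

stop_cfg <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cfg("configuration error: '%s' must be a finite numeric scalar", name)
  if (integer && x != round(x))
    stop_cfg("configuration error: '%s' must be an integer", name)
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    stop_cfg("configuration error: '%s' = %g out of range", name, x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Bilinear resize of a matrix
#'
#' Resamples a numeric matrix onto a new grid by bilinear interpolation,
#' treating entries as samples at pixel centres. Used to bring
#' time-frequency planes and convolutional feature maps to a common size.
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return an `out_h` x `out_w` matrix.
#' @keywords internal
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  # map output pixel centres into input coordinates (align-corners = FALSE)
  ry <- if (out_h > 1) in_h / out_h else 1
  rx <- if (out_w > 1) in_w / out_w else 1
  y <- pmin(pmax((seq_len(out_h) - 0.5) * ry + 0.5, 1), in_h)
  x <- pmin(pmax((seq_len(out_w) - 0.5) * rx + 0.5, 1), in_w)
  y0 <- pmin(floor(y), in_h - 1L); y0[in_h == 1] <- 1
  x0 <- pmin(floor(x), in_w - 1L); x0[in_w == 1] <- 1
  if (in_h == 1) { y0 <- rep(1, out_h); wy <- rep(0, out_h) } else wy <- y - y0
  if (in_w == 1) { x0 <- rep(1, out_w); wx <- rep(0, out_w) } else wx <- x - x0
  y1 <- pmin(y0 + 1L, in_h); x1 <- pmin(x0 + 1L, in_w)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

# Min-max normalization of a matrix to [0, 1]; a constant plane maps to all
# zeros rather than dividing by zero.
minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi)))
    return(array(0, dim(m)))
  (m - lo) / (hi - lo)
}

# 1/f ("pink") noise by spectral shaping of white Gaussian noise.
pink_noise <- function(n, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  shaped <- W / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x * sd
}
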