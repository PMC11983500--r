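# Sparse Bayesian extreme learning machine: a single-hidden-layer network
# with fixed random input weights; the output weights are the MAP estimate
# under a Gaussian likelihood and Laplace (L1) prior, i.e. the solution of
#   min_beta 1/2 ||H beta - y||^2 + lambda ||beta||_1,
# solved by cyclic coordinate descent, with lambda picked from a grid by a
# generalized-cross-validation (leave-one-out approximating) score.

#' Initialize the random hidden layer
#'
#' @param n_features input dimensionality.
#' @param L hidden width.
#' @param seed deterministic seed.
#' @return list with `W` (`n_features x L`, Uniform(-1,1)) and `b`
#'   (length `L`, Uniform(-1,1)).
#' @export
init_hidden <- function(n_features, L, seed = 1L) {
  check_scalar(L, "L", lower = 1, integer = TRUE)
  check_scalar(n_features, "n_features", lower = 1, integer = TRUE)
  with_seed(seed, {
    list(W = matrix(stats::runif(n_features * L, -1, 1), n_features, L),
         b = stats::runif(L, -1, 1))
  })
}

#' Construct an (unfitted) SBELM model
#'
#' @param n_features input dimensionality (after feature filtering).
#' @param L hidden-layer width.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param seed seed for the random hidden layer.
#' @return an object of class `sbelm` (unfitted).
#' @export
sbelm <- function(n_features, L = 200, activation = c("sigmoid", "tanh"),
                  seed = 1L) {
  activation <- match.arg(activation)
  h <- init_hidden(n_features, L, seed)
  structure(list(W = h$W, b = h$b, L = as.integer(L),
                 n_features = as.integer(n_features),
                 activation = activation, seed = as.integer(seed),
                 beta_out = NULL, lambda = NULL, scaler = NULL,
                 fitted = FALSE),
            class = "sbelm")
}

#' @export
print.sbelm <- function(x, ...) {
  cat(sprintf("sbelm: %d features -> %d hidden (%s)%s\n",
              x$n_features, x$L, x$activation,
              if (x$fitted)
                sprintf(", fitted: lambda=%.3g, %d/%d nonzero weights",
                        x$lambda, sum(x$beta_out != 0), x$L)
              else " (unfitted)"))
  invisible(x)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Hidden-layer activation matrix
#'
#' @param model an `sbelm`.
#' @param X standardized feature matrix (`n x n_features`).
#' @return `H = activation(X W + b)`, an `n x L` matrix.
#' @export
hidden_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop_cfg("hidden_matrix: X has %d columns, model expects %d",
             ncol(X), model$n_features)
  Z <- sweep(X %*% model$W, 2, model$b, "+")
  switch(model$activation, sigmoid = sigmoid(Z), tanh = tanh(Z))
}

#' L1-penalized least squares by cyclic coordinate descent
#'
#' Minimizes `1/2 ||H beta - y||^2 + lambda ||beta||_1` with
#' soft-thresholding updates; `beta = 0` exactly whenever
#' `lambda >= max|H^T y|` (the KKT bound).
#'
#' @param H design matrix (`n x L`).
#' @param y response vector.
#' @param lambda penalty (>= 0).
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter sweep cap.
#' @param beta0 optional warm start.
#' @return coefficient vector of length `L`.
#' @export
lasso_cd <- function(H, y, lambda, tol = 1e-8, max_iter = 2000L,
                     beta0 = NULL) {
  L <- ncol(H)
  G <- crossprod(H)            # H^T H
  c0 <- drop(crossprod(H, y))  # H^T y
  beta <- if (is.null(beta0)) numeric(L) else beta0
  if (lambda >= max(abs(c0))) return(numeric(L))
  as.numeric(cpp_lasso_cd(G, c0, lambda, beta, tol, as.integer(max_iter)))
}

lasso_objective <- function(H, y, beta, lambda) {
  0.5 * sum((H %*% beta - y)^2) + lambda * sum(abs(beta))
}

#' Fit the SBELM output weights
#'
#' Standardizes the features (training mean/sd), forms the hidden matrix,
#' codes the binary labels as -1/+1 and estimates the sparse output
#' weights as the L1-penalized least-squares (Laplace-prior MAP) solution.
#' The penalty is chosen from `lambda_grid` by the generalized
#' cross-validation score `GCV(lambda) = RSS/n / (1 - df/n)^2` with
#' `df = #nonzero(beta)` (an approximation of leave-one-out error).
#'
#' @param model an `sbelm` from [sbelm()].
#' @param X raw feature matrix (`n x n_features`).
#' @param y 0/1 labels (1 = motor imagery).
#' @param lambda_grid candidate penalties; default a log grid from the
#'   KKT bound `lambda_max = max|H^T y|` down to `1e-4 lambda_max`.
#' @param df_cap candidates whose active set exceeds `df_cap * n` are
#'   excluded from the GCV comparison (the score is unreliable near
#'   interpolation, where both numerator and denominator vanish).
#' @param plain when `TRUE`, fit the plain-ELM ablation: a ridge solve
#'   with penalty `1e-8` (dense output weights, no sparsity).
#' @return the fitted model (`beta_out`, `lambda`, `scaler` populated).
#' @export
fit.sbelm <- function(model, X, y, lambda_grid = NULL, plain = FALSE,
                      df_cap = 0.6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_cfg("fit: both classes must be present")
  if (nrow(X) < 2L) stop_cfg("fit: need at least 2 rows")
  yt <- ifelse(y == 1L, 1, -1)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  model$scaler <- list(mean = mu, sd = sd_)
  H <- hidden_matrix(model, apply_scaler(X, model$scaler))
  n <- nrow(H)
  if (plain) {
    model$beta_out <- drop(solve(crossprod(H) + 1e-8 * diag(ncol(H)),
                                 crossprod(H, yt)))
    model$lambda <- 1e-8
    model$plain <- TRUE
    model$fitted <- TRUE
    return(model)
  }
  lam_max <- max(abs(crossprod(H, yt)))
  if (is.null(lambda_grid))
    lambda_grid <- lam_max * 10^seq(-0.5, -4, length.out = 15)
  if (length(lambda_grid) == 0L) stop_cfg("fit: empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  best <- NULL; best_score <- Inf
  beta_warm <- NULL
  for (lam in lambda_grid) {
    beta <- lasso_cd(H, yt, lam, beta0 = beta_warm)
    beta_warm <- beta
    df <- sum(beta != 0)
    score <- if (df >= df_cap * n) Inf else
      (sum((H %*% beta - yt)^2) / n) / (1 - df / n)^2
    if (score < best_score) {
      best_score <- score; best <- list(beta = beta, lambda = lam)
    }
  }
  if (is.null(best)) { # every candidate saturated; fall back to strongest
    best <- list(beta = lasso_cd(H, yt, lambda_grid[1]),
                 lambda = lambda_grid[1])
  }
  model$beta_out <- best$beta
  model$lambda <- best$lambda
  model$plain <- FALSE
  model$fitted <- TRUE
  model
}

#' @rdname fit.sbelm
#' @export
fit <- function(model, ...) UseMethod("fit")

#' Predict with a fitted SBELM
#'
#' @param object fitted `sbelm`.
#' @param X raw feature matrix.
#' @param ... unused.
#' @return list with `scores` (`H beta`, the decision values feeding the
#'   AUC) and `labels` (1 when score > 0, else 0 — ties go to rest).
#' @export
predict.sbelm <- function(object, X, ...) {
  if (!isTRUE(object$fitted)) stop_cfg("predict: model is not fitted")
  H <- hidden_matrix(object, apply_scaler(as.matrix(X), object$scaler))
  scores <- drop(H %*% object$beta_out)
  list(scores = scores, labels = as.integer(scores > 0))
}

#' Save / load a fitted SBELM model
#'
#' Binary array container plus JSON manifest (seed, lambda, activation).
#'
#' @param model fitted `sbelm`.
#' @param path output `.rds` path.
#' @return `path` (save) or the model (load).
#' @export
save_sbelm <- function(model, path) {
  saveRDS(unclass(model), path)
  jsonlite::write_json(list(L = model$L, n_features = model$n_features,
                            seed = model$seed, activation = model$activation,
                            lambda = model$lambda,
                            nonzero = if (is.null(model$beta_out)) 0
                                      else sum(model$beta_out != 0)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_sbelm
#' @export
load_sbelm <- function(path) {
  structure(readRDS(path), class = "sbelm")
}
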