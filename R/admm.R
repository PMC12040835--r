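#' ADMM configuration for one decomposition layer
#'
#' @param beta positive augmented-Lagrangian penalty; the soft-threshold
#'   applied to the background matrix is `1/beta`, so larger `beta` keeps more
#'   (smaller) entries in `Z`.
#' @param max_iter maximum number of ADMM iterations.
#' @param tol relative-residual stopping tolerance
#'   (`||XY + Z - S||_F / ||S||_F`).
#' @param init `"svd"` (deterministic: leading left singular directions) or
#'   `"random"` (seeded Gaussian factor).
#' @param seed integer seed used by `init = "random"` and by any consumer that
#'   needs reproducible randomness; ignored by the deterministic path.
#' @return An object of class `admm_config`.
#' @export
admm_config <- function(beta = 1, max_iter = 200, tol = 1e-4,
                        init = c("svd", "random"), seed = 1L) {
  init <- match.arg(init)
  if (!is.numeric(beta) || beta <= 0) .stopf("beta must be > 0")
  if (!is.numeric(tol) || tol <= 0) .stopf("tol must be > 0")
  if (max_iter < 1) .stopf("max_iter must be >= 1")
  structure(list(beta = beta, max_iter = as.integer(max_iter), tol = tol,
                 init = init, seed = as.integer(seed)),
            class = "admm_config")
}

#' Soft-thresholding (shrinkage) operator
#'
#' Elementwise proximal operator of the L1 norm:
#' `sign(v) * max(|v| - tau, 0)`.
#'
#' @param value scalar, vector or matrix.
#' @param tau nonnegative threshold.
#' @return Same shape as `value`.
#' @export
soft_threshold <- function(value, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    .stopf("tau must be a single nonnegative number")
  sign(value) * pmax(abs(value) - tau, 0)
}

#' Fit one low-rank + sparse layer by ADMM
#'
#' Solves `input ~ X %*% Y + Z` with `X` (`rows x rank`), `Y`
#' (`rank x cols`) and an L1-sparse background `Z`, by alternating
#' least-squares updates of `X` and `Y` (via pseudoinverse of the partner
#' factor's Gram matrix, so rank-deficient normal equations never crash),
#' soft-thresholding of the residual-adjusted target for `Z` with threshold
#' `1/beta`, and the multiplier update `E <- E + beta * (XY + Z - input)`.
#' Iterations stop at `max_iter` or when the relative residual
#' `||XY + Z - input||_F / ||input||_F` drops to `tol`.
#'
#' @param input numeric matrix, all entries finite.
#' @param rank number of components `D`, `1 <= D <= min(dim(input))`.
#' @param config an [admm_config()].
#' @return An object of class `layer_decomposition` with fields `X`, `Y`,
#'   `Z`, `multiplier`, `rank`, `residual_history` (one entry per iteration)
#'   and `converged`.
#' @export
admm_layer <- function(input, rank, config = admm_config()) {
  input <- as.matrix(input)
  if (!all(is.finite(input))) .stopf("input contains non-finite values")
  n <- nrow(input); m <- ncol(input)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(n, m))
    .stopf("rank must be between 1 and min(rows, cols) = %d", min(n, m))
  stopifnot(inherits(config, "admm_config"))

  norm0 <- .fnorm(input)
  scale_resid <- if (norm0 > 0) norm0 else 1  # zero-norm input: absolute residual

  if (config$init == "svd") {
    sv <- svd(input, nu = rank, nv = 0)
    X <- sv$u
    Y <- crossprod(X, input)
  } else {
    X <- .with_seed(config$seed,
                    matrix(stats::rnorm(n * rank), n, rank))
    Y <- .pinv(crossprod(X)) %*% crossprod(X, input)
  }
  Z <- matrix(0, n, m)
  E <- matrix(0, n, m)
  beta <- config$beta
  tau <- 1 / beta
  hist <- numeric(config$max_iter)
  converged <- FALSE
  n_it <- 0L

  for (it in seq_len(config$max_iter)) {
    A <- input - Z - E / beta
    X <- A %*% t(Y) %*% .pinv(tcrossprod(Y))
    Y <- .pinv(crossprod(X)) %*% crossprod(X, A)
    XY <- X %*% Y
    Z <- soft_threshold(input - XY - E / beta, tau)
    P <- XY + Z - input
    E <- E + beta * P
    n_it <- it
    hist[it] <- .fnorm(P) / scale_resid
    if (hist[it] <= config$tol) { converged <- TRUE; break }
  }

  structure(list(X = X, Y = Y, Z = Z, multiplier = E, rank = rank,
                 residual_history = hist[seq_len(n_it)],
                 converged = converged, config = config),
            class = "layer_decomposition")
}

#' @export
print.layer_decomposition <- function(x, ...) {
  cat(sprintf("<layer_decomposition> rank %d, %d x %d, %d iteration(s), %s (final residual %.3g)\n",
              x$rank, nrow(x$X), ncol(x$Y), length(x$residual_history),
              if (x$converged) "converged" else "not converged",
              utils::tail(x$residual_history, 1)))
  invisible(x)
}

#' Relative reconstruction residual of a fitted layer
#'
#' Returns `||X %*% Y + Z - input||_F / ||input||_F`. For a zero-norm input
#' the absolute Frobenius residual is returned instead (the relative form is
#' undefined).
#'
#' @param decomp a [admm_layer()] result.
#' @param input_matrix the matrix the layer was fitted to.
#' @return Nonnegative scalar.
#' @export
layer_residual <- function(decomp, input_matrix) {
  stopifnot(inherits(decomp, "layer_decomposition"))
  input_matrix <- as.matrix(input_matrix)
  if (!all(dim(input_matrix) == c(nrow(decomp$X), ncol(decomp$Y))))
    .stopf("input dimensions do not match the decomposition")
  r <- .fnorm(decomp$X %*% decomp$Y + decomp$Z - input_matrix)
  n0 <- .fnorm(input_matrix)
  if (n0 > 0) r / n0 else r
}
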