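#' Thresholds for the rank reduction operator
#'
#' @param ratio_threshold minimum weighted ratio (one-step drop in the pivoted
#'   QR diagonal) accepted as a rank gap. If no ratio reaches it, the rank
#'   falls back to the numerical rank. Pivoted-QR diagonals compress spectral
#'   gaps relative to singular values, while consecutive ratios inside a
#'   noise plateau stay near 1; the default of 3 separates the two regimes.
#' @param eps_abs relative floor: diagonal entries below `eps_abs * d[1]` are
#'   treated as numerically zero.
#' @return An object of class `rro_thresholds`.
#' @export
rro_thresholds <- function(ratio_threshold = 3, eps_abs = 1e-8) {
  if (ratio_threshold <= 1) .stopf("ratio_threshold must be > 1")
  if (eps_abs <= 0 || eps_abs >= 1) .stopf("eps_abs must be in (0, 1)")
  structure(list(ratio_threshold = ratio_threshold, eps_abs = eps_abs),
            class = "rro_thresholds")
}

#' Diagonal magnitudes of a column-pivoted QR factorisation
#'
#' Column pivoting makes `|R[i,i]|` non-increasing (the entries track the
#' singular values); the returned vector is additionally sorted to guarantee
#' monotonicity against floating-point slack.
#'
#' @param x numeric matrix with at least one row and column, all finite.
#' @return Vector of `min(nrow, ncol)` nonnegative values, non-increasing.
#' @export
qr_diagonal <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) .stopf("matrix contains non-finite values")
  if (nrow(x) < 1L || ncol(x) < 1L) .stopf("matrix must have >= 1 row and column")
  qd <- qr(x, LAPACK = TRUE)  # LAPACK dgeqp3: column-pivoted Householder QR
  k <- min(dim(x))
  d <- abs(diag(qd$qr)[seq_len(k)])
  sort(d, decreasing = TRUE)
}

#' Weighted ratio of successive QR diagonal entries
#'
#' `wr[i] = d[i] / d[i+1]`; a zero following entry yields `Inf` (a maximal
#' gap).
#'
#' @param d non-increasing nonnegative vector, length >= 2.
#' @return Vector of length `length(d) - 1`.
#' @export
weighted_ratio <- function(d) {
  if (length(d) < 2L) .stopf("need at least 2 diagonal entries")
  num <- d[-length(d)]
  den <- d[-1L]
  wr <- ifelse(den == 0, ifelse(num == 0, 1, Inf), num / den)
  as.numeric(wr)
}

#' Weighted difference of successive QR diagonal entries
#'
#' `wd[i] = (d[i+1] - d[i]) / sum(d[1:i])`: the (signed) one-step drop
#' normalised by the cumulative mass of all preceding entries.
#'
#' @param d non-increasing nonnegative vector, length >= 2.
#' @return Vector of length `length(d) - 1`.
#' @export
weighted_difference <- function(d) {
  if (length(d) < 2L) .stopf("need at least 2 diagonal entries")
  diff(d) / cumsum(d)[-length(d)]
}

#' Weighted correlation differences between adjacent components
#'
#' `wc[i] = |corr(row[i+2], row[i+1]) - corr(row[i+1], row[i])|` with Pearson
#' correlation, for `i = 1 .. D-2`. A constant row makes its correlations
#' undefined; those terms are set to 0 with a warning.
#'
#' @param rows matrix with `D >= 3` row components.
#' @return Vector of length `D - 2`.
#' @export
weighted_correlation <- function(rows) {
  rows <- as.matrix(rows)
  d <- nrow(rows)
  if (d < 3L) .stopf("need at least 3 row components")
  sds <- apply(rows, 1, stats::sd)
  if (any(sds == 0)) warning("constant row(s): affected correlation terms set to 0")
  corr <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  adj <- vapply(seq_len(d - 1L), function(i) corr(rows[i + 1L, ], rows[i, ]),
                numeric(1))
  abs(adj[-1L] - adj[-(d - 1L)])
}

#' Full rank diagnostics for a matrix
#'
#' Computes the pivoted QR diagonal `d`, the weighted ratios `wr`, weighted
#' differences `wd` and (optionally, from the leading right singular vectors)
#' the weighted correlation differences `wc`, together with the estimated
#' rank. `wr` is the primary decision statistic (see [estimate_rank()]);
#' `wd` and `wc` are reported for diagnostics.
#'
#' @param x numeric matrix.
#' @param thresholds an [rro_thresholds()].
#' @param compute_wc also compute `wc` (requires a partial SVD; skipped by
#'   default for speed).
#' @return An object of class `rank_diagnostics` with fields `d`, `wr`, `wd`,
#'   `wc` and `estimated_rank`.
#' @export
rank_diagnostics <- function(x, thresholds = rro_thresholds(),
                             compute_wc = FALSE) {
  stopifnot(inherits(thresholds, "rro_thresholds"))
  d <- qr_diagonal(x)
  if (d[1] == 0) {
    warning("zero matrix: estimated rank set to 1")
    return(structure(list(d = d, wr = NULL, wd = NULL, wc = NULL,
                          estimated_rank = 1L),
                     class = "rank_diagnostics"))
  }
  wr <- if (length(d) >= 2L) weighted_ratio(d) else NULL
  wd <- if (length(d) >= 2L) weighted_difference(d) else NULL
  wc <- NULL
  if (compute_wc && min(dim(x)) >= 3L) {
    k <- min(length(d), 25L)
    vt <- t(svd(as.matrix(x), nu = 0, nv = k)$v)
    wc <- weighted_correlation(vt)
  }
  keep <- d >= thresholds$eps_abs * d[1]
  n_rank <- sum(keep)
  est <- n_rank
  if (!is.null(wr)) {
    cand <- which(keep[-length(d)])  # gaps at positions with d[i] above floor
    if (length(cand)) {
      best <- cand[which.max(wr[cand])]
      if (wr[best] >= thresholds$ratio_threshold) est <- best
    }
  }
  structure(list(d = d, wr = wr, wd = wd, wc = wc,
                 estimated_rank = as.integer(max(1L, est))),
            class = "rank_diagnostics")
}

#' @export
print.rank_diagnostics <- function(x, ...) {
  cat(sprintf("<rank_diagnostics> estimated rank %d of %d diagonal entries\n",
              x$estimated_rank, length(x$d)))
  invisible(x)
}

#' Estimate the effective rank of a matrix
#'
#' The rank is the index of the largest weighted ratio `wr[i] = d[i]/d[i+1]`
#' of the pivoted QR diagonal, restricted to entries above the numerical
#' floor, provided that ratio reaches `ratio_threshold`; otherwise the
#' numerical rank (count of `d[i] >= eps_abs * d[1]`) is returned. A zero
#' matrix yields 1 with a warning.
#'
#' @inheritParams rank_diagnostics
#' @return Positive integer between 1 and `min(dim(x))`.
#' @export
estimate_rank <- function(x, thresholds = rro_thresholds()) {
  rank_diagnostics(x, thresholds, compute_wc = FALSE)$estimated_rank
}

#' Drop the trailing components of an ordered component set
#'
#' The rank reduction operator: given `D` components ordered by decreasing
#' pivot magnitude (rows of a matrix), drop the trailing `k` (the weakest)
#' and keep the leading `D - k` in their original order.
#'
#' @param components matrix of `D` ordered row components.
#' @param k number of components to drop, `1 <= k < D`.
#' @return Matrix of the leading `D - k` rows.
#' @export
apply_rro <- function(components, k = 1L) {
  components <- as.matrix(components)
  d <- nrow(components)
  k <- as.integer(k)
  if (k < 1L || k >= d) .stopf("k must satisfy 1 <= k < D = %d", d)
  components[seq_len(d - k), , drop = FALSE]
}
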