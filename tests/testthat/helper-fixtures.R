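# Small fixtures shared across test files. Everything is built in code at
# test time; nothing is stored on disk.

# tiny spherical mask (~1100-1200 voxels) for fast end-to-end runs
tiny_mask <- function() make_mask(dim = c(15L, 15L, 15L), radius = 6.6)

# full-cube mask on an n^3 grid
cube_mask <- function(n = 4L) brain_mask(array(TRUE, dim = rep(n, 3L)))

# seeded low-rank matrix with known factors
lowrank_matrix <- function(n, m, r, seed = 1L) {
  set.seed(seed)
  list(X = matrix(rnorm(n * r), n, r),
       Y = matrix(rnorm(r * m), r, m))
}

# small synthetic study: reduced dimensions of the default preset, same
# structure (12 canonical networks in 4 meta-groups is too large for a tiny
# mask; 6 networks in 2 groups keeps every mechanism exercised)
tiny_truth <- function(seed = 7L, snr = 2, ...) {
  synthetic_truth(mask = tiny_mask(), n_canonical = 6L, n_meta = 2L,
                  n_time = 80L, snr = snr, seed = seed, ...)
}

# exhaustive-search oracle for the assignment problem: maximise total
# similarity over all injective template -> component assignments
exhaustive_assignment <- function(values) {
  n_comp <- nrow(values); n_tmpl <- ncol(values)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_total <- -Inf
  for (subset in utils::combn(n_comp, n_tmpl, simplify = FALSE)) {
    for (p in perms(subset)) {
      tot <- sum(values[cbind(p, seq_len(n_tmpl))])
      if (tot > best_total) { best_total <- tot; best <- p }
    }
  }
  list(assignment = best, total = best_total)
}

# classical Gram-Schmidt column-pivoted QR diagonal, as an independent
# linear-algebra oracle for qr_diagonal()
gs_pivoted_qr_diag <- function(x) {
  x <- as.matrix(x)
  k <- min(dim(x))
  d <- numeric(k)
  for (i in seq_len(k)) {
    norms <- sqrt(colSums(x^2))
    j <- which.max(norms)
    d[i] <- norms[j]
    if (norms[j] < .Machine$double.eps) { d[i:k] <- 0; break }
    q <- x[, j] / norms[j]
    x <- x[, -j, drop = FALSE]
    if (ncol(x) > 0) x <- x - q %*% crossprod(q, x)
  }
  d
}
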