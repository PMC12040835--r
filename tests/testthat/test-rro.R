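test_that("qr_diagonal matches an independent pivoted-QR oracle", {
  expect_equal(qr_diagonal(diag(5)), rep(1, 5))

  set.seed(31)
  u <- rnorm(20); v <- rnorm(30)
  d <- qr_diagonal(outer(u, v))
  expect_gt(d[1], 0)
  expect_true(all(d[-1] <= 1e-10 * d[1]))

  set.seed(32)
  x <- matrix(rnorm(100), 10, 10)
  expect_equal(qr_diagonal(x), gs_pivoted_qr_diag(x), tolerance = 1e-10)
})

test_that("weighted ratio, difference and correlation follow their formulas", {
  expect_equal(weighted_ratio(c(4, 2, 1)), c(2, 2))
  expect_equal(weighted_ratio(c(1, 1, 1)), c(1, 1))
  expect_equal(weighted_ratio(c(9, 3, 0.5)), c(3, 6))
  expect_equal(weighted_ratio(c(1, 0)), Inf)
  expect_error(weighted_ratio(3), "at least 2")

  expect_equal(weighted_difference(c(4, 2, 1)), c(-0.5, -1 / 6))
  expect_equal(weighted_difference(c(1, 1)), 0)
  expect_equal(weighted_difference(c(2, 4)), 1.0)

  same <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4)  # three identical rows
  expect_equal(weighted_correlation(same), 0)
  r1 <- c(1, -1, 1, -1); r2 <- c(1, 1, -1, -1)  # orthogonal
  expect_equal(weighted_correlation(rbind(r1, r2, r2)), 1)

  set.seed(33)
  rows <- matrix(rnorm(5 * 40), 5, 40)
  adj <- sapply(1:4, function(i) cor(rows[i + 1, ], rows[i, ]))
  expect_equal(weighted_correlation(rows), abs(diff(adj)), tolerance = 1e-12)
  expect_warning(weighted_correlation(rbind(r1, r2, rep(1, 4))), "constant")
})

test_that("estimate_rank recovers exact algebraic rank (SVD oracle)", {
  expect_equal(estimate_rank(diag(5)), 5L)
  set.seed(34)
  expect_equal(estimate_rank(outer(rnorm(20), rnorm(30))), 1L)
  for (r in 1:8) {
    set.seed(40 + r)
    a <- matrix(rnorm(50 * r), 50, r) %*% matrix(rnorm(r * 200), r, 200)
    sv <- svd(a, nu = 0, nv = 0)$d
    svd_rank <- sum(sv >= 1e-8 * sv[1])
    expect_equal(estimate_rank(a), r)
    expect_equal(estimate_rank(a), svd_rank)
  }
  expect_warning(expect_equal(estimate_rank(matrix(0, 4, 4)), 1L), "zero")
})

test_that("estimate_rank is robust to noise at SNR 10", {
  for (r in c(2, 5, 8)) {
    set.seed(50 + r)
    a <- matrix(rnorm(100 * r), 100, r) %*% matrix(rnorm(r * 1000), r, 1000)
    a <- a / sd(a) * 10
    expect_equal(estimate_rank(a + matrix(rnorm(1e5), 100, 1000)), r)
  }
})

test_that("apply_rro drops the weakest trailing components and composes", {
  comp <- matrix(seq_len(50), 5, 10)
  r1 <- apply_rro(comp, 1)
  expect_equal(nrow(r1), 4L)
  expect_equal(r1, comp[1:4, ])
  expect_equal(apply_rro(apply_rro(comp, 1), 1), apply_rro(comp, 2))
  expect_equal(apply_rro(matrix(1, 6, 3), 4), matrix(1, 2, 3))

  # repeated single reductions reach one component in exactly D - 1 steps
  cur <- comp; steps <- 0L
  while (nrow(cur) > 1L) { cur <- apply_rro(cur, 1); steps <- steps + 1L }
  expect_equal(steps, 4L)
  expect_error(apply_rro(comp, 5), "k must")
})

test_that("rank_diagnostics reports consistent d, wr, wd, wc fields", {
  set.seed(35)
  a <- matrix(rnorm(30 * 3), 30, 3) %*% matrix(rnorm(3 * 40), 3, 40) +
    0.01 * matrix(rnorm(1200), 30, 40)
  diag_ <- rank_diagnostics(a, compute_wc = TRUE)
  expect_true(all(diff(diag_$d) <= 0))
  expect_length(diag_$wr, length(diag_$d) - 1L)
  expect_length(diag_$wd, length(diag_$d) - 1L)
  expect_length(diag_$wc, min(length(diag_$d), 25L) - 2L)
  expect_equal(diag_$estimated_rank, 3L)
})
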