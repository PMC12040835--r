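test_that("binarize_top_fraction keeps the right voxels with index tie-breaks", {
  expect_length(binarize_top_fraction(rnorm(100), 0.05), 5L)
  expect_length(binarize_top_fraction(rnorm(10), 1.0), 10L)
  expect_setequal(binarize_top_fraction(c(5, 4, 3, 2, 1), 0.4), c(1L, 2L))
  # all-equal map: exactly ceil(f * M) voxels, lowest indices win
  expect_equal(sort(binarize_top_fraction(rep(1, 10), 0.3)), 1:3)
  expect_error(binarize_top_fraction(1:5, 0), "fraction")
})

test_that("spatial similarity follows the template-denominator formula", {
  x <- c(10, 9, 8, 7, 1, 1, 1, 1, 1, 1)
  expect_equal(spatial_similarity(x, x, fraction = 0.4), 1.0)

  # component active set covers 2 of the template's 4 active voxels
  comp <- c(9, 8, 0, 0, 7, 6, 0, 0, 0, 0)
  tmpl <- c(9, 8, 7, 6, 0, 0, 0, 0, 0, 0)
  expect_equal(spatial_similarity(comp, tmpl, fraction = 0.4), 0.5)

  # disjoint active sets
  a <- c(1, 1, 0, 0, rep(-1, 6)); b <- c(0, 0, 1, 1, rep(-1, 6))
  expect_equal(spatial_similarity(a, b, fraction = 0.2), 0)

  # asymmetric by construction (template denominator): a 5-active component
  # against a 2-active... fractions fixed, so asymmetry shows via unequal sets
  cx <- c(5, 4, 3, 0, 0, 0, 0, 0, 0, 0)
  cy <- c(5, 0, 0, 4, 3, 0, 0, 0, 0, 0)
  s_xy <- spatial_similarity(cx, cy, fraction = 0.3)
  expect_equal(s_xy, spatial_similarity(cy, cx, fraction = 0.3))  # equal sizes
  # union denominator variant (Jaccard)
  expect_equal(spatial_similarity(cx, cy, fraction = 0.3,
                                  denominator = "union"), 1 / 5)
})

test_that("intensity similarity matches hand-computed sums and the eps guard", {
  expect_equal(intensity_similarity(2, 1), 3.0)
  expect_equal(intensity_similarity(c(1, 3), c(2, 1)), 5.0)
  expect_equal(intensity_similarity(c(1, 1), c(1, 1)), 4e8)
})

test_that("hausdorff metric: identity, disjointness, symmetry, hand count", {
  set.seed(61)
  x <- abs(rnorm(40))
  expect_equal(hausdorff_metric(x, x), 1.0)

  a <- c(2, 2, 0, 0, rep(0.1, 6)); b <- c(0, 0, 2, 2, rep(0.1, 6))
  expect_equal(hausdorff_metric(a, b, fraction = 0.2), 0)

  # 2-voxel toy, one active voxel per map: the tie in y resolves to voxel 1
  # (index tie-break), so C = T = {1}, X = 2*min(2,1) = 2, Y = 2 + 1 = 3
  expect_equal(hausdorff_metric(c(2, 0), c(1, 1), fraction = 0.5), 2 / 3)

  y <- abs(rnorm(40))
  expect_equal(hausdorff_metric(x, y), hausdorff_metric(y, x))
  expect_gte(hausdorff_metric(x, y), 0)
  expect_lte(hausdorff_metric(x, y), 1)
  expect_warning(val <- hausdorff_metric(rep(0, 10), rep(0, 10)), "zero")
  expect_equal(val, 0)
})

test_that("hausdorff metric degrades monotonically with added noise", {
  set.seed(62)
  base <- abs(rnorm(500))
  mean_sim <- vapply(c(0, 0.5, 1, 2, 4), function(amp) {
    mean(vapply(1:20, function(i) {
      set.seed(1000 + i)
      hausdorff_metric(base + amp * abs(rnorm(500)), base)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sim) <= 0))
})

test_that("match_components equals exhaustive assignment", {
  mask <- cube_mask(3L)  # 27 voxels
  set.seed(63)
  # toy 2x2: the better diagonal wins
  tmpl2 <- spatial_map_set(matrix(abs(rnorm(54)), 2, 27), mask)
  res <- match_components(tmpl2, tmpl2, metric = "spatial")
  expect_equal(res$assignment, 1:2)
  expect_equal(unname(diag(res$values)), c(1, 1))

  # seeded 5 components x 4 templates vs brute force over all injections
  comps <- spatial_map_set(matrix(abs(rnorm(5 * 27)), 5, 27), mask)
  tmpls <- spatial_map_set(matrix(abs(rnorm(4 * 27)), 4, 27), mask)
  for (metric in c("spatial", "hausdorff", "intensity")) {
    res <- match_components(comps, tmpls, metric = metric)
    oracle <- exhaustive_assignment(res$values)
    expect_equal(res$total, oracle$total, tolerance = 1e-12)
    expect_equal(res$assignment, oracle$assignment)
  }
  expect_error(match_components(tmpls, comps), "at least as many")
})

test_that("hungarian solver matches exhaustive search on random instances", {
  for (i in 1:10) {
    set.seed(70 + i)
    v <- matrix(runif(6 * 4), 6, 4)
    oracle <- exhaustive_assignment(v)
    got <- delmar:::.hungarian(t(max(v) - v))
    expect_equal(sum(v[cbind(got, 1:4)]), oracle$total, tolerance = 1e-12)
  }
})

test_that("test_retest_matrix is diagonal-perfect for identical sessions", {
  mask <- cube_mask(3L)
  set.seed(64)
  maps <- spatial_map_set(matrix(abs(rnorm(4 * 27)), 4, 27), mask)
  res <- test_retest_matrix(maps, maps)
  expect_equal(res$matched, rep(1, 4))
  expect_equal(res$mean_matched, 1)
  expect_equal(dim(res$values), c(4L, 4L))
})

test_that("icc matches hand ANOVA on toy tables and detects no structure in noise", {
  # groups internally identical, groups differ -> 1
  tab <- matrix(c(1, 1, 3, 3, 5, 5), nrow = 3, byrow = TRUE)
  expect_equal(icc(tab), 1.0)

  # hand ANOVA oracle on a small unbalanced-free table
  tab2 <- matrix(c(1, 2, 4, 5, 8, 7), nrow = 3, byrow = TRUE)
  grand <- mean(tab2)
  msb <- 2 * sum((rowMeans(tab2) - grand)^2) / 2
  msw <- sum((tab2 - rowMeans(tab2))^2) / 3
  expect_equal(icc(tab2), (msb - msw) / (msb + msw), tolerance = 1e-12)

  # destroyed group structure: iid values give near-zero ICC
  set.seed(65)
  null_tab <- matrix(rnorm(40 * 5), 40, 5)
  expect_lte(abs(icc(null_tab)), 0.2)
  # and on average over replicates the null ICC is centred at ~0
  null_mean <- mean(vapply(1:200, function(i) {
    set.seed(300 + i)
    icc(matrix(rnorm(20 * 4), 20, 4))
  }, numeric(1)))
  expect_lte(abs(null_mean), 0.05)

  expect_error(icc(matrix(1:4, 1, 4)), "2 groups")
})

test_that("two-way icc variants run on a groups x raters layout", {
  set.seed(66)
  tab <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3) + rnorm(12, sd = 0.5)
  expect_gt(icc(tab, type = "twoway_consistency"), 0.9)
  expect_gt(icc(tab, type = "twoway_agreement"), 0.9)
})
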