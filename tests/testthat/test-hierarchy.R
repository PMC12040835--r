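test_that("single-echo denoising reduces exactly to a plain admm_layer call", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr, echo_times = 30)
  cfg <- admm_config(max_iter = 30)
  d1 <- denoise_first_layer(ds$signal, cfg, rank = 4)
  plain <- admm_layer(flatten_echoes(ds$signal), 4, cfg)
  expect_identical(d1$layer$Y, plain$Y)
  expect_identical(d1$features, plain$Y)
  expect_identical(d1$layer$X, plain$X)
})

test_that("noiseless multi-echo data is reconstructed almost exactly", {
  tr <- tiny_truth(snr = 0)
  tr$artifact_density <- 0
  ds <- make_multiecho_dataset(tr)
  d1 <- denoise_first_layer(ds$signal, admm_config(), rank = 6)
  expect_lte(layer_residual(d1$layer, flatten_echoes(ds$signal)), 1e-2)
})

test_that("explicit layer sizes are honoured and validated", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr)
  m <- fit_hierarchy(ds$signal, admm_config(max_iter = 30),
                     layer_sizes = c(8, 4, 2))
  expect_equal(m$layer_sizes, c(8L, 4L, 2L))
  expect_length(m$layers, 3L)
  expect_equal(m$denoise_layer_index, 1L)
  # layer k input dims equal layer k-1 feature dims
  expect_equal(nrow(m$layers[[2]]$X), 8L)
  expect_equal(nrow(m$layers[[3]]$X), 4L)
  expect_error(fit_hierarchy(ds$signal, layer_sizes = c(4, 4)),
               "decreasing")
})

test_that("automatic sizing gives strictly decreasing sizes and is deterministic", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr)
  m <- fit_hierarchy(ds$signal, admm_config(max_iter = 50))
  expect_gte(length(m$layer_sizes), 2L)
  expect_true(all(diff(m$layer_sizes) < 0))
  m2 <- fit_hierarchy(ds$signal, admm_config(max_iter = 50))
  expect_identical(lapply(m$layers, `[[`, "Y"), lapply(m2$layers, `[[`, "Y"))
})

test_that("layer_maps returns sign-fixed unit-peak maps per layer", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr)
  m <- fit_hierarchy(ds$signal, admm_config(max_iter = 30),
                     layer_sizes = c(6, 3))
  for (k in 1:2) {
    maps <- layer_maps(m, k)
    expect_equal(nrow(maps$maps), m$layer_sizes[k])
    expect_equal(ncol(maps$maps), tr$mask$n_voxels)
    expect_equal(unname(apply(maps$maps, 1, function(r) max(abs(r)))),
                 rep(1, nrow(maps$maps)))
    expect_true(all(apply(maps$maps, 1, max) > 0))  # peak is positive
  }
  expect_error(layer_maps(m, 5), "layer")
})

test_that("layer-wise residuals are recorded and converged fits respect tol", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr)
  cfg <- admm_config(max_iter = 100, tol = 1e-3)
  m <- fit_hierarchy(ds$signal, cfg, layer_sizes = c(6, 3))
  for (l in m$layers) {
    expect_gt(length(l$residual_history), 0L)
    if (l$converged)
      expect_lte(tail(l$residual_history, 1), cfg$tol)
  }
})

test_that("group averaging of identical subjects returns the matched maps", {
  mask <- tiny_mask()
  set.seed(81)
  ref <- spatial_map_set(matrix(abs(rnorm(3 * mask$n_voxels)), 3), mask)
  subj <- spatial_map_set(ref$maps[c(2, 3, 1), ], mask)  # permuted copies
  g1 <- group_average_bcns(list(subj), ref)
  expect_equal(unname(g1$maps), unname(ref$maps))

  # two subjects with maps a and b matched to one template -> (a+b)/2
  a <- abs(rnorm(mask$n_voxels)); b <- a + 0.1 * abs(rnorm(mask$n_voxels))
  s1 <- spatial_map_set(rbind(a), mask); s2 <- spatial_map_set(rbind(b), mask)
  ref1 <- spatial_map_set(rbind(a), mask)
  g2 <- group_average_bcns(list(s1, s2), ref1)
  expect_equal(as.numeric(g2$maps), (a + b) / 2)
  expect_error(group_average_bcns(list(), ref1), "at least one")
})

test_that("models serialize and reload losslessly", {
  tr <- tiny_truth()
  ds <- make_multiecho_dataset(tr)
  m <- fit_hierarchy(ds$signal, admm_config(max_iter = 20),
                     layer_sizes = c(5, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_equal(load_model(path), m)
})
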