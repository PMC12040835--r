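# automatic size for the noisy data layer: the weighted-ratio gap when one
# exists; otherwise the count of pivoted-QR diagonal entries above 1.5x the
# median — the median sits inside the thermal-noise plateau, so this counts
# components standing clear of the noise floor (the gapless fallback to the
# numerical rank would count the noise plateau itself)
.auto_rank_data <- function(smat, thresholds) {
  d <- qr_diagonal(smat)
  est <- rank_diagnostics(smat, thresholds)$estimated_rank
  if (est > min(dim(smat)) / 2) {
    est <- sum(d >= 1.5 * stats::median(d))
  }
  max(1L, min(as.integer(est), min(dim(smat))))
}

# automatic size for deeper layers: the feature matrices are small and
# essentially noise-free, so any detected gap is used; with no gap the size
# halves (geometric coarsening, mirroring the contraction of layer sizes
# reported for whole-brain hierarchies), always reducing by at least one
.auto_rank_deep <- function(y, d_prev, thresholds) {
  est <- estimate_rank(y, thresholds)
  if (est >= d_prev) est <- max(1L, d_prev %/% 2L)
  min(est, d_prev - 1L)
}

#' Multi-echo denoising first layer
#'
#' Runs [admm_layer()] on the echo-flattened signal (`T x (M * nTE)`), so the
#' low-rank part captures TE-coherent BOLD structure while the sparse
#' background absorbs TE-independent artifacts, then collapses the echo
#' blocks of the feature matrix to a single `D1 x M` spatial feature matrix
#' by a TE-weighted average (weights proportional to TE, the
#' BOLD-contrast-optimal combination). With a single echo this is exactly a
#' plain [admm_layer()] call and the collapse is the identity.
#'
#' @param signal a [multiecho_signal()].
#' @param config an [admm_config()].
#' @param rank number of first-layer components `D1`; `NULL` (default)
#'   estimates it with [estimate_rank()].
#' @param thresholds [rro_thresholds()] used when `rank` is `NULL`.
#' @return List with `layer` (the fitted [admm_layer()] object on the
#'   flattened matrix), `features` (`D1 x M`, echo-collapsed `Y`),
#'   `echo_weights` and `rank`.
#' @export
denoise_first_layer <- function(signal, config = admm_config(), rank = NULL,
                                thresholds = rro_thresholds()) {
  stopifnot(inherits(signal, "multiecho_signal"))
  smat <- flatten_echoes(signal)
  if (is.null(rank)) rank <- .auto_rank_data(smat, thresholds)
  layer <- admm_layer(smat, rank, config)
  n_te <- dim(signal$data)[3]
  m <- dim(signal$data)[2]
  w <- signal$echo_times / sum(signal$echo_times)
  feats <- matrix(0, rank, m)
  for (e in seq_len(n_te))
    feats <- feats + w[e] * layer$Y[, (e - 1L) * m + seq_len(m), drop = FALSE]
  list(layer = layer, features = feats, echo_weights = w, rank = rank)
}

#' Fit the full hierarchical decomposition
#'
#' Layer 1 is the multi-echo denoising layer ([denoise_first_layer()]); each
#' subsequent layer refactors the previous layer's spatial feature matrix
#' `Y[k-1]` (`D[k-1] x M`) with [admm_layer()]. Layer sizes come either from
#' an explicit strictly decreasing `layer_sizes` vector or automatically:
#' the first (data) layer uses the weighted-ratio gap of the pivoted QR
#' diagonal when one exists and otherwise counts the diagonal entries
#' standing clear of the thermal-noise plateau (1.5x its median); deeper
#' layers use any detected gap and otherwise halve the size. Every automatic
#' layer reduces the size by at least one (capped at `D[k-1] - 1`), and the
#' recursion ends once a rank-1 layer has been fitted.
#'
#' The rank gap demanded at the first (data) layer is stricter than at
#' deeper layers: the data carry thermal noise, so a clear spectral gap is
#' required before trusting a rank, whereas deeper inputs are small,
#' essentially noise-free factor matrices whose meaningful gaps are milder.
#'
#' @param signal a [multiecho_signal()].
#' @param config an [admm_config()].
#' @param layer_sizes optional explicit sizes `c(D1, D2, ...)`, strictly
#'   decreasing; `NULL` (default) for automatic sizing.
#' @param thresholds [rro_thresholds()] for the first (data) layer.
#' @param deep_thresholds [rro_thresholds()] for deeper feature matrices;
#'   default accepts a 2-fold one-step drop.
#' @param max_layers safety cap on the number of layers.
#' @return An object of class `hierarchical_model`: `layers` (list of
#'   [admm_layer()] fits; layer 1 additionally carries the echo-collapsed
#'   features), `layer_sizes`, `denoise_layer_index` (1), `mask`,
#'   `echo_times`, `echo_weights` and `config`.
#' @export
fit_hierarchy <- function(signal, config = admm_config(), layer_sizes = NULL,
                          thresholds = rro_thresholds(),
                          deep_thresholds = rro_thresholds(ratio_threshold = 2),
                          max_layers = 12L) {
  stopifnot(inherits(signal, "multiecho_signal"))
  auto <- is.null(layer_sizes)
  if (!auto) {
    layer_sizes <- as.integer(layer_sizes)
    if (length(layer_sizes) < 1L || any(layer_sizes < 1L))
      .stopf("layer_sizes must be positive integers")
    if (length(layer_sizes) > 1L && any(diff(layer_sizes) >= 0))
      .stopf("layer_sizes must be strictly decreasing")
  }

  d1 <- denoise_first_layer(signal, config,
                            rank = if (auto) NULL else layer_sizes[1],
                            thresholds = thresholds)
  layers <- list(c(d1$layer, list(features = d1$features)))
  class(layers[[1]]) <- "layer_decomposition"
  sizes <- d1$rank
  current <- d1$features

  k <- 2L
  while (k <= max_layers) {
    d_prev <- sizes[length(sizes)]
    if (d_prev <= 1L) break
    if (auto) {
      dk <- .auto_rank_deep(current, d_prev, deep_thresholds)
    } else {
      if (k > length(layer_sizes)) break
      dk <- layer_sizes[k]
    }
    layer <- admm_layer(current, dk, config)
    layers[[k]] <- layer
    sizes <- c(sizes, dk)
    current <- layer$Y
    if (auto && dk == 1L) break  # rank one: final layer
    k <- k + 1L
  }

  structure(list(layers = layers, layer_sizes = sizes,
                 denoise_layer_index = 1L, mask = signal$mask,
                 echo_times = signal$echo_times,
                 echo_weights = d1$echo_weights, config = config),
            class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf("<hierarchical_model> %d layer(s), sizes [%s]; layer 1 is the multi-echo denoiser\n",
              length(x$layers), paste(x$layer_sizes, collapse = ", ")))
  invisible(x)
}

#' Spatial maps of one layer
#'
#' Returns the rows of the layer's feature matrix as voxel maps (layer 1
#' uses the echo-collapsed features). Each map is sign-fixed so that its
#' largest-magnitude entry is positive and scaled to unit maximum, removing
#' the sign/scale ambiguity of the bilinear factorisation before metric
#' evaluation.
#'
#' @param model a [fit_hierarchy()] result.
#' @param layer layer index, `1 <= layer <= length(model$layers)`.
#' @return A [spatial_map_set()] with `layer_sizes[layer]` maps.
#' @export
layer_maps <- function(model, layer) {
  stopifnot(inherits(model, "hierarchical_model"))
  if (layer < 1L || layer > length(model$layers))
    .stopf("layer must be between 1 and %d", length(model$layers))
  y <- if (layer == 1L) model$layers[[1]]$features else model$layers[[layer]]$Y
  maps <- t(apply(y, 1, function(r) {
    peak <- r[which.max(abs(r))]
    if (peak < 0) r <- -r
    mx <- max(abs(r))
    if (mx > 0) r / mx else r
  }))
  spatial_map_set(maps, model$mask,
                  labels = sprintf("layer%d_bcn%d", layer, seq_len(nrow(maps))))
}

#' Group-wise average of best-matched subject maps
#'
#' For each reference template, selects every subject's best-matching map
#' (by optimal assignment under the named metric) and averages the selected
#' maps voxel-wise across subjects — the group-wise BCN construction.
#'
#' @param per_subject_maps non-empty list of [spatial_map_set()] objects, one
#'   per subject, all on the reference's mask.
#' @param reference a [spatial_map_set()] of templates, one per output map.
#' @param metric similarity metric name (see [match_components()]).
#' @param fraction binarization fraction.
#' @return A [spatial_map_set()] of group-average maps, one per template.
#' @export
group_average_bcns <- function(per_subject_maps, reference,
                               metric = "hausdorff", fraction = 0.05) {
  if (length(per_subject_maps) < 1L) .stopf("need at least one subject")
  stopifnot(inherits(reference, "spatial_map_set"))
  acc <- matrix(0, nrow(reference$maps), reference$mask$n_voxels)
  for (s in per_subject_maps) {
    res <- match_components(s, reference, metric = metric, fraction = fraction)
    acc <- acc + s$maps[res$assignment, , drop = FALSE]
  }
  spatial_map_set(acc / length(per_subject_maps), reference$mask,
                  labels = paste0("group_", reference$labels))
}

#' Save / load a fitted hierarchical model
#'
#' Serialises the full model (factors, sizes, configuration, mask) to a
#' single file using R's native RDS container.
#'
#' @param model a [fit_hierarchy()] result.
#' @param path output file path.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hierarchical_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hierarchical_model"))
    .stopf("'%s' does not contain a hierarchical model", path)
  model
}
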