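#' Brain mask with a fixed voxel ordering
#'
#' A `brain_mask` ties a 3D logical volume to a deterministic ordering of its
#' in-mask voxels: column-major (x fastest, then y, then z) array order, the
#' native scan order of R arrays. The ordering is the bijection between
#' in-mask 3D coordinates and the flat column indices used by every matrix in
#' the package, and is identical across calls and across loads of the same
#' file.
#'
#' @param volume 3D logical or numeric array; non-zero voxels are in-mask.
#' @param affine 4x4 voxel-to-world transform (default identity).
#' @return An object of class `brain_mask` with fields `dim` (3 spatial
#'   dimensions), `idx` (sorted flat indices of in-mask voxels), `n_voxels`
#'   and `affine`.
#' @export
brain_mask <- function(volume, affine = diag(4)) {
  if (length(dim(volume)) != 3L) .stopf("mask volume must be a 3D array")
  idx <- which(volume != 0)
  if (length(idx) < 1L) .stopf("mask is empty: no in-mask voxels")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) .stopf("affine must be a 4x4 matrix")
  structure(
    list(dim = dim(volume), idx = as.integer(idx),
         n_voxels = length(idx), affine = affine),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> grid %s, %d in-mask voxels\n",
              paste(x$dim, collapse = "x"), x$n_voxels))
  invisible(x)
}

#' Read a brain mask from a 3D NIfTI file
#'
#' @param path path to a 3D NIfTI volume; non-zero voxels are in-mask.
#' @return A [brain_mask()].
#' @export
mask_from_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  brain_mask(arr, affine = unclass(RNifti::xform(img)))
}

# vector of M in-mask values -> full 3D array (zeros outside the mask)
unflatten_map <- function(values, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(values) != mask$n_voxels)
    .stopf("map length %d != %d in-mask voxels", length(values), mask$n_voxels)
  vol <- array(0, dim = mask$dim)
  vol[mask$idx] <- values
  vol
}

# full 3D array -> vector of M in-mask values
flatten_map <- function(volume, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!all(dim(volume) == mask$dim)) .stopf("volume grid does not match mask grid")
  as.numeric(volume[mask$idx])
}

#' Multi-echo fMRI signal container
#'
#' Holds masked multi-echo fMRI data as a `T x M x nTE` numeric array
#' (time points x in-mask voxels x echoes) together with the echo times and
#' the mask that fixes the voxel ordering.
#'
#' @param data numeric array `T x M x nTE`; a `T x M` matrix is accepted for
#'   single-echo data.
#' @param echo_times echo times in ms, strictly increasing, one per echo.
#' @param mask a [brain_mask()] with `M` in-mask voxels.
#' @return An object of class `multiecho_signal`.
#' @export
multiecho_signal <- function(data, echo_times, mask) {
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) .stopf("data must be a T x M x nTE array")
  if (!all(is.finite(data))) .stopf("signal contains non-finite values")
  d <- dim(data)
  if (d[1] < 2L || d[2] < 2L) .stopf("need at least 2 time points and 2 voxels")
  if (length(echo_times) != d[3])
    .stopf("%d echo times given for %d echoes", length(echo_times), d[3])
  if (d[3] > 1L && any(diff(echo_times) <= 0))
    .stopf("echo_times must be strictly increasing")
  stopifnot(inherits(mask, "brain_mask"))
  if (mask$n_voxels != d[2])
    .stopf("mask has %d voxels but data has %d", mask$n_voxels, d[2])
  structure(list(data = data, echo_times = as.numeric(echo_times), mask = mask),
            class = "multiecho_signal")
}

#' @export
print.multiecho_signal <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multiecho_signal> %d time points, %d voxels, %d echo(es) [TE %s ms]\n",
              d[1], d[2], d[3], paste(x$echo_times, collapse = ", ")))
  invisible(x)
}

#' Load multi-echo fMRI from per-echo NIfTI series
#'
#' Reads one 4D NIfTI series per echo, applies the mask in fixed voxel order
#' and assembles the `T x M x nTE` signal array. All series must share the
#' spatial grid and number of volumes, and the mask must share the grid.
#'
#' @param nifti_paths_per_echo character vector of 4D NIfTI paths, one per
#'   echo, in the same order as `echo_times`.
#' @param mask_path path to the 3D brain-mask NIfTI.
#' @param echo_times echo times in ms, strictly increasing.
#' @return A [multiecho_signal()].
#' @export
load_multiecho <- function(nifti_paths_per_echo, mask_path, echo_times) {
  if (length(nifti_paths_per_echo) != length(echo_times))
    .stopf("%d echo series but %d echo times",
           length(nifti_paths_per_echo), length(echo_times))
  mask <- mask_from_nifti(mask_path)
  vols <- lapply(nifti_paths_per_echo, function(p) as.array(RNifti::readNifti(p)))
  dims <- vapply(vols, function(v) paste(dim(v), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L)
    .stopf("echo series have mismatched grids: %s", paste(dims, collapse = " vs "))
  d <- dim(vols[[1]])
  if (length(d) != 4L) .stopf("each echo series must be a 4D NIfTI")
  if (!all(d[1:3] == mask$dim)) .stopf("mask grid does not match fMRI grid")
  n_t <- d[4]
  dat <- array(0, dim = c(n_t, mask$n_voxels, length(vols)))
  for (e in seq_along(vols)) {
    v <- matrix(vols[[e]], nrow = prod(d[1:3]), ncol = n_t)
    dat[, , e] <- t(v[mask$idx, , drop = FALSE])
  }
  multiecho_signal(dat, echo_times, mask)
}

#' Flatten the echo dimension into column blocks
#'
#' Returns the `T x (M * nTE)` matrix whose column block `e` holds echo `e`'s
#' voxels in mask order (echo is the slowest-varying block). The inverse
#' operation is [unflatten_echoes()].
#'
#' @param signal a [multiecho_signal()].
#' @return A `T x (M * nTE)` matrix.
#' @export
flatten_echoes <- function(signal) {
  stopifnot(inherits(signal, "multiecho_signal"))
  d <- dim(signal$data)
  matrix(signal$data, nrow = d[1], ncol = d[2] * d[3])
}

#' Inverse of [flatten_echoes()]
#'
#' @param mat a `T x (M * nTE)` matrix with echoes as the slowest column block.
#' @param n_echoes number of echoes.
#' @return A `T x M x nTE` array.
#' @export
unflatten_echoes <- function(mat, n_echoes) {
  if (ncol(mat) %% n_echoes != 0L)
    .stopf("%d columns not divisible by %d echoes", ncol(mat), n_echoes)
  array(mat, dim = c(nrow(mat), ncol(mat) %/% n_echoes, n_echoes))
}

#' Labelled collection of voxel-wise network maps
#'
#' @param maps `D x M` numeric matrix; each row is one spatial map over the
#'   in-mask voxels.
#' @param mask a [brain_mask()] with `M` voxels.
#' @param labels character vector of `D` labels (default `map_1 ...`).
#' @return An object of class `spatial_map_set`.
#' @export
spatial_map_set <- function(maps, mask, labels = NULL) {
  maps <- rbind(maps)  # promote a single vector to a 1-row matrix
  stopifnot(inherits(mask, "brain_mask"))
  if (ncol(maps) != mask$n_voxels)
    .stopf("maps have %d columns but mask has %d voxels", ncol(maps), mask$n_voxels)
  if (!all(is.finite(maps))) .stopf("maps contain non-finite values")
  if (is.null(labels)) labels <- paste0("map_", seq_len(nrow(maps)))
  if (length(labels) != nrow(maps)) .stopf("need one label per map")
  structure(list(maps = unname(as.matrix(maps)), labels = as.character(labels),
                 mask = mask),
            class = "spatial_map_set")
}

#' @export
print.spatial_map_set <- function(x, ...) {
  cat(sprintf("<spatial_map_set> %d map(s) over %d voxels\n",
              nrow(x$maps), x$mask$n_voxels))
  invisible(x)
}

#' Write spatial maps as 3D NIfTI volumes
#'
#' One file per map, named after its label; out-of-mask voxels are zero and
#' the mask affine is preserved. Data are stored as 64-bit floats so that a
#' save/load round trip reproduces the values.
#'
#' @param maps a [spatial_map_set()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
save_maps <- function(maps, out_dir) {
  stopifnot(inherits(maps, "spatial_map_set"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      .stopf("cannot create output directory '%s'", out_dir)
  paths <- file.path(out_dir, paste0(maps$labels, ".nii.gz"))
  for (i in seq_len(nrow(maps$maps))) {
    vol <- unflatten_map(maps$maps[i, ], maps$mask)
    img <- RNifti::asNifti(vol, datatype = "double")
    img <- RNifti::`sform<-`(img, structure(maps$mask$affine, code = 2L))
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read spatial maps written by [save_maps()]
#'
#' @param paths NIfTI file paths, one 3D volume per map.
#' @param mask the [brain_mask()] the maps are tied to.
#' @param labels optional labels (default: file names without extension).
#' @return A [spatial_map_set()].
#' @export
load_maps <- function(paths, mask, labels = NULL) {
  if (is.null(labels)) labels <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  maps <- t(vapply(paths, function(p) {
    flatten_map(as.array(RNifti::readNifti(p)), mask)
  }, numeric(mask$n_voxels)))
  spatial_map_set(maps, mask, labels)
}
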