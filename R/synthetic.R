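#' Spherical brain mask on a cubic grid
#'
#' @param dim 3-vector of grid dimensions.
#' @param radius sphere radius in voxels (default just under half the grid,
#'   giving roughly 8000 voxels on the default 27-cube).
#' @return A [brain_mask()].
#' @export
make_mask <- function(dim = c(27L, 27L, 27L), radius = 12.4) {
  ctr <- (dim + 1) / 2
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  brain_mask(array(d2 <= radius^2, dim = dim))
}

# in-mask voxel coordinates as an M x 3 matrix, in mask order
.mask_coords <- function(mask) {
  idx <- mask$idx - 1L
  d <- mask$dim
  cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2])) + 1L
}

# smooth AR(1) series, mutually orthogonalised (QR) and scaled to unit
# standard deviation: planted time courses with no chance cross-correlation
.draw_timecourses <- function(n_time, n, ar_coef) {
  raw <- vapply(seq_len(n), function(i) {
    x <- stats::filter(stats::rnorm(n_time + 50L), ar_coef,
                       method = "recursive")
    as.numeric(x[-seq_len(50L)])
  }, numeric(n_time))
  qr.Q(qr(raw)) * sqrt(n_time)
}

# row-normalized 1D Gaussian smoothing operator for one grid axis
.smooth_operator <- function(n, sigma) {
  idx <- seq_len(n)
  k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  k[abs(outer(idx, idx, "-")) > ceiling(3 * sigma)] <- 0
  k / rowSums(k)
}

# separable 3D Gaussian smoothing of every volume in a grid x time array
# (dims nx, ny, nz, T), emulating the preprocessing smoothing kernel
.smooth_volumes <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    k <- .smooth_operator(d[ax], sigma)
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    dp <- dim(a)
    a <- k %*% matrix(a, nrow = dp[1])
    arr <- aperm(array(a, dp), order(perm))
  }
  arr
}

# truncated Gaussian blob rendered over the in-mask voxels (unit peak)
.render_blob <- function(coords, center, radius) {
  d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
    (coords[, 3] - center[3])^2
  sigma2 <- (radius / 2)^2
  v <- exp(-d2 / (2 * sigma2))
  v[d2 > radius^2] <- 0
  v
}

#' Planted canonical network templates
#'
#' Places `n_canonical` smooth compact blobs (truncated Gaussians, unit
#' peak) at seeded random in-mask locations with a controlled pairwise
#' overlap: `overlap_fraction = 0` forces disjoint supports (centres at
#' least two radii apart), larger values allow proportionally closer
#' centres.
#'
#' @param n_canonical number of templates, at least 2.
#' @param mask a [brain_mask()].
#' @param overlap_fraction allowed overlap in `[0, 1)`; 0 means disjoint.
#' @param seed integer seed.
#' @param blob_radius blob truncation radius in voxels.
#' @return `n_canonical x M` matrix of unit-peak maps.
#' @export
make_templates <- function(n_canonical, mask, overlap_fraction = 0.25,
                           seed = 1L, blob_radius = 5) {
  if (n_canonical < 2L) .stopf("need at least 2 templates")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    .stopf("overlap_fraction must be in [0, 1)")
  coords <- .mask_coords(mask)
  min_dist <- 2 * blob_radius * (1 - overlap_fraction)
  centers <- .with_seed(seed, {
    chosen <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(chosen) < n_canonical) {
      tries <- tries + 1L
      if (tries > 5000L)
        .stopf("mask too small to place %d blobs of radius %g at overlap %g",
               n_canonical, blob_radius, overlap_fraction)
      cand <- coords[sample.int(nrow(coords), 1L), ]
      if (nrow(chosen) == 0 ||
          all(sqrt(rowSums((chosen - rep(cand, each = nrow(chosen)))^2)) >= min_dist))
        chosen <- rbind(chosen, cand)
    }
    chosen
  })
  maps <- t(apply(centers, 1, function(ctr) {
    v <- .render_blob(coords, ctr, blob_radius)
    if (max(v) == 0) .stopf("degenerate blob placement")
    v / max(v)
  }))
  maps
}

#' Synthetic ground truth with a planted two-level network hierarchy
#'
#' Builds the generative model behind [make_multiecho_dataset()]:
#' `n_canonical` canonical networks grouped into `n_meta` meta-networks.
#' Each canonical map is a compact blob plus a co-activation bridge (weight
#' `backbone_strength`) into each sibling blob of its meta-group, so
#' networks of one group recruit each other's territory — the spatial
#' signature that deeper decomposition layers recover as meta-networks —
#' while networks of different groups stay spatially disjoint.
#' Meta-network templates are
#' nonnegative combinations of at least three canonical member maps, with
#' seeded Dirichlet-jittered weights proportional to the members' squared
#' amplitudes. Canonical time courses are smooth AR(1) series, mutually
#' orthogonalised so that no chance temporal correlation couples networks;
#' BOLD amplitude is exactly linear in TE through zero (`te_slopes`);
#' thermal noise is TE-independent Gaussian, plus a TE-independent sparse
#' large-amplitude artifact matrix shared across echoes.
#'
#' `snr` is the ratio of the clean BOLD signal's standard deviation over the
#' network-covered voxels (at the mean echo time) to the thermal noise
#' standard deviation — an active-region SNR, the scale on which multi-echo
#' BOLD sensitivity is usually quoted.
#'
#' @param mask a [brain_mask()]; default [make_mask()] (about 8000 voxels).
#' @param n_canonical number of canonical networks (default 12).
#' @param n_meta number of meta-networks (default 4); requires
#'   `n_canonical >= 3 * n_meta`.
#' @param n_time number of time points (default 200).
#' @param echo_times echo times in ms (default the 11/30/49 ms of a typical
#'   3-echo MBME acquisition).
#' @param snr active-region signal-to-noise ratio (default 2).
#' @param artifact_density fraction of entries carrying sparse artifacts.
#' @param artifact_amplitude artifact magnitude in noise-SD units.
#' @param backbone_strength weight of the co-activation bridge a canonical
#'   network extends into each sibling network's blob.
#' @param amp_spread geometric ratio between successive steps of the global
#'   per-network amplitude ladder (interleaved across groups, so each group
#'   holds a weak, a mid and a strong member); values above 1 separate the
#'   networks' spectral weights so they are individually identifiable.
#' @param blob_radius blob truncation radius in voxels.
#' @param ar_coef AR(1) coefficient of the time courses.
#' @param smooth_fwhm_vox FWHM (in voxels) of the Gaussian kernel applied to
#'   every acquired volume, emulating the spatial smoothing step of standard
#'   fMRI preprocessing (4 mm at 3 mm voxels by default); `snr` refers to
#'   the data before smoothing, as it does at the scanner. Set to 0 for raw
#'   unsmoothed volumes.
#' @param seed integer seed; regeneration with the same seed is bitwise
#'   identical.
#' @return An object of class `synthetic_truth` with fields `templates`
#'   (`n_canonical x M`, unit peak), `meta_mixing` (`n_meta x n_canonical`),
#'   `meta_templates`, `groups`, `timecourses` (`n_time x n_canonical`),
#'   `te_slopes`, `noise_sigma`, `artifact_density`, `artifact_amplitude`,
#'   `mask`, `echo_times`, `snr` and `seed`.
#' @export
synthetic_truth <- function(mask = make_mask(), n_canonical = 12L,
                            n_meta = 4L, n_time = 200L,
                            echo_times = c(11, 30, 49), snr = 2,
                            artifact_density = 0.005,
                            artifact_amplitude = 4,
                            backbone_strength = 0.15, amp_spread = 1.18,
                            blob_radius = NULL,
                            ar_coef = 0.6, smooth_fwhm_vox = 4 / 3,
                            seed = 7L) {
  if (n_canonical < 3L * n_meta)
    .stopf("need n_canonical >= 3 * n_meta so each meta-network combines >= 3 networks")
  coords <- .mask_coords(mask)
  m <- mask$n_voxels
  # the default radius scales with the mask; each template's support (own
  # blob plus sibling bridges) then stays above the top-5% active-set size
  scale_r <- (m / 8000)^(1 / 3)
  if (is.null(blob_radius)) blob_radius <- 4.2 * scale_r

  out <- .with_seed(seed, {
    groups <- rep(seq_len(n_meta), length.out = n_canonical)
    groups <- sort(groups)

    # one compact blob per canonical network, packed over the whole mask by
    # greedy maximin (farthest-point) placement over interior voxels
    ctr <- colMeans(coords)
    r_in <- sqrt(max(rowSums((coords - rep(ctr, each = m))^2)))
    interior <- which(sqrt(rowSums((coords - rep(ctr, each = m))^2)) <=
                        r_in - 0.45 * blob_radius)
    bc <- matrix(0, n_canonical, 3)
    bc[1, ] <- coords[sample(interior, 1L), ]
    if (n_canonical > 1L) for (i in 2L:n_canonical) {
      dmin <- rep(Inf, length(interior))
      for (h in seq_len(i - 1L))
        dmin <- pmin(dmin, rowSums((coords[interior, , drop = FALSE] -
                                      rep(bc[h, ], each = length(interior)))^2))
      bc[i, ] <- coords[interior[which.max(dmin)], ]
    }
    blobs <- t(apply(bc, 1, function(p) {
      v <- .render_blob(coords, p, blob_radius)
      v / max(v)
    }))

    # canonical map = own blob + a co-activation bridge into each sibling
    # blob of its meta-group: networks of one group recruit each other's
    # territory, the spatial signature that deep layers recover as the
    # meta-network, while networks of different groups stay disjoint
    templates <- matrix(0, n_canonical, m)
    for (i in seq_len(n_canonical)) {
      sib <- setdiff(which(groups == groups[i]), i)
      v <- blobs[i, ] + backbone_strength * colSums(blobs[sib, , drop = FALSE])
      templates[i, ] <- v / max(v)
    }

    # group union maps (diagnostic view of each meta-group's territory)
    backbones <- t(vapply(seq_len(n_meta), function(g) {
      v <- colSums(blobs[groups == g, , drop = FALSE])
      v / max(v)
    }, numeric(m)))

    # per-network BOLD amplitude: a single geometric ladder over all
    # networks, interleaved across groups (each group holds a weak, a mid
    # and a strong member). Distinct spectral weights make the networks
    # individually identifiable to a low-rank decomposition; without them
    # near-tied components mix arbitrarily.
    ladder_rank <- integer(n_canonical)
    for (g in seq_len(n_meta)) {
      members <- which(groups == g)
      ladder_rank[members] <- (seq_along(members) - 1L) * n_meta + g
    }
    amps <- amp_spread^(ladder_rank - 1)
    te_slopes <- amps / mean(echo_times)

    # meta-network weights: seeded Dirichlet-style jitter around weights
    # proportional to the squared member amplitudes — constituents contribute
    # in proportion to their signal power, as they do in the data
    meta_mixing <- matrix(0, n_meta, n_canonical)
    for (g in seq_len(n_meta)) {
      members <- which(groups == g)
      w <- amps[members]^2 * stats::rgamma(length(members), shape = 20)
      meta_mixing[g, members] <- w / sum(w)
    }
    meta_templates <- meta_mixing %*% templates
    meta_templates <- meta_templates / apply(meta_templates, 1, max)

    tc <- .draw_timecourses(n_time, n_canonical, ar_coef)

    clean_ref <- tc %*% ((te_slopes * mean(echo_times)) * templates)
    active <- colSums(abs(templates)) > 0
    noise_sigma <- if (snr > 0) stats::sd(clean_ref[, active]) / snr else 0

    list(groups = groups, templates = templates, backbones = backbones,
         meta_mixing = meta_mixing, meta_templates = meta_templates,
         timecourses = tc, te_slopes = te_slopes, noise_sigma = noise_sigma)
  })

  structure(c(out, list(mask = mask, echo_times = as.numeric(echo_times),
                        snr = snr, artifact_density = artifact_density,
                        artifact_amplitude = artifact_amplitude,
                        n_canonical = as.integer(n_canonical),
                        n_meta = as.integer(n_meta),
                        n_time = as.integer(n_time),
                        blob_radius = blob_radius,
                        backbone_strength = backbone_strength,
                        amp_spread = amp_spread,
                        smooth_fwhm_vox = smooth_fwhm_vox,
                        ar_coef = ar_coef, seed = as.integer(seed))),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d canonical networks in %d meta-groups, %d time points, %d voxels, SNR %g, seed %d\n",
              x$n_canonical, x$n_meta, x$n_time, x$mask$n_voxels, x$snr, x$seed))
  invisible(x)
}

#' Generate a multi-echo dataset from planted ground truth
#'
#' `data[t, v, e] = sum_n timecourses[t, n] * te_slopes[n] * TE[e] *
#' templates[n, v]` plus a sparse TE-independent artifact matrix (shared
#' across echoes) and TE-independent Gaussian thermal noise (independent
#' draws per echo).
#'
#' @param truth a [synthetic_truth()].
#' @param echo_times echo times in ms (default the truth's).
#' @param session_seed optional seed for an independent session: new time
#'   courses, artifacts and noise are drawn while templates, mixing and
#'   slopes are shared. `NULL` (default) uses the truth's own time courses
#'   and a noise stream derived from the truth seed.
#' @return List with `signal` (a [multiecho_signal()]) and `truth`
#'   (untouched, except that a session's regenerated time courses are
#'   reported in `session_timecourses`).
#' @export
make_multiecho_dataset <- function(truth, echo_times = truth$echo_times,
                                   session_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_te <- length(echo_times)
  if (n_te < 1L) .stopf("need at least one echo time")
  n_t <- truth$n_time
  m <- truth$mask$n_voxels

  draw_seed <- if (is.null(session_seed)) truth$seed + 1000L
               else as.integer(session_seed)
  gen <- .with_seed(draw_seed, {
    tc <- if (is.null(session_seed)) truth$timecourses else
      .draw_timecourses(n_t, truth$n_canonical, truth$ar_coef)
    art <- matrix(0, n_t, m)
    n_art <- round(truth$artifact_density * n_t * m)
    if (n_art > 0 && truth$noise_sigma > 0) {
      pos <- sample.int(n_t * m, n_art)
      art[pos] <- sample(c(-1, 1), n_art, replace = TRUE) *
        truth$artifact_amplitude * truth$noise_sigma
    }
    noise <- if (truth$noise_sigma > 0)
      array(stats::rnorm(n_t * m * n_te, 0, truth$noise_sigma),
            dim = c(n_t, m, n_te))
    else array(0, dim = c(n_t, m, n_te))
    list(tc = tc, art = art, noise = noise)
  })

  dat <- array(0, dim = c(n_t, m, n_te))
  sigma_vox <- truth$smooth_fwhm_vox / 2.355
  for (e in seq_len(n_te)) {
    amp <- truth$te_slopes * echo_times[e]
    slab <- gen$tc %*% (amp * truth$templates) + gen$art + gen$noise[, , e]
    if (sigma_vox > 0) {
      # emulate the preprocessing smoothing kernel on the acquired volumes
      vol <- array(0, dim = c(truth$mask$dim, n_t))
      flat <- matrix(vol, nrow = prod(truth$mask$dim))
      flat[truth$mask$idx, ] <- t(slab)
      vol <- .smooth_volumes(array(flat, dim = c(truth$mask$dim, n_t)),
                             sigma_vox)
      slab <- t(matrix(vol, nrow = prod(truth$mask$dim))[truth$mask$idx, ])
    }
    dat[, , e] <- slab
  }
  truth$session_timecourses <- if (is.null(session_seed)) NULL else gen$tc
  list(signal = multiecho_signal(dat, echo_times, truth$mask), truth = truth)
}

#' Two independent sessions sharing one ground truth
#'
#' Test-retest analogue: templates, meta-mixing and TE slopes are shared;
#' time courses, artifacts and noise are drawn independently per session.
#'
#' @param truth a [synthetic_truth()].
#' @param echo_times echo times in ms (default the truth's).
#' @param seed_pair two distinct integer seeds, one per session.
#' @return List of two [make_multiecho_dataset()] results.
#' @export
make_two_sessions <- function(truth, echo_times = truth$echo_times,
                              seed_pair = c(101L, 202L)) {
  if (length(seed_pair) != 2L || seed_pair[1] == seed_pair[2])
    .stopf("seed_pair must contain two distinct seeds")
  lapply(seed_pair, function(s)
    make_multiecho_dataset(truth, echo_times, session_seed = s))
}
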