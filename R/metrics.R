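#' Top-fraction binarization of a voxel map
#'
#' Returns the indices of the `ceiling(fraction * M)` voxels of largest
#' intensity. Ties at the threshold are broken deterministically by voxel
#' index (lower index wins).
#'
#' @param map numeric vector of voxel intensities.
#' @param fraction fraction of voxels to keep, in (0, 1]; default 0.05
#'   (the top 5 percent).
#' @return Integer vector of active voxel indices (unsorted set, in
#'   decreasing-intensity order).
#' @export
binarize_top_fraction <- function(map, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    .stopf("fraction must be in (0, 1]")
  n <- ceiling(fraction * length(map))
  order(map, decreasing = TRUE)[seq_len(n)]  # stable sort: index breaks ties
}

#' Spatial similarity of two maps after top-fraction binarization
#'
#' `|binarize(component) intersect binarize(template)| / |binarize(template)|`.
#' The template active set is the denominator, so the measure is not
#' symmetric in its arguments. A Jaccard variant (union denominator) is
#' available via `denominator = "union"`.
#'
#' @param component_map,template_map numeric voxel vectors on the same mask.
#' @param fraction binarization fraction, default 0.05.
#' @param denominator `"template"` (default) or `"union"`.
#' @return Value in \[0, 1\].
#' @export
spatial_similarity <- function(component_map, template_map, fraction = 0.05,
                               denominator = c("template", "union")) {
  denominator <- match.arg(denominator)
  if (length(component_map) != length(template_map))
    .stopf("maps must share a mask (equal length)")
  comp <- binarize_top_fraction(component_map, fraction)
  tmpl <- binarize_top_fraction(template_map, fraction)
  if (length(tmpl) == 0L) .stopf("template active set is empty")
  inter <- length(intersect(comp, tmpl))
  den <- switch(denominator,
                template = length(tmpl),
                union = length(union(comp, tmpl)))
  inter / den
}

#' Intensity similarity of two maps
#'
#' `sum((|x_i| + |y_i|) / max(|x_i - y_i|, eps))`: large where the maps agree
#' in intensity, unbounded above (the `eps` guard keeps identical maps at a
#' large finite value instead of infinity).
#'
#' @param component_map,template_map numeric voxel vectors on the same mask.
#' @param eps guard for the denominator, default `1e-8`.
#' @return Nonnegative scalar.
#' @export
intensity_similarity <- function(component_map, template_map, eps = 1e-8) {
  if (length(component_map) != length(template_map))
    .stopf("maps must share a mask (equal length)")
  sum((abs(component_map) + abs(template_map)) /
        pmax(abs(component_map - template_map), eps))
}

#' Intensity-weighted Hausdorff overlap of two maps
#'
#' Not the classical point-set Hausdorff distance: with active sets `C` and
#' `T` from [binarize_top_fraction()], returns
#' `X / Y` where `X = sum over C & T of 2 * min(x_i, y_i)` and
#' `Y = sum over C | T of (x_i + y_i)`. Equal to 1 iff the maps coincide on
#' a common active set, 0 for disjoint active sets; symmetric in its
#' arguments. Maps are expected nonnegative (sign-fix upstream, e.g. via
#' [layer_maps()]); negative intensities are clamped to 0 so that the value
#' stays in \[0, 1\].
#'
#' @param component_map,template_map numeric voxel vectors on the same mask.
#' @param fraction binarization fraction, default 0.05.
#' @return Value in \[0, 1\]; 0 with a warning if both maps vanish on the
#'   union of the active sets.
#' @export
hausdorff_metric <- function(component_map, template_map, fraction = 0.05) {
  if (length(component_map) != length(template_map))
    .stopf("maps must share a mask (equal length)")
  x <- pmax(component_map, 0)
  y <- pmax(template_map, 0)
  comp <- binarize_top_fraction(component_map, fraction)
  tmpl <- binarize_top_fraction(template_map, fraction)
  both <- intersect(comp, tmpl)
  either <- union(comp, tmpl)
  X <- if (length(both)) sum(2 * pmin(x[both], y[both])) else 0
  Y <- sum(x[either] + y[either])
  if (Y == 0) {
    warning("both maps are zero on the union of active sets; returning 0")
    return(0)
  }
  X / Y
}

# similarity between two map vectors under a named metric
.map_similarity <- function(metric, x, y, fraction) {
  switch(metric,
         spatial = spatial_similarity(x, y, fraction),
         intensity = intensity_similarity(x, y),
         hausdorff = hausdorff_metric(x, y, fraction),
         pearson = abs(stats::cor(x, y)),
         .stopf("unknown metric '%s'", metric))
}

# Hungarian algorithm (shortest augmenting paths with potentials):
# minimise sum(cost[i, match[i]]) over injective matchings,
# nrow(cost) <= ncol(cost). Returns the matched column for each row.
.hungarian <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc)
  INF <- .Machine$double.xmax / 4
  u <- numeric(nr + 1L)
  v <- numeric(nc + 1L)
  p <- integer(nc + 1L)   # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(nc + 1L) # way[j + 1]: previous column on the augmenting path
  for (i in seq_len(nr)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, nc + 1L)
    used <- rep(FALSE, nc + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(nc)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0L:nc) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(nr)
  for (j in seq_len(nc)) if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
  match
}

#' Match components to templates by optimal assignment
#'
#' Computes the full component-by-template similarity matrix under the named
#' metric and the injective assignment of one component per template that
#' maximises the total similarity (Hungarian algorithm; exact, equals
#' exhaustive enumeration).
#'
#' @param components,templates [spatial_map_set()] objects on the same mask;
#'   `components` must have at least as many maps as `templates`.
#' @param metric `"spatial"`, `"intensity"`, `"hausdorff"` or `"pearson"`.
#' @param fraction binarization fraction for the set-based metrics.
#' @return An object of class `similarity_matrix`: `values`
#'   (components x templates), `metric_name`, `assignment` (component index
#'   chosen for each template), `matched` (the assigned similarity per
#'   template) and `total`.
#' @export
match_components <- function(components, templates,
                             metric = c("spatial", "hausdorff", "intensity",
                                        "pearson"),
                             fraction = 0.05) {
  metric <- match.arg(metric)
  stopifnot(inherits(components, "spatial_map_set"),
            inherits(templates, "spatial_map_set"))
  if (components$mask$n_voxels != templates$mask$n_voxels)
    .stopf("components and templates must share a mask")
  nc_ <- nrow(components$maps); nt <- nrow(templates$maps)
  if (nc_ < nt) .stopf("need at least as many components (%d) as templates (%d)",
                       nc_, nt)
  values <- matrix(0, nc_, nt,
                   dimnames = list(components$labels, templates$labels))
  for (i in seq_len(nc_)) for (j in seq_len(nt))
    values[i, j] <- .map_similarity(metric, components$maps[i, ],
                                    templates$maps[j, ], fraction)
  # maximise total similarity: minimise (max - values), templates as rows
  cost <- t(max(values) - values)
  assignment <- .hungarian(cost)
  matched <- values[cbind(assignment, seq_len(nt))]
  structure(list(values = values, metric_name = metric,
                 assignment = assignment, matched = matched,
                 total = sum(matched)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d component(s) x %d template(s), metric '%s', mean matched %.3f\n",
              nrow(x$values), ncol(x$values), x$metric_name, mean(x$matched)))
  invisible(x)
}

#' Test-retest similarity matrix of two sessions' maps
#'
#' Matches the second session's maps to the first session's (treated as the
#' reference) and returns the full cross-session similarity matrix, the
#' matched pairs and their mean — the session-level reproducibility summary.
#'
#' @param session1,session2 [spatial_map_set()] objects on the same mask.
#' @param metric similarity metric, default `"hausdorff"`.
#' @param fraction binarization fraction.
#' @return A `similarity_matrix` (see [match_components()]) with an extra
#'   field `mean_matched`.
#' @export
test_retest_matrix <- function(session1, session2, metric = "hausdorff",
                               fraction = 0.05) {
  res <- match_components(session2, session1, metric = metric,
                          fraction = fraction)
  res$mean_matched <- mean(res$matched)
  res
}

#' Intraclass correlation coefficient
#'
#' One-way random-effects ICC(1,1):
#' `(MSB - MSW) / (MSB + (k - 1) * MSW)` with between/within mean squares
#' from a one-way ANOVA of value on group and `k` the (mean) group size.
#' Two-way variants on a groups x raters layout are available:
#' `"twoway_agreement"` (ICC(2,1)) and `"twoway_consistency"` (ICC(3,1)).
#'
#' @param measurements either a numeric matrix (rows = groups, columns =
#'   repeated measurements) or a data frame with columns `group` and `value`
#'   (and `rater` for the two-way variants).
#' @param type ICC variant, default `"oneway"`.
#' @return Scalar in (-1, 1]; 1 when within-group variance is 0.
#' @export
icc <- function(measurements, type = c("oneway", "twoway_agreement",
                                       "twoway_consistency")) {
  type <- match.arg(type)
  if (is.matrix(measurements)) {
    measurements <- data.frame(
      group = factor(rep(seq_len(nrow(measurements)), ncol(measurements))),
      rater = factor(rep(seq_len(ncol(measurements)),
                         each = nrow(measurements))),
      value = as.numeric(measurements))
  }
  df <- measurements
  if (!all(c("group", "value") %in% names(df)))
    .stopf("measurements need columns 'group' and 'value'")
  df$group <- factor(df$group)
  g <- nlevels(df$group)
  if (g < 2L) .stopf("need at least 2 groups")
  sizes <- table(df$group)
  if (any(sizes < 2L)) .stopf("need at least 2 measurements per group")
  n <- nrow(df)

  if (type == "oneway") {
    # suppress the F-test warning on zero-residual (perfect) fits; only the
    # mean squares are used
    a <- suppressWarnings(stats::anova(stats::lm(value ~ group, data = df)))
    msb <- a["group", "Mean Sq"]
    msw <- a["Residuals", "Mean Sq"]
    # balanced: k = common group size; unbalanced: standard n0 correction
    k <- (n - sum(sizes^2) / n) / (g - 1)
    if (msw == 0 && msb == 0) return(0)
    return((msb - msw) / (msb + (k - 1) * msw))
  }

  if (!"rater" %in% names(df))
    .stopf("two-way ICC variants need a 'rater' column")
  df$rater <- factor(df$rater)
  k <- nlevels(df$rater)
  a <- suppressWarnings(stats::anova(stats::lm(value ~ group + rater,
                                               data = df)))
  msr <- a["group", "Mean Sq"]       # rows (targets)
  msc <- a["rater", "Mean Sq"]       # columns (raters)
  mse <- a["Residuals", "Mean Sq"]
  if (type == "twoway_consistency")
    (msr - mse) / (msr + (k - 1) * mse)
  else
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / g)
}
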