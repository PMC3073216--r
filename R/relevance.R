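#' Distance map from every block to an example block
#'
#' For one feature and one metric, computes the per-block distance to the
#' example's histogram over the whole grid. The example block's own cell is
#' exactly 0.
#'
#' @param features a `grid_features` object from [characterize_grid()].
#' @param example a `block_features` object (typically `features_at()` of the
#'   target or distractor block).
#' @param feature one of [feature_ids()].
#' @param metric one of [metric_ids()].
#' @return numeric `n_rows x n_cols` matrix of distances (attribute
#'   `kind = "distance"`).
#' @export
build_distance_map <- function(features, example, feature, metric) {
  feature <- match.arg(feature, feature_ids())
  metric <- match.arg(metric, metric_ids())
  grid <- attr(features, "grid")
  ex_h <- example[[feature]]
  m <- matrix(0, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      m[r + 1L, cc + 1L] <-
        hist_distance(features[[r * grid$n_cols + cc + 1L]][[feature]],
                      ex_h, metric)
    }
  }
  attr(m, "kind") <- "distance"
  m
}

#' Reassign the global minimum of a distance map to the second minimum
#'
#' The example block always sits at distance 0 of itself; left as is, it
#' would dominate the normalized map. Every cell equal to the global minimum
#' is raised to the smallest strictly larger value. A constant map is
#' returned unchanged.
#'
#' @param map numeric matrix (distance map) with at least 2 cells.
#' @return matrix of the same shape.
#' @export
reassign_zero_minimum <- function(map) {
  if (length(map) < 2L)
    stop("map must have at least 2 cells", call. = FALSE)
  mn <- min(map)
  larger <- map[map > mn]
  if (length(larger) == 0L) return(map)  # constant map
  map[map == mn] <- min(larger)
  map
}

#' Invert a distance map into a similarity map on [0, N_scale]
#'
#' Affine inversion `N_scale * (d_max - d) / (d_max - d_min)`: the maximum
#' distance maps to 0 and the minimum distance to `N_scale`, so large values
#' mark blocks similar to the example. A constant map (degenerate range) maps
#' to all zeros.
#'
#' @param map numeric distance map (after [reassign_zero_minimum()]).
#' @param N_scale upper end of the similarity scale (default 1).
#' @return similarity matrix in `[0, N_scale]` (attribute
#'   `kind = "similarity"`).
#' @export
normalize_to_similarity <- function(map, N_scale = 1) {
  rng <- max(map) - min(map)
  out <- if (rng == 0) {
    matrix(0, nrow(map), ncol(map))
  } else {
    N_scale * (max(map) - map) / rng
  }
  attr(out, "kind") <- "similarity"
  out
}

#' Peak-promotion weight of a similarity map
#'
#' Implements the map-promotion operator used before integration: with `M`
#' the global maximum and `m_bar` the mean value of the other local maxima
#' (cells with positive value that are >= all of their existing 3 x 3
#' neighbors, excluding cells equal to `M`; `m_bar = 0` when there are none),
#' the map's weight is `(M - m_bar)^2`. A map with a single strong activity
#' peak keeps its full weight; a map with many comparable peaks is demoted.
#'
#' @param map similarity matrix in `[0, N_scale]`.
#' @return non-negative scalar weight.
#' @export
peak_promotion_weight <- function(map) {
  M <- max(map)
  if (M <= 0) return(0)
  h <- nrow(map); w <- ncol(map)
  neigh_max <- matrix(-Inf, h, w)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      rs <- seq_len(h) + dy
      cs <- seq_len(w) + dx
      ok_r <- rs >= 1L & rs <= h
      ok_c <- cs >= 1L & cs <= w
      neigh_max[ok_r, ok_c] <- pmax(neigh_max[ok_r, ok_c],
                                    map[rs[ok_r], cs[ok_c], drop = FALSE])
    }
  }
  local_max <- map > 0 & map >= neigh_max
  peaks <- map[local_max]
  others <- peaks[peaks < M]
  m_bar <- if (length(others) == 0L) 0 else mean(others)
  (M - m_bar)^2
}

#' Weighted cellwise integration of similarity maps
#'
#' @param maps list of equally-shaped numeric matrices.
#' @param weights non-negative numeric vector, one per map.
#' @return matrix `sum_m weights[m] * maps[[m]]` (attribute
#'   `kind = "integrated"`).
#' @export
integrate_maps <- function(maps, weights) {
  if (length(maps) == 0L) stop("no maps to integrate", call. = FALSE)
  if (length(maps) != length(weights))
    stop("need exactly one weight per map", call. = FALSE)
  dims <- vapply(maps, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("maps have mismatched shapes", call. = FALSE)
  out <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  for (i in seq_along(maps)) out <- out + weights[i] * maps[[i]]
  attr(out, "kind") <- "integrated"
  out
}

#' Combine target and distractor integrated maps into the relevance map
#'
#' `R = (T - D) / N_maps` cellwise, then min-max rescaled to `[0, 1]` so the
#' downstream relevance threshold has a fixed scale; a constant difference
#' map (degenerate range) rescales to all zeros. Higher values mark blocks
#' more similar to the target example and less similar to the distractor.
#'
#' @param target_map integrated target similarity map.
#' @param distractor_map integrated distractor similarity map (same shape).
#' @param n_maps total number of feature x metric maps that entered each
#'   integration.
#' @return relevance matrix in `[0, 1]` (attribute `kind = "relevance"`).
#' @export
relevance_map <- function(target_map, distractor_map, n_maps) {
  if (!all(dim(target_map) == dim(distractor_map)))
    stop("target and distractor maps have different shapes", call. = FALSE)
  r <- (target_map - distractor_map) / n_maps
  rng <- max(r) - min(r)
  out <- if (rng == 0) matrix(0, nrow(r), ncol(r)) else (r - min(r)) / rng
  attr(out, "kind") <- "relevance"
  out
}

#' Select the top-ranked fraction of blocks as regions of interest
#'
#' Returns the `ceiling(fraction * n_blocks)` highest-scoring blocks. Ties
#' are broken deterministically in row-major order (smaller row first, then
#' smaller column).
#'
#' @param relevance relevance matrix.
#' @param fraction fraction of blocks to keep, in `(0, 1]` (default 0.1).
#' @return data.frame with 0-based `row`, `col` and `score`, ordered by
#'   decreasing score.
#' @export
threshold_rois <- function(relevance, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  n_r <- nrow(relevance); n_c <- ncol(relevance)
  df <- data.frame(
    row = rep(seq_len(n_r) - 1L, each = n_c),
    col = rep(seq_len(n_c) - 1L, times = n_r)
  )
  df$score <- relevance[cbind(df$row + 1L, df$col + 1L)]
  # small epsilon keeps e.g. ceiling(0.07 * 100) at 7 despite FP representation
  k <- max(1L, as.integer(ceiling(fraction * nrow(df) - 1e-9)))
  df <- df[order(-df$score, df$row, df$col), , drop = FALSE]
  out <- df[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a slide from one target and one distractor example block
#'
#' End-to-end composition: the image is partitioned into a block grid, every
#' block is described by the five histogram features, per-feature/per-metric
#' distance maps to each example are built, zero-reassigned, inverted to
#' similarity maps, weighted by the peak-promotion operator and integrated;
#' the relevance map is the rescaled difference of the target and distractor
#' integrations. Deterministic for fixed inputs and configuration.
#'
#' For grayscale images the color feature duplicates the gray feature (see
#' [extract_block_features()]) and is skipped at integration so no feature is
#' double-counted.
#'
#' @param image gray matrix or RGB array, values 0-255.
#' @param target,distractor 0-based `(row, col)` of the example blocks; must
#'   differ.
#' @param block_size block side in pixels (default 70).
#' @param features subset of [feature_ids()] to use.
#' @param metrics subset of [metric_ids()] to use.
#' @param N_scale similarity scale (default 1).
#' @param grid optional precomputed `block_grid`.
#' @param grid_features optional precomputed `grid_features` (skips feature
#'   extraction).
#' @return a `slide_score` object: list with `relevance` (matrix in `[0, 1]`),
#'   `grid`, `n_maps`, `features`, `metrics`, `target`, `distractor`, and the
#'   integrated `target_map` / `distractor_map`.
#' @export
score_slide <- function(image, target, distractor, block_size = 70L,
                        features = feature_ids(), metrics = metric_ids(),
                        N_scale = 1, grid = NULL, grid_features = NULL) {
  features <- match.arg(features, feature_ids(), several.ok = TRUE)
  metrics <- match.arg(metrics, metric_ids(), several.ok = TRUE)
  if (length(target) != 2L || length(distractor) != 2L)
    stop("target and distractor must be (row, col) pairs", call. = FALSE)
  if (all(target == distractor))
    stop("target and distractor blocks must differ", call. = FALSE)
  if (is.null(grid_features)) {
    d <- dim(image)
    if (is.null(grid)) grid <- partition_image(d[2], d[1], block_size)
    grid_features <- characterize_grid(image, grid)
  } else {
    grid <- attr(grid_features, "grid")
  }
  if (n_blocks(grid) < 2L)
    stop("grid must contain at least 2 blocks", call. = FALSE)
  ex_t <- features_at(grid_features, target[1], target[2])
  ex_d <- features_at(grid_features, distractor[1], distractor[2])
  # grayscale input: the color histogram duplicates the gray one; keep one
  if (!isTRUE(attr(ex_t, "color_input")) && all(c("gray", "color") %in% features))
    features <- setdiff(features, "color")

  build_integrated <- function(example) {
    maps <- list(); weights <- numeric(0)
    for (f in features) {
      for (m in metrics) {
        dm <- build_distance_map(grid_features, example, f, m)
        sm <- normalize_to_similarity(reassign_zero_minimum(dm), N_scale)
        maps[[length(maps) + 1L]] <- sm
        weights <- c(weights, peak_promotion_weight(sm))
      }
    }
    integrate_maps(maps, weights)
  }

  t_map <- build_integrated(ex_t)
  d_map <- build_integrated(ex_d)
  n_maps <- length(features) * length(metrics)
  structure(
    list(relevance = relevance_map(t_map, d_map, n_maps),
         grid = grid, n_maps = n_maps,
         features = features, metrics = metrics,
         target = as.integer(target), distractor = as.integer(distractor),
         target_map = t_map, distractor_map = d_map),
    class = "slide_score"
  )
}

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf(paste0("slide_score: %d x %d relevance map (%d maps: %d ",
                     "features x %d metrics)\n"),
              x$grid$n_rows, x$grid$n_cols, 2L * x$n_maps,
              length(x$features), length(x$metrics)))
  cat(sprintf("  target (%d,%d)  distractor (%d,%d)\n",
              x$target[1], x$target[2], x$distractor[1], x$distractor[2]))
  invisible(x)
}
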