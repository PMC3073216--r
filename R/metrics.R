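#' The five histogram metrics
#'
#' Identifiers accepted by [hist_distance()]: Euclidean distance, histogram
#' intersection (as a distance), Jensen-Shannon divergence, relative bin
#' deviation and relative histogram deviation.
#'
#' @return character vector of metric names.
#' @export
metric_ids <- function() {
  c("euclidean", "intersection", "jsd", "rel_bin_dev", "rel_dev")
}

#' Feature identifiers
#' @return character vector of the five block feature names.
#' @export
feature_ids <- function() {
  c("gray", "color", "lbp", "tamura", "sobel")
}

#' L1-normalize a histogram into a probability vector
#'
#' @param h a `block_histogram` or a non-negative numeric vector with
#'   positive mass.
#' @return numeric vector summing to 1.
#' @export
l1_normalize <- function(h) {
  counts <- if (inherits(h, "block_histogram")) h$counts else as.numeric(h)
  s <- sum(counts)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize an all-zero histogram", call. = FALSE)
  counts / s
}

#' Distance between two histograms
#'
#' Both inputs are L1-normalized before the metric is applied, so distances
#' are comparable across blocks regardless of how many pixels contributed.
#' All five metrics are symmetric, non-negative and zero at equality. With
#' per-bin probabilities `H_m`, `G_m` and guard `eps = 1e-12`:
#'
#' * `euclidean`: `sqrt(sum (H_m - G_m)^2)`
#' * `intersection`: `1 - sum min(H_m, G_m)`, in `[0, 1]`
#' * `jsd`: `sum H_m log(2 H_m / (H_m + G_m)) + G_m log(2 G_m / (H_m + G_m))`
#'   with `0 log 0 = 0` (natural log; bounded above by `2 log 2`)
#' * `rel_bin_dev`: `sum (H_m - G_m)^2 / ((H_m + G_m)/2 + eps)` (chi-square
#'   type per-bin relative deviation)
#' * `rel_dev`: `sqrt(sum (H_m - G_m)^2) / ((||H||_2 + ||G||_2)/2 + eps)`
#'
#' A zero-mass histogram (possible for the Tamura feature on a perfectly flat
#' block) is kept as the zero vector rather than normalized, so two such
#' histograms are at distance 0.
#'
#' @param h,g `block_histogram` objects (same feature, same bin count) or
#'   plain numeric count vectors of equal length.
#' @param metric one of [metric_ids()].
#' @return non-negative scalar distance.
#' @export
hist_distance <- function(h, g, metric = "euclidean") {
  metric <- match.arg(metric, metric_ids())
  if (inherits(h, "block_histogram") && inherits(g, "block_histogram") &&
      h$feature != g$feature)
    stop("cannot compare histograms of different features: ",
         h$feature, " vs ", g$feature, call. = FALSE)
  # a zero-mass histogram (e.g. the Tamura histogram of a perfectly flat
  # block, where no pixel passes the gradient threshold) is kept as the zero
  # vector: two textureless blocks are then at distance 0 of each other
  norm0 <- function(x) {
    counts <- if (inherits(x, "block_histogram")) x$counts else as.numeric(x)
    if (sum(counts) > 0) counts / sum(counts) else counts
  }
  H <- norm0(h)
  G <- norm0(g)
  if (length(H) != length(G))
    stop("histograms have different bin counts: ", length(H), " vs ",
         length(G), call. = FALSE)
  eps <- 1e-12
  switch(metric,
    euclidean = sqrt(sum((H - G)^2)),
    intersection = 1 - sum(pmin(H, G)),
    jsd = {
      s <- H + G
      th <- ifelse(H > 0, H * log(2 * H / s), 0)
      tg <- ifelse(G > 0, G * log(2 * G / s), 0)
      sum(th) + sum(tg)
    },
    rel_bin_dev = sum((H - G)^2 / ((H + G) / 2 + eps)),
    rel_dev = sqrt(sum((H - G)^2)) /
      ((sqrt(sum(H^2)) + sqrt(sum(G^2))) / 2 + eps)
  )
}
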