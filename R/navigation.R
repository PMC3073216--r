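#' Parse a navigation log of window-of-interest requests
#'
#' A navigation log records each viewport (window-of-interest, WoI) request a
#' user made while examining a slide: time in milliseconds, rectangle origin
#' and size in base-resolution pixels, and a resolution tag. The CSV must
#' have header `time_ms,x,y,w,h,level`.
#'
#' @param path path to the CSV file.
#' @return a `navigation_log`: data.frame with the six columns, validated
#'   (non-decreasing times, positive rectangle areas).
#' @export
parse_navigation_log <- function(path) {
  if (!file.exists(path))
    stop("navigation log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_ms", "x", "y", "w", "h", "level")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("navigation log ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, required]
  for (col in c("time_ms", "x", "y", "w", "h")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("navigation log ", path, ": non-numeric '", col, "' at line ",
           bad[1] + 1L, call. = FALSE)
    df[[col]] <- v
  }
  bad_area <- which(df$w <= 0 | df$h <= 0)
  if (length(bad_area) > 0L)
    stop("navigation log ", path, ": non-positive WoI area at line ",
         bad_area[1] + 1L, call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$time_ms) < 0))
    stop("navigation log ", path, ": request times are not non-decreasing",
         call. = FALSE)
  df$level <- as.character(df$level)
  class(df) <- c("navigation_log", "data.frame")
  df
}

#' Write a navigation log to CSV
#'
#' Inverse of [parse_navigation_log()]; the two round-trip exactly.
#'
#' @param log a `navigation_log` (or data.frame with the same columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_navigation_log <- function(log, path) {
  required <- c("time_ms", "x", "y", "w", "h", "level")
  stopifnot(all(required %in% names(log)))
  utils::write.csv(as.data.frame(log)[, required], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-block visit counts from a navigation log
#'
#' Each WoI request increments by 1 the count of every block its rectangle
#' intersects (a "visit" is an intersecting request; dwell time is not
#' weighted).
#'
#' @param log a `navigation_log` with coordinates in the grid's reference
#'   resolution.
#' @param grid a `block_grid`.
#' @return integer `n_rows x n_cols` matrix of visit counts.
#' @export
visits_per_block <- function(log, grid) {
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(log))) {
    hit <- blocks_intersecting(grid, log$x[i], log$y[i], log$w[i], log$h[i])
    if (nrow(hit) > 0L) {
      idx <- cbind(hit$row + 1L, hit$col + 1L)
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

#' Mark interesting blocks from visit counts
#'
#' A block is marked interesting (set I) when its visit count is strictly
#' larger than `visit_threshold` times the count of the most visited block.
#'
#' @param visits visit-count matrix from [visits_per_block()].
#' @param visit_threshold fraction of the maximum count (default 0.5).
#' @return data.frame of 0-based `row`, `col` (row-major order).
#' @export
mark_interesting <- function(visits, visit_threshold = 0.5) {
  mx <- max(visits)
  if (mx == 0) {
    warning("all visit counts are zero; no interesting blocks")
    return(data.frame(row = integer(0), col = integer(0)))
  }
  sel <- which(visits > visit_threshold * mx, arr.ind = TRUE)
  out <- data.frame(row = sel[, 1] - 1L, col = sel[, 2] - 1L)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mark estimated-relevant blocks from a relevance map
#'
#' A block enters the estimated set E when its relevance score is strictly
#' larger than the threshold on the `[0, 1]` min-max-rescaled map (default
#' 0.9). With `percentile = TRUE` the threshold is instead read as a sample
#' quantile of the scores (so 0.9 selects blocks above the 90th percentile).
#'
#' @param relevance relevance matrix in `[0, 1]`.
#' @param relevance_threshold threshold (default 0.9).
#' @param percentile interpret the threshold as a quantile instead of an
#'   absolute score (default `FALSE`).
#' @return data.frame of 0-based `row`, `col` (row-major order).
#' @export
mark_estimated <- function(relevance, relevance_threshold = 0.9,
                           percentile = FALSE) {
  if (max(relevance) == 0)
    warning("degenerate all-zero relevance map; no estimated blocks")
  cut <- if (percentile) {
    stats::quantile(relevance, relevance_threshold, names = FALSE)
  } else {
    relevance_threshold
  }
  sel <- which(relevance > cut, arr.ind = TRUE)
  out <- data.frame(row = sel[, 1] - 1L, col = sel[, 2] - 1L)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision and recall of an estimated block set against an interesting set
#'
#' Precision is the fraction of estimated blocks (E) that are interesting
#' (I), `|E intersect I| / |E|`; recall is the fraction of interesting blocks
#' correctly estimated, `|E intersect I| / |I|`. Empty sets yield 0.
#'
#' @param E,I data.frames of 0-based `row`, `col` over the same grid.
#' @return an `eval_result`: list with `E`, `I`, `precision`, `recall`,
#'   `n_E`, `n_I`, `n_overlap`.
#' @export
precision_recall <- function(E, I) {
  kE <- block_key(E)
  kI <- block_key(I)
  n_overlap <- length(intersect(kE, kI))
  structure(
    list(E = E, I = I,
         precision = if (length(kE) == 0L) 0 else n_overlap / length(kE),
         recall = if (length(kI) == 0L) 0 else n_overlap / length(kI),
         n_E = length(kE), n_I = length(kI), n_overlap = n_overlap),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: precision %.3f  recall %.3f  (|E|=%d, |I|=%d, overlap %d)\n",
              x$precision, x$recall, x$n_E, x$n_I, x$n_overlap))
  invisible(x)
}

#' Random block-selection baseline
#'
#' Uniform sample of blocks without replacement; the reference comparator
#' for the example-driven relevance ranking.
#'
#' @param grid a `block_grid`.
#' @param n_select number of blocks to draw (at most `n_blocks(grid)`).
#' @param seed optional integer; fixed seeds reproduce the same draw without
#'   disturbing the caller's RNG state.
#' @return data.frame of 0-based `row`, `col`.
#' @export
random_baseline <- function(grid, n_select, seed = NULL) {
  total <- n_blocks(grid)
  if (n_select > total)
    stop("cannot select ", n_select, " blocks from a grid of ", total,
         call. = FALSE)
  idx <- with_local_seed(seed, sample.int(total, n_select))
  out <- data.frame(row = (idx - 1L) %/% grid$n_cols,
                    col = (idx - 1L) %% grid$n_cols)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}
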