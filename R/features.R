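#' Histograms describing a block
#'
#' Constructor for the histogram objects produced by the per-feature
#' operations. Bin counts are non-negative and sum to the number of pixels
#' that contributed to the feature (all pixels for gray and color, interior
#' pixels for LBP and Sobel, pixels with a defined texture triple for Tamura).
#'
#' @param counts numeric vector of non-negative bin counts.
#' @param feature one of `"gray"`, `"color"`, `"lbp"`, `"tamura"`, `"sobel"`.
#' @return a `block_histogram` object.
#' @export
new_histogram <- function(counts, feature) {
  feature <- match.arg(feature, c("gray", "color", "lbp", "tamura", "sobel"))
  expected <- if (feature %in% c("gray", "lbp")) 256L else 512L
  counts <- as.numeric(counts)
  if (length(counts) != expected)
    stop(feature, " histogram must have ", expected, " bins, got ",
         length(counts), call. = FALSE)
  if (any(counts < 0)) stop("histogram counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, n_bins = expected, feature = feature),
            class = "block_histogram")
}

#' @export
print.block_histogram <- function(x, ...) {
  cat(sprintf("block_histogram <%s>: %d bins, mass %g\n",
              x$feature, x$n_bins, sum(x$counts)))
  invisible(x)
}

#' Convert an RGB image or block to 8-bit luminance
#'
#' Uses the ITU-R BT.601 weights `round(0.299 R + 0.587 G + 0.114 B)`.
#' Grayscale input is returned unchanged.
#'
#' @param image integer matrix (gray) or h x w x 3 array (RGB), values 0-255.
#' @return integer matrix of luminance values in 0-255.
#' @export
as_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("expected a gray matrix or an RGB array", call. = FALSE)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

check_intensity_block <- function(block, min_side = 1L) {
  if (length(dim(block)) != 2L)
    stop("expected a single-channel intensity block; convert color input ",
         "with as_gray()", call. = FALSE)
  if (length(block) == 0L) stop("empty block", call. = FALSE)
  if (nrow(block) < min_side || ncol(block) < min_side)
    stop("block must be at least ", min_side, "x", min_side, " pixels",
         call. = FALSE)
  invisible(block)
}

#' Gray-level histogram of a block
#'
#' 256 bins, one per 8-bit intensity value; `counts[v + 1]` is the number of
#' pixels with intensity `v`.
#'
#' @param block single-channel 8-bit block (integer matrix, values 0-255).
#' @return a `block_histogram` with 256 bins summing to the pixel count.
#' @export
gray_histogram <- function(block) {
  check_intensity_block(block)
  new_histogram(tabulate(as.integer(block) + 1L, nbins = 256L), "gray")
}

#' RGB color histogram of a block
#'
#' The RGB cube is partitioned into 8 x 8 x 8 = 512 bins (32 intensity levels
#' per cell); a pixel maps to bin `64 * floor(R/32) + 8 * floor(G/32) +
#' floor(B/32)`.
#'
#' @param block RGB 8-bit block (h x w x 3 array, values 0-255).
#' @return a `block_histogram` with 512 bins summing to the pixel count.
#' @export
color_histogram <- function(block) {
  if (length(dim(block)) != 3L || dim(block)[3] < 3L)
    stop("color_histogram requires a 3-channel RGB block", call. = FALSE)
  if (dim(block)[1] == 0L || dim(block)[2] == 0L)
    stop("empty block", call. = FALSE)
  idx <- 64L * (as.integer(block[, , 1]) %/% 32L) +
    8L * (as.integer(block[, , 2]) %/% 32L) +
    (as.integer(block[, , 3]) %/% 32L)
  new_histogram(tabulate(idx + 1L, nbins = 512L), "color")
}

#' Local binary pattern histogram of a block
#'
#' For each interior pixel (the 1-pixel border is excluded rather than
#' padded), an 8-bit code is formed from its 8 neighbors in clockwise order
#' starting at the top-left neighbor; a bit is 1 iff the neighbor intensity
#' is strictly larger than the center. Codes 0-255 are tallied, so a constant
#' block puts all its mass in code 0.
#'
#' @param block single-channel 8-bit block, at least 3 x 3.
#' @return a `block_histogram` with 256 bins summing to
#'   `(nrow - 2) * (ncol - 2)`.
#' @export
lbp_histogram <- function(block) {
  check_intensity_block(block, min_side = 3L)
  h <- nrow(block); w <- ncol(block)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  center <- block[ri, ci, drop = FALSE]
  # clockwise from top-left: (dy,dx) offsets; first neighbor = most
  # significant bit
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, length(ri), length(ci))
  for (k in seq_along(offs)) {
    nb <- block[ri + offs[[k]][1], ci + offs[[k]][2], drop = FALSE]
    code <- code + (nb > center) * bitwShiftL(1L, 8L - k)
  }
  new_histogram(tabulate(as.integer(code) + 1L, nbins = 256L), "lbp")
}

#' Sobel gradient-magnitude histogram of a block
#'
#' The standard 3 x 3 Sobel pair is applied at each interior pixel; the
#' gradient magnitude `sqrt(Gx^2 + Gy^2)` is normalized by its analytic
#' maximum `4 * 255 * sqrt(2)` to `[0, 1]` and quantized into 512 uniform
#' bins (a normalized magnitude of exactly 1 falls in the last bin).
#'
#' @param block single-channel 8-bit block, at least 3 x 3.
#' @return a `block_histogram` with 512 bins summing to
#'   `(nrow - 2) * (ncol - 2)`.
#' @export
sobel_histogram <- function(block) {
  check_intensity_block(block, min_side = 3L)
  h <- nrow(block); w <- ncol(block)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  m <- block
  gx <- (m[ri - 1L, ci + 1L] + 2 * m[ri, ci + 1L] + m[ri + 1L, ci + 1L]) -
    (m[ri - 1L, ci - 1L] + 2 * m[ri, ci - 1L] + m[ri + 1L, ci - 1L])
  gy <- (m[ri + 1L, ci - 1L] + 2 * m[ri + 1L, ci] + m[ri + 1L, ci + 1L]) -
    (m[ri - 1L, ci - 1L] + 2 * m[ri - 1L, ci] + m[ri - 1L, ci + 1L])
  mag <- sqrt(gx^2 + gy^2) / (4 * 255 * sqrt(2))
  bins <- pmin(511L, as.integer(floor(mag * 512)))
  new_histogram(tabulate(bins + 1L, nbins = 512L), "sobel")
}

# --- Tamura texture helpers ------------------------------------------------

# replicate-pad a matrix by p pixels on every side
pad_replicate <- function(m, p) {
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

# summed-area table with a leading zero row/column:
# S[i+1, j+1] = sum(m[1:i, 1:j])
integral_image <- function(m) {
  s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  s
}

# mean over the even-sized window rows r-half .. r+half-1 (same for cols),
# evaluated at the outer grid rows x cols (1-based indices into the padded
# matrix underlying S)
win_mean_even <- function(S, rows, cols, half) {
  a <- rows - half; b <- rows + half - 1L
  cc <- cols - half; d <- cols + half - 1L
  (S[b + 1L, d + 1L] - S[a, d + 1L] - S[b + 1L, cc] + S[a, cc]) / (2 * half)^2
}

# sum over the odd window r-hw .. r+hw (same for cols)
win_sum_odd <- function(S, rows, cols, hw) {
  S[rows + hw + 1L, cols + hw + 1L] - S[rows - hw, cols + hw + 1L] -
    S[rows + hw + 1L, cols - hw] + S[rows - hw, cols - hw]
}

# per-pixel Tamura components on an intensity block; returns a list of
# matrices (coarseness scale 2^k, contrast, directionality angle in [0, pi),
# and a logical "defined" mask where the gradient magnitude exceeds the
# directionality threshold)
tamura_components <- function(block, dir_threshold = 12) {
  h <- nrow(block); w <- ncol(block)
  p <- 32L  # supports the largest coarseness scale (window 32 + shift 16)
  g <- pad_replicate(block, p)
  S <- integral_image(g)
  rows <- seq_len(h) + p
  cols <- seq_len(w) + p

  # coarseness: best k in 1..5 maximizing the nearest-neighbor average
  # difference E_k (horizontal or vertical); ties keep the smaller scale
  best_e <- matrix(-1, h, w)
  best_k <- matrix(1L, h, w)
  for (k in 1:5) {
    half <- 2L^(k - 1L)
    eh <- abs(win_mean_even(S, rows, cols + half, half) -
                win_mean_even(S, rows, cols - half, half))
    ev <- abs(win_mean_even(S, rows + half, cols, half) -
                win_mean_even(S, rows - half, cols, half))
    ek <- pmax(eh, ev)
    better <- ek > best_e
    best_e[better] <- ek[better]
    best_k[better] <- k
  }
  coarseness <- 2^best_k

  # contrast: sigma / kurtosis^(1/4) over a 13 x 13 window
  hw <- 6L
  n_win <- (2 * hw + 1)^2
  s1 <- win_sum_odd(S, rows, cols, hw)
  s2 <- win_sum_odd(integral_image(g^2), rows, cols, hw)
  s3 <- win_sum_odd(integral_image(g^3), rows, cols, hw)
  s4 <- win_sum_odd(integral_image(g^4), rows, cols, hw)
  mu <- s1 / n_win
  m2 <- pmax(s2 / n_win - mu^2, 0)
  m4 <- s4 / n_win - 4 * mu * s3 / n_win + 6 * mu^2 * s2 / n_win - 3 * mu^4
  eps <- 1e-12
  kurt <- m4 / (m2^2 + eps)
  contrast <- sqrt(m2) / (kurt + eps)^(1 / 4)
  contrast[m2 == 0] <- 0

  # directionality: per-pixel gradient angle from the Prewitt pair, defined
  # only where the gradient magnitude exceeds the threshold
  sh <- function(dy, dx) g[seq_len(h) + p + dy, seq_len(w) + p + dx, drop = FALSE]
  dh <- (sh(-1L, 1L) + sh(0L, 1L) + sh(1L, 1L)) -
    (sh(-1L, -1L) + sh(0L, -1L) + sh(1L, -1L))
  dv <- (sh(-1L, -1L) + sh(-1L, 0L) + sh(-1L, 1L)) -
    (sh(1L, -1L) + sh(1L, 0L) + sh(1L, 1L))
  mag <- (abs(dh) + abs(dv)) / 2
  defined <- mag > dir_threshold
  theta <- atan(dv / dh) + pi / 2
  theta[dh == 0 & dv > 0] <- 0        # atan(+Inf) + pi/2 = pi, wraps to 0
  theta[dh == 0 & dv <= 0] <- 0       # undefined/vertical-null gradient
  theta[dh == 0 & dv < 0] <- 0
  theta[theta >= pi] <- theta[theta >= pi] - pi

  list(coarseness = coarseness, contrast = contrast,
       directionality = theta, defined = defined)
}

#' Tamura texture histogram of a block
#'
#' Per-pixel coarseness, contrast and directionality (the three Tamura
#' features most correlated with human texture perception) are computed and
#' jointly quantized into 8 x 8 x 8 = 512 bins:
#'
#' * coarseness: dominant texel scale `2^k`, `k` in 1..5 maximizing the
#'   nearest-neighbor average-intensity difference; quantized on a log2 scale
#'   over scales 2..32.
#' * contrast: `sigma / kurtosis^(1/4)` over a 13 x 13 window, clipped to
#'   `[0, 128]` and split into 8 uniform levels.
#' * directionality: gradient angle in `[0, pi)` from the Prewitt operator
#'   pair, in 8 uniform levels; a pixel only contributes a triple where its
#'   gradient magnitude exceeds 12 (flat pixels carry no orientation).
#'
#' Windows near the block border use replicate padding. Quantization ranges
#' are fixed a priori so that histograms are comparable across blocks.
#'
#' @param block single-channel 8-bit block, at least 8 x 8.
#' @return a `block_histogram` with 512 bins; the mass equals the number of
#'   pixels with gradient magnitude above the directionality threshold.
#' @export
tamura_histogram <- function(block) {
  check_intensity_block(block, min_side = 8L)
  tc <- tamura_components(block)
  lvl_coarse <- pmin(7L, 2L * (as.integer(log2(tc$coarseness)) - 1L))
  lvl_contrast <- pmin(7L, as.integer(floor(pmin(tc$contrast, 128) / 16)))
  lvl_dir <- pmin(7L, as.integer(floor(tc$directionality / pi * 8)))
  idx <- 64L * lvl_coarse + 8L * lvl_contrast + lvl_dir
  counts <- tabulate(idx[tc$defined] + 1L, nbins = 512L)
  new_histogram(counts, "tamura")
}

#' Extract all five histogram descriptors of one grid block
#'
#' Color images use the luminance conversion of [as_gray()] for the
#' intensity-based features (gray, LBP, Tamura, Sobel). For grayscale images
#' the color histogram degenerates to the 256-bin gray histogram zero-padded
#' to 512 bins (flagged with attribute `degenerate_color = TRUE`) so the
#' pipeline shape is unchanged; map integration skips the duplicate.
#'
#' @param image gray matrix or RGB array, values 0-255.
#' @param grid a `block_grid` matching the image.
#' @param row,col 0-based block indices.
#' @return a `block_features` object: list with elements `gray`, `color`,
#'   `lbp`, `tamura`, `sobel`, each a `block_histogram`.
#' @export
extract_block_features <- function(image, grid, row, col) {
  px <- block_pixels(image, grid, row, col)
  is_color <- length(dim(px)) == 3L
  gpx <- as_gray(px)
  if (is_color) {
    col_hist <- color_histogram(px)
  } else {
    col_hist <- new_histogram(c(gray_histogram(gpx)$counts, rep(0, 256)),
                              "color")
    attr(col_hist, "degenerate_color") <- TRUE
  }
  structure(
    list(gray = gray_histogram(gpx),
         color = col_hist,
         lbp = lbp_histogram(gpx),
         tamura = tamura_histogram(gpx),
         sobel = sobel_histogram(gpx)),
    class = "block_features",
    color_input = is_color
  )
}

#' Compute features for every block of a grid
#'
#' @param image gray matrix or RGB array, values 0-255.
#' @param grid a `block_grid`; defaults to partitioning the image with
#'   `block_size`.
#' @param block_size used only when `grid` is missing.
#' @return a `grid_features` object: row-major list of `block_features`
#'   (index `row * n_cols + col + 1`) with the grid attached as an attribute.
#' @export
characterize_grid <- function(image, grid = NULL, block_size = 70L) {
  d <- dim(image)
  if (is.null(grid)) grid <- partition_image(d[2], d[1], block_size)
  if (d[1] < grid$n_rows * grid$block_size || d[2] < grid$n_cols * grid$block_size)
    stop("grid does not fit inside the image", call. = FALSE)
  feats <- vector("list", n_blocks(grid))
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      feats[[r * grid$n_cols + cc + 1L]] <-
        extract_block_features(image, grid, r, cc)
    }
  }
  structure(feats, class = "grid_features", grid = grid)
}

#' Fetch the features of one block from a `grid_features` object
#' @param features a `grid_features` object.
#' @param row,col 0-based block indices.
#' @return the `block_features` of that block.
#' @export
features_at <- function(features, row, col) {
  grid <- attr(features, "grid")
  if (row < 0L || row >= grid$n_rows || col < 0L || col >= grid$n_cols)
    stop("block index outside grid", call. = FALSE)
  features[[row * grid$n_cols + col + 1L]]
}
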