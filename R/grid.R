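#' Partition an image into a homogeneous grid of equal-size blocks
#'
#' The slide is tiled by square, non-overlapping blocks of `block_size`
#' pixels. Trailing partial strips (the remainder of the integer division of
#' the image dimensions by `block_size`) are dropped, so every block covers
#' exactly the same number of pixels and block histograms are directly
#' comparable without renormalization.
#'
#' Coordinate conventions used throughout the package: pixel coordinates are
#' 0-based with the origin at the top-left corner; grid indices `(row, col)`
#' are 0-based; block rectangles are half-open,
#' `[x0, x0 + block_size) x [y0, y0 + block_size)`.
#'
#' @param image_width,image_height image dimensions in pixels.
#' @param block_size side of the square blocks in pixels (default 70).
#' @return A `block_grid` object: list with `image_width`, `image_height`,
#'   `block_size`, `n_rows`, `n_cols`.
#' @examples
#' g <- partition_image(640, 480, 70)
#' g$n_cols # 9
#' g$n_rows # 6
#' @export
partition_image <- function(image_width, image_height, block_size = 70L) {
  image_width <- as.integer(image_width)
  image_height <- as.integer(image_height)
  block_size <- as.integer(block_size)
  if (block_size < 3L)
    stop("block_size must be at least 3 pixels", call. = FALSE)
  if (image_width < block_size || image_height < block_size)
    stop("image (", image_width, "x", image_height,
         ") is smaller than one block of size ", block_size, call. = FALSE)
  structure(
    list(
      image_width = image_width,
      image_height = image_height,
      block_size = block_size,
      n_rows = image_height %/% block_size,
      n_cols = image_width %/% block_size
    ),
    class = "block_grid"
  )
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("block_grid: %d x %d blocks of %d px (image %d x %d)\n",
              x$n_rows, x$n_cols, x$block_size, x$image_width, x$image_height))
  invisible(x)
}

#' Number of blocks in a grid
#' @param grid a `block_grid`.
#' @return integer block count.
#' @export
n_blocks <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  grid$n_rows * grid$n_cols
}

#' Pixel rectangle of a grid block
#'
#' @param grid a `block_grid`.
#' @param row,col 0-based block indices.
#' @return list with `row`, `col`, `x0`, `y0`, `width`, `height`; the
#'   rectangle is half-open in both axes.
#' @export
block_rect <- function(grid, row, col) {
  stopifnot(inherits(grid, "block_grid"))
  row <- as.integer(row); col <- as.integer(col)
  if (row < 0L || row >= grid$n_rows || col < 0L || col >= grid$n_cols)
    stop("block index (", row, ",", col, ") outside grid ",
         grid$n_rows, "x", grid$n_cols, call. = FALSE)
  list(row = row, col = col,
       x0 = col * grid$block_size, y0 = row * grid$block_size,
       width = grid$block_size, height = grid$block_size)
}

#' Blocks intersecting a pixel rectangle
#'
#' Returns all grid blocks whose pixel rectangle has a nonempty intersection
#' with the query rectangle `[x, x+w) x [y, y+h)`, clipped to the grid's
#' covered region. Used to map window-of-interest requests from navigation
#' logs to blocks.
#'
#' @param grid a `block_grid`.
#' @param x,y top-left corner of the query rectangle (0-based pixels).
#' @param w,h rectangle width and height in pixels; must be positive.
#' @return data.frame with 0-based `row`, `col` columns, row-major order;
#'   zero rows when the rectangle misses the covered region entirely.
#' @export
blocks_intersecting <- function(grid, x, y, w, h) {
  stopifnot(inherits(grid, "block_grid"))
  if (w <= 0 || h <= 0)
    stop("query rectangle must have positive area", call. = FALSE)
  bs <- grid$block_size
  # half-open query [x, x+w): last contained pixel column is x+w-1
  c0 <- max(0L, as.integer(floor(x / bs)))
  c1 <- min(grid$n_cols - 1L, as.integer(floor((x + w - 1) / bs)))
  r0 <- max(0L, as.integer(floor(y / bs)))
  r1 <- min(grid$n_rows - 1L, as.integer(floor((y + h - 1) / bs)))
  if (c0 > c1 || r0 > r1)
    return(data.frame(row = integer(0), col = integer(0)))
  out <- expand.grid(col = c0:c1, row = r0:r1)[, c("row", "col")]
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the pixels of one block from an image
#'
#' @param image gray matrix or RGB array as returned by [read_slide()].
#' @param grid a `block_grid` matching the image dimensions.
#' @param row,col 0-based block indices.
#' @return matrix (gray) or array (RGB) of the block's pixels.
#' @export
block_pixels <- function(image, grid, row, col) {
  r <- block_rect(grid, row, col)
  ri <- (r$y0 + 1L):(r$y0 + r$height)  # matrix rows are y (1-based)
  ci <- (r$x0 + 1L):(r$x0 + r$width)
  if (length(dim(image)) == 3L) image[ri, ci, , drop = FALSE]
  else image[ri, ci, drop = FALSE]
}
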