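#' Read a slide image from PNG, TIFF or JPEG
#'
#' Returns an 8-bit integer raster: a matrix for grayscale input or an
#' `h x w x 3` array for color (an alpha channel, if present, is dropped).
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return integer matrix or array with values in 0-255.
#' @export
read_slide <- function(path) {
  if (!file.exists(path))
    stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  img <- round(raw * 255)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1]
    } else if (dim(img)[3] >= 3L) {
      img <- img[, , 1:3, drop = FALSE]
    } else {
      stop("unsupported channel count: ", dim(img)[3], call. = FALSE)
    }
  }
  storage.mode(img) <- "integer"
  img
}

#' Write a slide image to PNG
#'
#' @param image integer matrix or `h x w x 3` array, values 0-255.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_slide <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a relevance map as CSV
#'
#' One row per block: 0-based `row`, `col` and `score`, in row-major order.
#'
#' @param relevance relevance matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_relevance_csv <- function(relevance, path) {
  n_r <- nrow(relevance); n_c <- ncol(relevance)
  df <- data.frame(
    row = rep(seq_len(n_r) - 1L, each = n_c),
    col = rep(seq_len(n_c) - 1L, times = n_r)
  )
  df$score <- relevance[cbind(df$row + 1L, df$col + 1L)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relevance map written by [write_relevance_csv()]
#'
#' @param path CSV path with columns `row`, `col`, `score`.
#' @return numeric matrix reconstructed from the 0-based indices.
#' @export
read_relevance_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col", "score") %in% names(df)))
  m <- matrix(NA_real_, max(df$row) + 1L, max(df$col) + 1L)
  m[cbind(df$row + 1L, df$col + 1L)] <- df$score
  if (anyNA(m))
    stop("relevance CSV does not cover a full grid: ", path, call. = FALSE)
  m
}

#' Render a relevance map as a block-constant heatmap PNG
#'
#' Each block is painted as a `block_size`-pixel square; high relevance is
#' red, low relevance blue.
#'
#' @param relevance relevance matrix in `[0, 1]`.
#' @param path output PNG path.
#' @param block_size upsampling factor in pixels per block (default 70).
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(relevance, path, block_size = 70L) {
  up <- kronecker(relevance, matrix(1, block_size, block_size))
  img <- array(0, dim = c(dim(up), 3))
  img[, , 1] <- up          # red = high
  img[, , 2] <- 0.15 * (1 - abs(2 * up - 1))
  img[, , 3] <- 1 - up      # blue = low
  png::writePNG(img, path)
  invisible(path)
}

#' Cache grid features to a columnar CSV
#'
#' One row per block: 0-based `row`, `col`, then the five histograms
#' flattened in a fixed order (`gray_0..gray_255`, `color_0..color_511`,
#' `lbp_*`, `tamura_*`, `sobel_*`).
#'
#' @param features a `grid_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  grid <- attr(features, "grid")
  rows <- lapply(features, function(bf) {
    unlist(lapply(feature_ids(), function(f) bf[[f]]$counts))
  })
  mat <- do.call(rbind, rows)
  nb <- c(gray = 256L, color = 512L, lbp = 256L, tamura = 512L, sobel = 512L)
  colnames(mat) <- unlist(lapply(feature_ids(), function(f)
    paste0(f, "_", seq_len(nb[[f]]) - 1L)))
  df <- data.frame(
    row = rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols),
    col = rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  )
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read grid features cached by [write_features_csv()]
#'
#' @param path CSV path.
#' @param grid the `block_grid` the features were computed on.
#' @param color_input whether the slide was color (affects the degenerate
#'   color-histogram flag; default `TRUE`).
#' @return a `grid_features` object.
#' @export
read_features_csv <- function(path, grid, color_input = TRUE) {
  df <- utils::read.csv(path)
  if (nrow(df) != n_blocks(grid))
    stop("feature cache has ", nrow(df), " rows but grid has ",
         n_blocks(grid), " blocks", call. = FALSE)
  nb <- c(gray = 256L, color = 512L, lbp = 256L, tamura = 512L, sobel = 512L)
  feats <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    offset <- 2L
    hs <- list()
    for (f in feature_ids()) {
      hs[[f]] <- new_histogram(as.numeric(df[i, offset + seq_len(nb[[f]])]), f)
      offset <- offset + nb[[f]]
    }
    if (!color_input) attr(hs$color, "degenerate_color") <- TRUE
    idx <- df$row[i] * grid$n_cols + df$col[i] + 1L
    feats[[idx]] <- structure(hs, class = "block_features",
                              color_input = color_input)
  }
  structure(feats, class = "grid_features", grid = grid)
}
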