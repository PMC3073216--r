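#' Specification of a synthetic H&E-like slide
#'
#' Describes a generated test slide: a pale, lightly textured pink background
#' emulating eosin-stained stroma, plus disjoint rectangular regions rendered
#' in a target texture (default: a dense field of dark purple elliptical
#' blobs emulating hematoxylin-stained nuclei clusters) and in a visually
#' distinct distractor texture.
#'
#' @param width,height image size in pixels (default 700 x 700).
#' @param block_size grid block side (default 70).
#' @param n_target_regions,n_distractor_regions region counts (defaults 3
#'   and 2).
#' @param target_texture,distractor_texture one of `"dense_dark_blobs"`,
#'   `"smooth_tint"`, `"stripes"`.
#' @param background_noise_sd Gaussian intensity noise of the background, in
#'   8-bit intensity units (default 8).
#' @param seed integer RNG seed; the whole slide is a deterministic function
#'   of the spec.
#' @return a `synthetic_slide_spec` object.
#' @export
synthetic_slide_spec <- function(width = 700L, height = 700L, block_size = 70L,
                                 n_target_regions = 3L,
                                 n_distractor_regions = 2L,
                                 target_texture = "dense_dark_blobs",
                                 distractor_texture = "smooth_tint",
                                 background_noise_sd = 8,
                                 seed = 1L) {
  textures <- c("dense_dark_blobs", "smooth_tint", "stripes")
  target_texture <- match.arg(target_texture, textures)
  distractor_texture <- match.arg(distractor_texture, textures)
  if (width < block_size || height < block_size)
    stop("slide smaller than one block", call. = FALSE)
  if (n_target_regions < 0L || n_distractor_regions < 0L)
    stop("region counts must be non-negative", call. = FALSE)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         block_size = as.integer(block_size),
         n_target_regions = as.integer(n_target_regions),
         n_distractor_regions = as.integer(n_distractor_regions),
         target_texture = target_texture,
         distractor_texture = distractor_texture,
         background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_slide_spec"
  )
}

# sample disjoint axis-aligned region rectangles (1-based pixel index lists);
# sizes span roughly 1.5-2.5 blocks so each region fully covers several
# grid blocks. A 2 px margin keeps region-coverage labels unambiguous.
place_regions <- function(n, width, height, block_size, existing = list(),
                          max_tries = 500L) {
  regions <- list()
  overlaps <- function(a, b, margin = 2L) {
    a$x0 < b$x1 + margin && b$x0 < a$x1 + margin &&
      a$y0 < b$y1 + margin && b$y0 < a$y1 + margin
  }
  all_regions <- existing
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      w <- round(stats::runif(1, 1.5, 2.5) * block_size)
      h <- round(stats::runif(1, 1.5, 2.5) * block_size)
      w <- min(w, width); h <- min(h, height)
      x0 <- sample.int(width - w + 1L, 1L)
      y0 <- sample.int(height - h + 1L, 1L)
      cand <- list(x0 = x0, y0 = y0, x1 = x0 + w - 1L, y1 = y0 + h - 1L)
      if (!any(vapply(all_regions, overlaps, logical(1), b = cand))) {
        regions[[length(regions) + 1L]] <- cand
        all_regions[[length(all_regions) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " disjoint regions after ", max_tries,
           " tries; reduce region count or enlarge the slide", call. = FALSE)
  }
  regions
}

# render one texture into img[rows, cols, ]; img is a numeric h x w x 3 array
render_texture <- function(img, region, texture, noise_sd) {
  rows <- region$y0:region$y1
  cols <- region$x0:region$x1
  rh <- length(rows); rw <- length(cols)
  if (texture == "smooth_tint") {
    base <- c(190, 215, 235)  # pale blue-gray wash
    for (ch in 1:3)
      img[rows, cols, ch] <- base[ch] + stats::rnorm(rh * rw, 0, noise_sd / 2)
  } else if (texture == "stripes") {
    light <- c(230, 190, 205); dark <- c(120, 120, 190)
    stripe <- ((cols - region$x0) %/% 4L) %% 2L == 0L
    for (ch in 1:3) {
      plane <- img[rows, cols, ch]
      plane[, stripe] <- light[ch]
      plane[, !stripe] <- dark[ch]
      img[rows, cols, ch] <- plane + stats::rnorm(rh * rw, 0, noise_sd / 2)
    }
  } else {  # dense_dark_blobs: nuclei-cluster look
    n_blobs <- max(8L, round(rh * rw / 140))
    cy <- stats::runif(n_blobs, region$y0, region$y1)
    cx <- stats::runif(n_blobs, region$x0, region$x1)
    ry <- stats::runif(n_blobs, 3, 7)
    rx <- stats::runif(n_blobs, 3, 7)
    base <- c(80, 50, 120)  # hematoxylin-like dark purple
    shade <- stats::rnorm(n_blobs, 0, 12)
    for (b in seq_len(n_blobs)) {
      br <- max(region$y0, floor(cy[b] - ry[b])):min(region$y1, ceiling(cy[b] + ry[b]))
      bc <- max(region$x0, floor(cx[b] - rx[b])):min(region$x1, ceiling(cx[b] + rx[b]))
      mask <- outer(((br - cy[b]) / ry[b])^2, ((bc - cx[b]) / rx[b])^2, "+") <= 1
      for (ch in 1:3) {
        plane <- img[br, bc, ch]
        plane[mask] <- base[ch] + shade[b]
        img[br, bc, ch] <- plane
      }
    }
  }
  img
}

# fraction of each grid block's pixels covered by any of the regions
region_coverage <- function(regions, grid) {
  bs <- grid$block_size
  cov <- matrix(0, grid$n_rows, grid$n_cols)
  for (reg in regions) {
    for (r in seq_len(grid$n_rows) - 1L) {
      for (cc in seq_len(grid$n_cols) - 1L) {
        # block pixels (1-based): rows r*bs+1 .. (r+1)*bs
        oy <- max(0L, min(reg$y1, (r + 1L) * bs) - max(reg$y0 - 1L, r * bs))
        ox <- max(0L, min(reg$x1, (cc + 1L) * bs) - max(reg$x0 - 1L, cc * bs))
        cov[r + 1L, cc + 1L] <- cov[r + 1L, cc + 1L] + oy * ox / bs^2
      }
    }
  }
  cov
}

coverage_blocks <- function(cov, threshold = 0.5) {
  sel <- which(cov >= threshold, arr.ind = TRUE)
  out <- data.frame(row = sel[, 1] - 1L, col = sel[, 2] - 1L)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Generate a synthetic slide with block-level ground truth
#'
#' Produces an RGB image per the spec and the induced ground-truth partition
#' of the block grid: a block is labeled target (distractor) when at least
#' half of its pixels fall inside a target (distractor) region; everything
#' else is background. Deterministic for a fixed spec (including its seed).
#'
#' @param spec a [synthetic_slide_spec()].
#' @return list with `image` (h x w x 3 integer array, 0-255),
#'   `ground_truth` (list of data.frames `target_blocks`,
#'   `distractor_blocks`, `background_blocks`), `grid`, and the region
#'   rectangles (`target_regions`, `distractor_regions`).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  grid <- partition_image(spec$width, spec$height, spec$block_size)
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- array(0, dim = c(h, w, 3))
    base <- c(240, 200, 210)  # eosin-like pale pink stroma
    for (ch in 1:3)
      img[, , ch] <- base[ch] + stats::rnorm(h * w, 0, spec$background_noise_sd)

    t_regions <- place_regions(spec$n_target_regions, w, h, spec$block_size)
    d_regions <- place_regions(spec$n_distractor_regions, w, h,
                               spec$block_size, existing = t_regions)
    for (reg in t_regions)
      img <- render_texture(img, reg, spec$target_texture,
                            spec$background_noise_sd)
    for (reg in d_regions)
      img <- render_texture(img, reg, spec$distractor_texture,
                            spec$background_noise_sd)

    img <- round(clamp(img, 0, 255))
    storage.mode(img) <- "integer"

    t_blocks <- coverage_blocks(region_coverage(t_regions, grid))
    d_blocks <- coverage_blocks(region_coverage(d_regions, grid))
    all_keys <- paste(rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols),
                      rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows),
                      sep = ",")
    bg_keys <- setdiff(all_keys, c(block_key(t_blocks), block_key(d_blocks)))
    bg <- do.call(rbind, lapply(strsplit(bg_keys, ","), as.integer))
    bg_blocks <- if (is.null(bg)) data.frame(row = integer(0), col = integer(0))
      else data.frame(row = bg[, 1], col = bg[, 2])
    rownames(t_blocks) <- rownames(d_blocks) <- NULL

    list(image = img,
         ground_truth = list(target_blocks = t_blocks,
                             distractor_blocks = d_blocks,
                             background_blocks = bg_blocks),
         grid = grid,
         target_regions = t_regions,
         distractor_regions = d_regions)
  })
}

#' Generate a synthetic navigation log concentrated on ground-truth regions
#'
#' Emulates an expert viewing session: most window-of-interest requests are
#' centered on randomly chosen target blocks, with a smaller number spread
#' over other blocks. Each request's window fits inside its block (side 60-95%
#' of the block size), so a request visits exactly the block it was aimed at;
#' background blocks are drawn without replacement whenever possible so no
#' single background block accumulates spurious visits. Timestamps are
#' synthetic, strictly increasing.
#'
#' @param ground_truth the `ground_truth` list from [generate_slide()].
#' @param grid the matching `block_grid`.
#' @param visits_on_target number of requests aimed at target blocks
#'   (default 50).
#' @param visits_background number of requests aimed at non-target blocks
#'   (default 5).
#' @param seed optional integer seed.
#' @return a `navigation_log` data.frame.
#' @export
generate_navigation <- function(ground_truth, grid, visits_on_target = 50L,
                                visits_background = 5L, seed = NULL) {
  tb <- ground_truth$target_blocks
  other <- rbind(ground_truth$background_blocks,
                 ground_truth$distractor_blocks)
  if (visits_on_target > 0L && nrow(tb) == 0L)
    stop("no target blocks to visit", call. = FALSE)
  if (visits_background > 0L && nrow(other) == 0L)
    stop("no non-target blocks to visit", call. = FALSE)
  with_local_seed(seed, {
    pick <- function(blocks, n, replace) {
      if (n == 0L) return(blocks[integer(0), , drop = FALSE])
      blocks[sample.int(nrow(blocks), n, replace = replace), , drop = FALSE]
    }
    aimed <- rbind(
      pick(tb, visits_on_target, replace = TRUE),
      pick(other, visits_background,
           replace = visits_background > nrow(other))
    )
    n <- nrow(aimed)
    bs <- grid$block_size
    sizes <- round(stats::runif(n, 0.6, 0.95) * bs)
    # center the window in its block with jitter that keeps it inside
    slack <- bs - sizes
    x <- aimed$col * bs + floor(slack / 2) +
      round(stats::runif(n, -0.5, 0.5) * slack / 2)
    y <- aimed$row * bs + floor(slack / 2) +
      round(stats::runif(n, -0.5, 0.5) * slack / 2)
    ord <- sample.int(n)  # interleave target and background requests
    log <- data.frame(
      time_ms = cumsum(round(stats::runif(n, 200, 3000))),
      x = clamp(x[ord], 0, grid$image_width - sizes[ord]),
      y = clamp(y[ord], 0, grid$image_height - sizes[ord]),
      w = sizes[ord], h = sizes[ord],
      level = "base", stringsAsFactors = FALSE
    )
    class(log) <- c("navigation_log", "data.frame")
    log
  })
}
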