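# Independent brute-force oracles: plain nested loops, written directly from
# the definitions, kept deliberately separate from the package's vectorized
# implementations.

random_gray_block <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

random_rgb_block <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

oracle_gray_hist <- function(block) {
  counts <- numeric(256)
  for (v in as.integer(block)) counts[v + 1] <- counts[v + 1] + 1
  counts
}

oracle_color_hist <- function(block) {
  counts <- numeric(512)
  for (y in seq_len(nrow(block))) {
    for (x in seq_len(ncol(block))) {
      idx <- 64 * (block[y, x, 1] %/% 32) + 8 * (block[y, x, 2] %/% 32) +
        block[y, x, 3] %/% 32
      counts[idx + 1] <- counts[idx + 1] + 1
    }
  }
  counts
}

# clockwise neighbor order starting top-left; first neighbor = MSB
oracle_lbp_hist <- function(block) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  counts <- numeric(256)
  for (y in 2:(nrow(block) - 1)) {
    for (x in 2:(ncol(block) - 1)) {
      code <- 0
      for (k in 1:8) {
        if (block[y + offs[[k]][1], x + offs[[k]][2]] > block[y, x])
          code <- code + 2^(8 - k)
      }
      counts[code + 1] <- counts[code + 1] + 1
    }
  }
  counts
}

oracle_sobel_hist <- function(block) {
  counts <- numeric(512)
  for (y in 2:(nrow(block) - 1)) {
    for (x in 2:(ncol(block) - 1)) {
      gx <- -block[y - 1, x - 1] + block[y - 1, x + 1] -
        2 * block[y, x - 1] + 2 * block[y, x + 1] -
        block[y + 1, x - 1] + block[y + 1, x + 1]
      gy <- -block[y - 1, x - 1] - 2 * block[y - 1, x] - block[y - 1, x + 1] +
        block[y + 1, x - 1] + 2 * block[y + 1, x] + block[y + 1, x + 1]
      b <- min(511, floor(sqrt(gx^2 + gy^2) / (4 * 255 * sqrt(2)) * 512))
      counts[b + 1] <- counts[b + 1] + 1
    }
  }
  counts
}

# per-pixel Tamura triple with clamped-coordinate (replicate) border handling
oracle_tamura_hist <- function(block) {
  h <- nrow(block); w <- ncol(block)
  gv <- function(y, x) block[min(max(y, 1), h), min(max(x, 1), w)]
  amean <- function(y, x, half) {
    s <- 0
    for (yy in (y - half):(y + half - 1))
      for (xx in (x - half):(x + half - 1)) s <- s + gv(yy, xx)
    s / (2 * half)^2
  }
  eps <- 1e-12
  counts <- numeric(512)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      best_e <- -1; best_k <- 1
      for (k in 1:5) {
        half <- 2^(k - 1)
        eh <- abs(amean(y, x + half, half) - amean(y, x - half, half))
        ev <- abs(amean(y + half, x, half) - amean(y - half, x, half))
        ek <- max(eh, ev)
        if (ek > best_e) { best_e <- ek; best_k <- k }
      }
      lvl_coarse <- min(7, 2 * (best_k - 1))

      v <- numeric(0)
      for (yy in (y - 6):(y + 6))
        for (xx in (x - 6):(x + 6)) v <- c(v, gv(yy, xx))
      n_win <- length(v)
      s1 <- sum(v); s2 <- sum(v^2); s3 <- sum(v^3); s4 <- sum(v^4)
      mu <- s1 / n_win
      m2 <- max(s2 / n_win - mu^2, 0)
      m4 <- s4 / n_win - 4 * mu * s3 / n_win + 6 * mu^2 * s2 / n_win - 3 * mu^4
      kurt <- m4 / (m2^2 + eps)
      contrast <- if (m2 == 0) 0 else sqrt(m2) / (kurt + eps)^(1 / 4)
      lvl_contrast <- min(7, floor(min(contrast, 128) / 16))

      dh <- gv(y - 1, x + 1) + gv(y, x + 1) + gv(y + 1, x + 1) -
        gv(y - 1, x - 1) - gv(y, x - 1) - gv(y + 1, x - 1)
      dv <- gv(y - 1, x - 1) + gv(y - 1, x) + gv(y - 1, x + 1) -
        gv(y + 1, x - 1) - gv(y + 1, x) - gv(y + 1, x + 1)
      if ((abs(dh) + abs(dv)) / 2 > 12) {
        theta <- if (dh == 0) {
          0  # atan(+/-Inf) + pi/2 is pi or 0; both wrap to 0 mod pi
        } else {
          t0 <- atan(dv / dh) + pi / 2
          if (t0 >= pi) t0 - pi else t0
        }
        lvl_dir <- min(7, floor(theta / pi * 8))
        idx <- 64 * lvl_coarse + 8 * lvl_contrast + lvl_dir
        counts[idx + 1] <- counts[idx + 1] + 1
      }
    }
  }
  counts
}

# straight-from-formula metric oracles on L1-normalized vectors
oracle_metric <- function(hc, gc, metric) {
  H <- hc / sum(hc); G <- gc / sum(gc)
  eps <- 1e-12
  switch(metric,
    euclidean = sqrt(sum((H - G)^2)),
    intersection = 1 - sum(pmin(H, G)),
    jsd = {
      s <- 0
      for (m in seq_along(H)) {
        if (H[m] > 0) s <- s + H[m] * log(2 * H[m] / (H[m] + G[m]))
        if (G[m] > 0) s <- s + G[m] * log(2 * G[m] / (H[m] + G[m]))
      }
      s
    },
    rel_bin_dev = sum((H - G)^2 / ((H + G) / 2 + eps)),
    rel_dev = sqrt(sum((H - G)^2)) /
      ((sqrt(sum(H^2)) + sqrt(sum(G^2))) / 2 + eps)
  )
}

# brute-force rectangle-overlap test over all blocks
oracle_blocks_intersecting <- function(grid, x, y, w, h) {
  hits <- data.frame(row = integer(0), col = integer(0))
  for (r in seq_len(grid$n_rows) - 1) {
    for (cc in seq_len(grid$n_cols) - 1) {
      bx0 <- cc * grid$block_size; by0 <- r * grid$block_size
      bx1 <- bx0 + grid$block_size; by1 <- by0 + grid$block_size
      if (x < bx1 && bx0 < x + w && y < by1 && by0 < y + h)
        hits <- rbind(hits, data.frame(row = r, col = cc))
    }
  }
  hits
}

block_set_key <- function(df) sort(paste(df$row, df$col, sep = ","))

# mean gray level of a set of blocks on an RGB image
mean_block_gray <- function(image, grid, blocks) {
  vals <- vapply(seq_len(nrow(blocks)), function(i) {
    mean(as_gray(block_pixels(image, grid, blocks$row[i], blocks$col[i])))
  }, numeric(1))
  mean(vals)
}
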