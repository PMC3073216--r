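test_that("gray histogram counts intensities exactly", {
  blk <- matrix(128L, 70, 70)
  h <- gray_histogram(blk)
  expect_equal(h$counts[129], 4900)
  expect_equal(sum(h$counts), 4900)

  blk2 <- matrix(255L, 70, 70); blk2[1, 1] <- 0L
  h2 <- gray_histogram(blk2)
  expect_equal(h2$counts[1], 1)
  expect_equal(h2$counts[256], 4899)

  expect_error(gray_histogram(matrix(integer(0), 0, 0)), "empty")
  expect_error(gray_histogram(random_rgb_block(5, 5)), "single-channel")
})

test_that("color histogram uses R-major 8x8x8 binning", {
  black <- array(0L, dim = c(70, 70, 3))
  expect_equal(color_histogram(black)$counts[1], 4900)

  red <- array(0L, dim = c(70, 70, 3)); red[, , 1] <- 255L
  h <- color_histogram(red)
  expect_equal(h$counts[448 + 1], 4900)  # 64 * floor(255/32) = 448
  expect_equal(sum(h$counts), 4900)

  expect_error(color_histogram(matrix(0L, 5, 5)), "3-channel")
})

test_that("LBP uses strict comparison and excludes the border", {
  const <- matrix(77L, 70, 70)
  h <- lbp_histogram(const)
  expect_equal(h$counts[1], 68 * 68)  # equal neighbors give bit 0
  expect_equal(sum(h$counts), 68 * 68)

  tiny <- matrix(255L, 3, 3); tiny[2, 2] <- 0L
  h2 <- lbp_histogram(tiny)
  expect_equal(h2$counts[256], 1)  # all 8 neighbors larger -> code 255
  expect_equal(sum(h2$counts), 1)

  expect_error(lbp_histogram(matrix(0L, 2, 5)), "at least 3")
})

test_that("Sobel histogram matches the analytic step-edge response", {
  const <- matrix(13L, 70, 70)
  h <- sobel_histogram(const)
  expect_equal(h$counts[1], 68 * 68)

  # ideal vertical step edge 0|255: |Gx| = 4*255 on the edge columns
  step <- cbind(matrix(0L, 9, 5), matrix(255L, 9, 5))
  h2 <- sobel_histogram(step)
  expect_gt(h2$counts[floor(512 / sqrt(2)) + 1], 0)  # bin 362
  expect_equal(sum(h2$counts), 7 * 8)

  expect_error(sobel_histogram(matrix(0L, 5, 2)), "at least 3")
})

test_that("Tamura histogram handles degenerate and oriented textures", {
  # constant block: zero contrast everywhere, no gradient -> empty histogram
  const <- matrix(100L, 16, 16)
  expect_equal(sum(tamura_histogram(const)$counts), 0)

  # 2-px vertical stripes: horizontal gradient only, so every defined pixel
  # falls in the same directionality level (theta = pi/2 -> level 4)
  stripes <- matrix(0L, 16, 16)
  stripes[, rep(c(FALSE, FALSE, TRUE, TRUE), 4)] <- 255L
  h <- tamura_histogram(stripes)
  expect_gt(sum(h$counts), 0)
  dir_levels <- unique((which(h$counts > 0) - 1) %% 8)
  expect_equal(dir_levels, 4)

  expect_error(tamura_histogram(matrix(0L, 5, 5)), "at least 8")
})

test_that("each feature matches its brute-force oracle on random blocks", {
  set.seed(42)
  for (i in 1:3) {
    blk <- random_gray_block(10, 10)
    expect_equal(gray_histogram(blk)$counts, oracle_gray_hist(blk))
    expect_equal(lbp_histogram(blk)$counts, oracle_lbp_hist(blk))
    expect_equal(sobel_histogram(blk)$counts, oracle_sobel_hist(blk))
    rgb <- random_rgb_block(10, 10)
    expect_equal(color_histogram(rgb)$counts, oracle_color_hist(rgb))
  }
  blk <- random_gray_block(10, 10)
  expect_equal(tamura_histogram(blk)$counts, oracle_tamura_hist(blk))
})

test_that("extract_block_features composes the per-feature operations", {
  set.seed(7)
  img <- array(sample(0:255, 140 * 210 * 3, replace = TRUE),
               dim = c(140, 210, 3))
  grid <- partition_image(210, 140, 70)
  bf <- extract_block_features(img, grid, 1, 2)
  px <- block_pixels(img, grid, 1, 2)
  gpx <- as_gray(px)
  expect_equal(bf$gray$counts, gray_histogram(gpx)$counts)
  expect_equal(bf$color$counts, color_histogram(px)$counts)
  expect_equal(bf$lbp$counts, lbp_histogram(gpx)$counts)
  expect_equal(bf$tamura$counts, tamura_histogram(gpx)$counts)
  expect_equal(bf$sobel$counts, sobel_histogram(gpx)$counts)

  # determinism
  bf2 <- extract_block_features(img, grid, 1, 2)
  expect_identical(bf, bf2)
})

test_that("grayscale images get a zero-padded degenerate color histogram", {
  set.seed(8)
  img <- matrix(sample(0:255, 140 * 140, replace = TRUE), 140, 140)
  grid <- partition_image(140, 140, 70)
  bf <- extract_block_features(img, grid, 0, 0)
  expect_true(isTRUE(attr(bf$color, "degenerate_color")))
  expect_equal(bf$color$counts[1:256], bf$gray$counts)
  expect_equal(bf$color$counts[257:512], rep(0, 256))
})

test_that("features are translation consistent across grid positions", {
  set.seed(9)
  blk <- random_gray_block(70, 70)
  img <- matrix(0L, 140, 210)
  img[1:70, 1:70] <- blk          # block (0,0)
  img[71:140, 141:210] <- blk     # block (1,2)
  grid <- partition_image(210, 140, 70)
  f1 <- extract_block_features(img, grid, 0, 0)
  f2 <- extract_block_features(img, grid, 1, 2)
  expect_identical(f1, f2)
})

test_that("image inversion complements tie-free LBP codes", {
  set.seed(10)
  blk <- matrix(sample(0:255, 81), 9, 9)  # distinct values: no ties
  h <- lbp_histogram(blk)$counts
  h_inv <- lbp_histogram(255L - blk)$counts
  expect_equal(h_inv, rev(h))  # code k maps to 255 - k
})
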