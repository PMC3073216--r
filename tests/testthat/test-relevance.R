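test_that("reassign_zero_minimum raises all global minima to the runner-up", {
  expect_equal(as.vector(reassign_zero_minimum(matrix(c(0, 2, 4), 1))),
               c(2, 2, 4))
  expect_equal(as.vector(reassign_zero_minimum(matrix(c(5, 5, 5), 1))),
               c(5, 5, 5))
  expect_equal(as.vector(reassign_zero_minimum(matrix(c(0, 0, 3), 1))),
               c(3, 3, 3))
  expect_error(reassign_zero_minimum(matrix(1)), "at least 2")
})

test_that("normalize_to_similarity inverts the range onto [0, N_scale]", {
  s <- normalize_to_similarity(matrix(c(2, 2, 4), 1), N_scale = 1)
  expect_equal(as.vector(s), c(1, 1, 0))

  expect_equal(as.vector(normalize_to_similarity(matrix(7, 2, 2))),
               rep(0, 4))

  set.seed(31)
  m <- matrix(runif(30, 1, 9), 5, 6)
  s2 <- normalize_to_similarity(m, N_scale = 2.5)
  expect_equal(min(s2), 0)
  expect_equal(max(s2), 2.5)
  expect_equal(which.max(s2), which.min(m))  # min distance -> max similarity
})

test_that("peak promotion favors single strong peaks", {
  expect_equal(peak_promotion_weight(matrix(0.8, 4, 4)), 0.64)  # M^2
  expect_equal(peak_promotion_weight(matrix(0, 4, 4)), 0)

  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(peak_promotion_weight(single), 1)

  multi <- matrix(0, 5, 5)
  multi[1, 1] <- 1; multi[1, 5] <- 1            # two global peaks
  multi[3, c(1, 3, 5)] <- 0.9; multi[5, c(1, 3, 5)] <- 0.9
  expect_equal(peak_promotion_weight(multi), 0.01)
  expect_lt(peak_promotion_weight(multi), peak_promotion_weight(single))
})

test_that("integrate_maps is an exact weighted cellwise sum", {
  m1 <- matrix(1:6, 2, 3)
  expect_equal(unclass(integrate_maps(list(m1), 1))[, ], m1[, ])
  expect_equal(unclass(integrate_maps(list(m1, m1), c(1, 1)))[, ], 2 * m1[, ])

  set.seed(32)
  maps <- lapply(1:4, function(i) matrix(runif(12), 3, 4))
  w <- runif(4)
  naive <- matrix(0, 3, 4)
  for (i in 1:4) for (r in 1:3) for (cc in 1:4)
    naive[r, cc] <- naive[r, cc] + w[i] * maps[[i]][r, cc]
  expect_equal(unclass(integrate_maps(maps, w))[, ], naive)

  expect_error(integrate_maps(maps, w[1:3]), "one weight per map")
  expect_error(integrate_maps(list(m1, matrix(0, 3, 3)), c(1, 1)),
               "mismatched shapes")
})

test_that("relevance_map is the rescaled (T - D)/N difference", {
  T_map <- matrix(c(4, 2, 0, 2), 2, 2)  # [[4,0],[2,2]] row-wise
  D_map <- matrix(c(0, 2, 4, 2), 2, 2)
  r <- relevance_map(T_map, D_map, 2)
  expect_equal(unclass(r)[, ], matrix(c(1, 0.5, 0, 0.5), 2, 2))

  zeros <- matrix(0, 2, 2)
  expect_equal(unclass(relevance_map(T_map, zeros, 2))[, ],
               unclass(relevance_map(T_map, zeros, 5))[, ])  # scale-free
  expect_equal(unclass(relevance_map(T_map, T_map, 2))[, ], zeros)

  expect_error(relevance_map(T_map, matrix(0, 3, 3), 2), "different shapes")
})

test_that("threshold_rois takes the ceiling count with row-major ties", {
  set.seed(33)
  r <- matrix(runif(100), 10, 10)
  expect_equal(nrow(threshold_rois(r, 0.1)), 10)
  expect_equal(nrow(threshold_rois(r, 1.0)), 100)

  # distinct scores: agrees with naive sort-and-take
  top <- threshold_rois(r, 0.07)
  naive_top7 <- sort(as.vector(r), decreasing = TRUE)[1:7]
  expect_equal(sort(top$score, decreasing = TRUE), naive_top7)

  # all-tied scores resolve in row-major order
  flat <- matrix(1, 4, 4)
  t3 <- threshold_rois(flat, 3 / 16)
  expect_equal(t3$row, c(0, 0, 0))
  expect_equal(t3$col, c(0, 1, 2))

  expect_error(threshold_rois(r, 0), "fraction")
  expect_error(threshold_rois(r, 1.5), "fraction")
})

test_that("build_distance_map matches per-block recomputation and zeroes the example cell", {
  set.seed(34)
  img <- matrix(sample(0:255, 60 * 80, replace = TRUE), 60, 80)
  grid <- partition_image(80, 60, 20)
  gf <- characterize_grid(img, grid)
  ex <- features_at(gf, 1, 2)
  dm <- build_distance_map(gf, ex, "gray", "euclidean")
  expect_equal(dm[2, 3], 0)
  for (r in seq_len(grid$n_rows) - 1) {
    for (cc in seq_len(grid$n_cols) - 1) {
      expect_equal(dm[r + 1, cc + 1],
                   hist_distance(features_at(gf, r, cc)$gray, ex$gray,
                                 "euclidean"))
    }
  }
})

test_that("uniform images yield all-zero distance and relevance maps", {
  img <- matrix(200L, 120, 120)
  sc <- score_slide(img, c(0, 0), c(1, 1), block_size = 40)
  expect_equal(max(abs(sc$relevance)), 0)
  gf <- characterize_grid(img, partition_image(120, 120, 40))
  dm <- build_distance_map(gf, features_at(gf, 0, 0), "lbp", "jsd")
  expect_equal(max(abs(dm)), 0)
})

test_that("score_slide is deterministic and validates its examples", {
  set.seed(35)
  img <- array(sample(0:255, 120 * 120 * 3, replace = TRUE),
               dim = c(120, 120, 3))
  s1 <- score_slide(img, c(0, 0), c(2, 2), block_size = 40)
  s2 <- score_slide(img, c(0, 0), c(2, 2), block_size = 40)
  expect_identical(s1$relevance, s2$relevance)
  expect_error(score_slide(img, c(0, 0), c(0, 0), block_size = 40),
               "must differ")
})

test_that("swapping target and distractor inverts the planted-class ranking", {
  spec <- synthetic_slide_spec(width = 490, height = 490, n_target_regions = 2,
                               n_distractor_regions = 2, seed = 5)
  sl <- generate_slide(spec)
  gt <- sl$ground_truth
  t_ex <- unlist(gt$target_blocks[1, c("row", "col")])
  d_ex <- unlist(gt$distractor_blocks[1, c("row", "col")])
  gf <- characterize_grid(sl$image, sl$grid)
  fwd <- score_slide(sl$image, t_ex, d_ex, grid_features = gf)
  rev_ <- score_slide(sl$image, d_ex, t_ex, grid_features = gf)
  planted <- rbind(gt$target_blocks, gt$distractor_blocks)
  idx <- cbind(planted$row + 1, planted$col + 1)
  expect_lt(cor(rank(fwd$relevance[idx]), rank(rev_$relevance[idx])), 0)
})

test_that("grayscale slides integrate without the duplicate color feature", {
  set.seed(36)
  img <- matrix(sample(0:255, 120 * 120, replace = TRUE), 120, 120)
  sc <- score_slide(img, c(0, 0), c(2, 2), block_size = 40)
  expect_false("color" %in% sc$features)
  expect_equal(sc$n_maps, 4 * 5)
})
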