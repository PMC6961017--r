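test_that("superpixel segmentation partitions the image at the requested granularity", {
  img <- matrix(0.5, 64, 64)
  lab <- compute_superpixels(img, graph_config(A = 64, downscale = 1))
  k <- max(lab)
  # constant image: near-regular grid of ~64 compact superpixels
  expect_gt(k, 40)
  expect_lt(k, 90)
  expect_setequal(unique(as.integer(lab)), seq_len(k))
  sizes <- table(lab)
  expect_identical(sum(sizes), 64L * 64L)          # partition
  expect_true(all(sizes > 0))
  expect_lt(max(sizes), 4 * 64)                     # compact, no runaway label

  # degenerate: one superpixel covering everything
  lab1 <- compute_superpixels(img, graph_config(A = 64 * 64, downscale = 1))
  expect_identical(max(lab1), 1L)
  expect_true(all(lab1 == 1L))
})

test_that("segmentation rejects invalid inputs", {
  expect_error(compute_superpixels(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(compute_superpixels(matrix(0.5, 8, 8), graph_config(A = 256)),
               "exceeds")
  expect_error(graph_config(A = 2), "A must")
  expect_error(graph_config(D = 0), "D must")
  expect_error(graph_config(W = 0), "W must")
  expect_error(graph_config(downscale = 1.5), "downscale")
})

test_that("node features are per-superpixel means of the image", {
  set.seed(4)
  img <- matrix(runif(48 * 48), 48, 48)
  lab <- compute_superpixels(img, graph_config(A = 144, downscale = 1))
  f <- mean_node_features(lab, img)
  # brute-force pixel loop
  for (k in seq_len(max(lab))) {
    expect_equal(f[k, 1], mean(img[lab == k]), tolerance = 1e-12)
  }
  expect_true(all(f >= 0 & f <= 1))
  expect_error(mean_node_features(lab, img[1:10, ]), "differ")

  # constant regions give their constant back
  img2 <- matrix(0.7, 16, 16)
  lab2 <- matrix(1L, 16, 16)
  expect_equal(as.numeric(mean_node_features(lab2, img2)), 0.7)
  img3 <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  expect_equal(as.numeric(mean_node_features(lab2, img3)), 0.5)
})

test_that("edge construction follows hop distance with loops and antisymmetric u", {
  # three superpixels in a row: 1 - 2 - 3
  strips <- cbind(matrix(1L, 6, 4), matrix(2L, 6, 4), matrix(3L, 6, 4))
  e1 <- build_edges(strips, D = 1, coord_scale = 4)
  expect_identical(nrow(e1$edges), 7L)   # 3 loops + (1,2),(2,1),(2,3),(3,2)
  e2 <- build_edges(strips, D = 2, coord_scale = 4)
  expect_identical(nrow(e2$edges), 9L)   # adds (1,3),(3,1)
  key1 <- paste(e1$edges[, 1], e1$edges[, 2])
  key2 <- paste(e2$edges[, 1], e2$edges[, 2])
  expect_true(all(key1 %in% key2))       # monotone in D
  expect_true(all(paste(1:3, 1:3) %in% key1))  # loops

  # two adjacent superpixels: 2 loops + 2 directed edges
  two <- cbind(matrix(1L, 4, 4), matrix(2L, 4, 4))
  e <- build_edges(two, D = 1, coord_scale = 4)
  expect_identical(nrow(e$edges), 4L)

  # pseudo-coordinates: loops at exactly (0,0); x rightward, y upward
  loop <- e1$edges[, 1] == e1$edges[, 2]
  expect_true(all(e1$u[loop, ] == 0))
  i12 <- which(e1$edges[, 1] == 1 & e1$edges[, 2] == 2)
  expect_equal(unname(e1$u[i12, 1]), 1)  # 4 px to the right / coord_scale 4
  expect_equal(unname(e1$u[i12, 2]), 0)
  i21 <- which(e1$edges[, 1] == 2 & e1$edges[, 2] == 1)
  expect_identical(e1$u[i21, ], -e1$u[i12, ])
  # vertical neighbours point up in u
  vert <- rbind(matrix(2L, 4, 6), matrix(1L, 4, 6))  # 1 below 2
  ev <- build_edges(vert, D = 1, coord_scale = 4)
  iup <- which(ev$edges[, 1] == 1 & ev$edges[, 2] == 2)
  expect_gt(ev$u[iup, 2], 0)
})

test_that("mask targets are W-scaled coverage fractions", {
  lab <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  mask <- cbind(matrix(1L, 8, 4), matrix(0L, 8, 4))
  expect_equal(mask_to_targets(lab, mask, W = 100), c(100, 0))
  half <- mask; half[1:4, 5:8] <- 1L
  expect_equal(mask_to_targets(lab, half, W = 1), c(1, 0.5))
  expect_error(mask_to_targets(lab, mask * 2L, W = 1), "binary")
  expect_error(mask_to_targets(lab, mask[1:4, ], W = 1), "differ")
})

test_that("graph construction is deterministic and satisfies the invariants", {
  sc <- gen_scene(scene_spec(seed = 2, subject_id = 3))
  cfg <- graph_config(A = 256, D = 2, W = 100, downscale = 1)
  g1 <- build_graph(sc$image, sc$mask, cfg)
  g2 <- build_graph(sc$image, sc$mask, cfg)
  expect_identical(g1, g2)
  expect_valid_graph(g1)
  expect_gte(g1$n_nodes, 20)
  expect_identical(sum(table(g1$labels)), length(sc$image))

  # edge set grows monotonically with D
  gd1 <- build_graph(sc$image, NULL, graph_config(A = 256, D = 1, downscale = 1))
  k1 <- paste(gd1$edges[, 1], gd1$edges[, 2])
  k2 <- paste(g1$edges[, 1], g1$edges[, 2])
  expect_true(all(k1 %in% k2))

  # all-zero mask gives all-zero targets
  g0 <- build_graph(sc$image, matrix(0L, nrow(sc$image), ncol(sc$image)), cfg)
  expect_true(all(g0$targets == 0))
})

test_that("downscaling is applied before segmentation", {
  sc <- gen_scene(scene_spec(seed = 9, subject_id = 1, size = c(128, 128)))
  g <- build_graph(sc$image, sc$mask, graph_config(A = 64, D = 1, W = 1,
                                                   downscale = 0.5))
  expect_identical(dim(g$labels), c(64L, 64L))
  expect_equal(g$scale, 0.5)
  expect_valid_graph(g)
})
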