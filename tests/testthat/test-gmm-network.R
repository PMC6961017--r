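test_that("filter response evaluates the Gaussian mixture", {
  f1 <- gmm_filter(1, c(0, 0), c(1, 1))
  expect_equal(filter_response(f1, c(0, 0)), 1)
  f0 <- gmm_filter(c(0, 0), rbind(c(1, 0), c(0, 1)), matrix(1, 2, 2))
  for (u in list(c(0, 0), c(1, 2), c(-3, 0.5)))
    expect_equal(filter_response(f0, u), 0)
  # term-by-term evaluation of a 2-component mixture
  f2 <- gmm_filter(c(1, -2), rbind(c(1, 0), c(0, 1)), matrix(0.5, 2, 2))
  u <- c(0.5, 0.5)
  expected <- 1 * exp(-0.5 * ((0.5 - 1)^2 / 0.5 + 0.5^2 / 0.5)) +
    (-2) * exp(-0.5 * (0.5^2 / 0.5 + (0.5 - 1)^2 / 0.5))
  expect_equal(filter_response(f2, u), expected, tolerance = 1e-14)
  expect_error(gmm_filter(1, c(0, 0), c(1, 0)), "variance")
})

test_that("layer forward reduces to bias for zero weights and to loop response for isolated nodes", {
  g <- rand_graph(1, K = 12)
  l <- gmm_layer(1, 3, J = 4, activation = "identity")
  l$b[1, ] <- c(-1, 0.5, 2)
  out <- layer_forward(l, g)
  expect_equal(out, matrix(rep(c(-1, 0.5, 2), each = 12), 12, 3))

  # a single node with only its loop: h = b + phi(0,0) * f
  iso <- manual_graph(rbind(c(1, 1)), rbind(c(0, 0)), f = 0.8)
  l1 <- gmm_layer(1, 1, J = 2, activation = "identity")
  l1$g[] <- c(0.3, -0.7); l1$mux[] <- c(0.2, -0.4); l1$muy[] <- c(0, 1)
  l1$b[] <- 0.1
  phi00 <- sum(l1$g * exp(-0.5 * (l1$mux^2 / exp(l1$lvx) +
                                  l1$muy^2 / exp(l1$lvy))))
  expect_equal(as.numeric(layer_forward(l1, iso)), 0.1 + phi00 * 0.8,
               tolerance = 1e-14)
})

test_that("layer and network forward match the brute-force oracle", {
  for (seed in 1:4) {
    g <- rand_graph(seed, K = 20, N = 3)
    net <- rand_net(seed * 7, c(3, 2))
    expect_lt(max(abs(network_forward(net, g) - oracle_net(net, g))), 1e-10)
  }
  # verification architecture composed of two layers
  g <- rand_graph(42, K = 25, N = 1)
  net <- rand_net(5, c(1, 10, 1))
  expect_lt(max(abs(network_forward(net, g) - oracle_net(net, g))), 1e-10)
  # one-layer network equals the layer operation
  g1 <- rand_graph(3, K = 10, N = 2)
  net1 <- rand_net(9, c(2, 3))
  expect_equal(network_forward(net1, g1),
               layer_forward(net1$layers[[1]], g1))
  expect_error(network_forward(net1, g1, matrix(0, 10, 5)), "channels")
})

test_that("pre-activation output is linear in the input features", {
  g <- rand_graph(8, K = 15, N = 2)
  net <- rand_net(4, c(2, 3))
  net$layers[[1]]$activation <- "identity"
  net$layers[[1]]$b[] <- 0
  f1 <- matrix(rnorm(30), 15, 2)
  f2 <- matrix(rnorm(30), 15, 2)
  lhs <- network_forward(net, g, 2 * f1 - 0.5 * f2)
  rhs <- 2 * network_forward(net, g, f1) - 0.5 * network_forward(net, g, f2)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("output only depends on features inside the neighborhood", {
  g <- rand_graph(17, K = 15, N = 1)
  net <- rand_net(6, c(1, 2))
  base <- network_forward(net, g)
  t0 <- 7L
  f2 <- g$features
  f2[t0, 1] <- f2[t0, 1] + 1
  out2 <- network_forward(net, g, f2)
  changed <- which(rowSums(abs(out2 - base)) > 1e-12)
  neighbours_of_t <- sort(g$edges[g$edges[, 2] == t0, 1])
  expect_true(all(changed %in% neighbours_of_t))
})

test_that("relabeling nodes permutes the output identically", {
  g <- rand_graph(23, K = 14, N = 1)
  net <- rand_net(2, c(1, 3, 1))
  out <- network_forward(net, g)
  set.seed(33)
  p <- sample.int(g$n_nodes)   # node i becomes p[i]
  gp <- g
  gp$features <- g$features[order(p), , drop = FALSE]
  gp$targets <- g$targets[order(p)]
  gp$centroids <- g$centroids[order(p), ]
  gp$edges <- matrix(p[g$edges], ncol = 2)
  ord <- order(gp$edges[, 1], gp$edges[, 2])
  gp$edges <- gp$edges[ord, ]
  gp$u <- g$u[ord, ]
  outp <- network_forward(net, gp)
  expect_lt(max(abs(outp[p, , drop = FALSE] - out)), 1e-10)
})

test_that("parameter count follows MN(J(2d+1)+1) and matches enumeration", {
  one <- gmm_network(list(gmm_layer(1, 10, J = 4)))
  expect_identical(param_count(one), 210)
  expect_identical(param_count(build_architecture("verification")), 420)
  expect_identical(param_count(build_architecture("main")),
                   (1 * 20 + 20 * 10 + 10 * 5 + 5 * 1) * 21)
  for (name in c("verification", "main", "main_plus")) {
    net <- build_architecture(name)
    expect_identical(length(gmmconv:::params_to_vec(net)), as.integer(param_count(net)))
    expect_identical(length(coef(gmmnet_train(init_glorot(net, 1),
                                              rand_graph(1, K = 6),
                                              config = train_config(epochs = 0)))),
                     as.integer(param_count(net)))
  }
})

test_that("Glorot initialization is deterministic, bounded and centred", {
  net <- build_architecture("verification")
  a <- init_glorot(net, 11)
  b <- init_glorot(net, 11)
  expect_identical(a, b)
  expect_false(identical(a, init_glorot(net, 12)))
  for (l in a$layers) {
    bound <- sqrt(6 / (l$N * l$J + l$M * l$J))
    expect_true(all(abs(l$g) <= bound))
    expect_true(all(abs(l$mux) <= 1) && all(abs(l$muy) <= 1))
    expect_true(all(l$lvx == 0) && all(l$lvy == 0))
    expect_true(all(l$b == 0))
  }
  # Monte-Carlo: mean of 10^4 Glorot draws within 3 standard errors of 0
  big <- init_glorot(gmm_network(list(gmm_layer(50, 50, J = 4))), 5)
  gs <- as.numeric(big$layers[[1]]$g)
  bound <- sqrt(6 / (50 * 4 + 50 * 4))
  se <- bound / sqrt(3) / sqrt(length(gs))
  expect_lt(abs(mean(gs)), 3 * se)
  expect_identical(length(gs), 10000L)
})
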