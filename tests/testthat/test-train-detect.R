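make_training_set <- function(n, seed, K = 12) {
  lapply(seq_len(n), function(i) {
    g <- rand_graph(seed + i, K = K)
    g$targets <- oriented_targets(g, g$features, 0)
    g
  })
}

test_that("zero-step training returns the initial parameters and empty history", {
  net <- init_glorot(build_architecture("verification"), 3)
  fit <- gmmnet_train(net, make_training_set(2, 100),
                      config = train_config(epochs = 0))
  expect_identical(gmmconv:::params_to_vec(fit$network),
                   gmmconv:::params_to_vec(net))
  expect_identical(nrow(fit$history), 0L)
  untargeted <- rand_graph(1)
  untargeted$targets <- NULL
  expect_error(gmmnet_train(net, list(untargeted)), "targets")
})

test_that("training reduces the error and records checkpoints on schedule", {
  train <- make_training_set(6, 200)
  val <- make_training_set(2, 300)
  net <- init_glorot(build_architecture("verification"), 7)
  mse0 <- network_mse(net, train)
  fit <- gmmnet_train(net, train, val,
                      config = train_config(learning_rate = 1e-3,
                                            epochs = 250, eval_interval = 50,
                                            seed = 5))
  expect_identical(fit$history$epoch, c(50L, 100L, 150L, 200L, 250L))
  expect_lt(network_mse(fit$network, train), mse0)
  # selected checkpoint achieves the minimum recorded validation error
  expect_equal(fit$best_error, min(fit$history$val_mse))
  expect_identical(fit$best_epoch,
                   fit$history$epoch[which.min(fit$history$val_mse)])
  # determinism
  fit2 <- gmmnet_train(net, train, val,
                       config = train_config(learning_rate = 1e-3,
                                             epochs = 250, eval_interval = 50,
                                             seed = 5))
  expect_identical(coef(fit), coef(fit2))
})

test_that("mini-batch training is deterministic and trains comparably", {
  train <- make_training_set(8, 400)
  net <- init_glorot(build_architecture("verification"), 9)
  cfg <- train_config(learning_rate = 1e-3, epochs = 100, eval_interval = 50,
                      seed = 4, batch_size = 3)
  f1 <- gmmnet_train(net, train, config = cfg)
  f2 <- gmmnet_train(net, train, config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_lt(network_mse(f1$final_network, train), network_mse(net, train))
})

test_that("fit methods expose predictions, residuals and coefficients", {
  train <- make_training_set(3, 500)
  net <- init_glorot(build_architecture("verification"), 2)
  fit <- gmmnet_train(net, train,
                      config = train_config(epochs = 50, eval_interval = 50))
  g <- train[[1]]
  pred <- predict(fit, g)
  expect_identical(dim(pred), c(as.integer(g$n_nodes), 1L))
  expect_equal(as.numeric(residuals(fit, g)),
               as.numeric(g$targets) - as.numeric(pred))
  expect_identical(length(coef(fit)), 420L)
  expect_output(print(fit), "selected checkpoint")
})

test_that("argmax detection picks the highest node with lowest-id ties", {
  g <- rand_graph(600, K = 10)
  out <- runif(10)
  out[7] <- 2
  det <- detect_node(out, g)
  expect_identical(det$node, 7L)
  expect_equal(det$score, 2)
  expect_equal(unname(det$centroid), unname(g$centroids[7, ]))
  # all-equal outputs: first (lowest-id) node wins
  expect_identical(detect_node(rep(1, 10), g)$node, 1L)
  # independent linear-scan oracle
  for (seed in 1:5) {
    set.seed(seed)
    o <- rnorm(10)
    best <- 1
    for (i in 2:10) if (o[i] > o[best]) best <- i
    expect_identical(detect_node(o, g)$node, best)
  }
  # invariant to adding a constant
  expect_identical(detect_node(out + 100, g)$node, det$node)
  expect_error(detect_node(numeric(0), g), "empty")
})

test_that("hit evaluation uses the enlarged bounding box inclusively", {
  bbox <- c(xmin = 40, ymin = 30, xmax = 60, ymax = 50)
  expect_true(evaluate_hit(c(50, 40), bbox, 16))
  expect_true(evaluate_hit(c(60 + 15, 40), bbox, 16))   # sqrt(A)-1 outside
  expect_true(evaluate_hit(c(60 + 16, 40), bbox, 16))   # boundary inclusive
  expect_false(evaluate_hit(c(60 + 17, 40), bbox, 16))
  expect_false(evaluate_hit(c(200, 200), bbox, 16))
  g <- rand_graph(700, K = 5)
  det <- detect_node(c(0, 0, 1, 0, 0), g)
  res <- evaluate_hit(det, c(0, 0, 20, 20), 5)
  expect_type(res, "logical")
  expect_identical(attr(res, "detection")$hit, as.logical(res))
})

test_that("rotation-bank decision rules behave as documented", {
  net <- rand_net(44, c(1, 3, 1))
  g <- rand_graph(800, K = 12)

  # singleton bank reduces to plain detection
  b1 <- rotation_bank(net, 1)
  d1 <- ensemble_detect_max(b1, g)
  d0 <- detect_node(network_forward(net, g), g)
  expect_identical(d1$node, d0$node)
  expect_equal(d1$score, d0$score)

  bank <- rotation_bank(net, 7)
  # independent recount: evaluate every network, replicate the tie rules
  ord <- order(abs(bank$angles), bank$angles)
  best <- NULL
  for (i in ord) {
    o <- network_forward(bank$networks[[i]], g)
    sc <- max(o)
    if (is.null(best) || sc > best$score)
      best <- list(score = sc, angle = bank$angles[i],
                   node = which.max(o))
  }
  dm <- ensemble_detect_max(bank, g)
  expect_equal(dm$score, best$score)
  expect_equal(dm$angle, best$angle)
  expect_identical(dm$node, best$node)

  # the equivariance route: on a graph rotated by a bank angle, the rotated
  # network reproduces the base network's response
  th <- bank$angles[6]
  rot <- g
  rot$u <- g$u %*% t(gmmconv:::rotation_matrix(th))
  o_base <- network_forward(net, g)
  o_rot <- network_forward(bank$networks[[6]], rot)
  expect_lt(max(abs(o_rot - o_base)), 1e-9)

  # any-rule dominates max-rule on every trial (set inclusion)
  for (seed in 1:6) {
    gg <- rand_graph(900 + seed, K = 10)
    bbox <- c(gg$centroids[3, 1] - 1, gg$centroids[3, 2] - 1,
              gg$centroids[3, 1] + 1, gg$centroids[3, 2] + 1)
    max_hit <- isTRUE(evaluate_hit(ensemble_detect_max(bank, gg), bbox, 2))
    any_hit <- ensemble_detect_any(bank, gg, bbox, 2)
    if (max_hit) expect_true(any_hit)
  }
})

test_that("accuracy is the hit fraction", {
  expect_equal(detection_accuracy(c(TRUE, TRUE, TRUE, FALSE)), 0.75)
  expect_equal(detection_accuracy(rep(TRUE, 5)), 1)
  set.seed(3)
  hits <- runif(40) > 0.5
  expect_equal(detection_accuracy(hits), sum(hits) / 40)
  expect_error(detection_accuracy(logical(0)), "no detection")
})

test_that("named architectures have the documented shape", {
  v <- build_architecture("verification")
  expect_length(v$layers, 2)
  expect_identical(vapply(v$layers, function(l) l$activation, character(1)),
                   c("relu", "identity"))
  m <- build_architecture("main")
  expect_length(m$layers, 4)
  expect_identical(vapply(m$layers, function(l) l$M, integer(1)),
                   c(20L, 10L, 5L, 1L))
  expect_identical(m$layers[[4]]$activation, "identity")
  p <- build_architecture("main_plus")
  expect_length(p$layers, 5)
  expect_identical(p$layers[[1]]$M, 20L)
  expect_error(build_architecture("unknown"))
})

test_that("analytic gradients match central finite differences", {
  g <- rand_graph(3, K = 10, N = 1)
  g$targets <- runif(10)
  net <- rand_net(11, c(1, 3, 1))
  merged <- gmmconv:::merge_graphs(list(g))
  fw <- gmmconv:::net_forward_cpp(net, merged$edges, merged$u,
                                  merged$features, TRUE)
  dout <- 2 * merged$node_weight * (fw$out - merged$targets)
  gr <- gmmconv:::cpp_net_backward(gmmconv:::layers_for_cpp(net),
                                   merged$edges[, 1] - 1L,
                                   merged$edges[, 2] - 1L,
                                   merged$u[, 1], merged$u[, 2],
                                   fw$inputs, fw$pre, fw$z, as.matrix(dout))
  analytic <- gmmconv:::grads_to_vec(gr)
  v0 <- gmmconv:::params_to_vec(net)
  h <- 1e-5
  numeric_grad <- vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (network_mse(gmmconv:::vec_to_params(net, vp), list(g)) -
       network_mse(gmmconv:::vec_to_params(net, vm), list(g))) / (2 * h)
  }, numeric(1))
  rel <- abs(analytic - numeric_grad) / pmax(abs(numeric_grad), 1e-8)
  expect_lt(max(rel), 1e-4)
})
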