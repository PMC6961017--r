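# Fixture builders and independent oracles used across the suite.
# The oracles deliberately use plain nested loops and scalar arithmetic so
# they share no code path with the package's compiled kernels.

# A structurally valid random graph: random centroids, random symmetric
# adjacency, loops on every node, antisymmetric scaled pseudo-coordinates.
rand_graph <- function(seed, K = 20, N = 1, p_edge = 0.2) {
  set.seed(seed)
  cent <- cbind(runif(K, 0, 10), runif(K, 0, 10))
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  keep <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  edges <- rbind(cbind(seq_len(K), seq_len(K)), keep, keep[, 2:1, drop = FALSE])
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  storage.mode(edges) <- "integer"
  u <- cbind(cent[edges[, 2], 1] - cent[edges[, 1], 1],
             -(cent[edges[, 2], 2] - cent[edges[, 1], 2])) / 3
  u[edges[, 1] == edges[, 2], ] <- 0
  structure(list(n_nodes = K, features = matrix(runif(K * N), K, N),
                 edges = edges, u = u, centroids = cent, labels = NULL,
                 targets = runif(K), config = graph_config(downscale = 1),
                 scale = 1),
            class = "spxgraph")
}

# A hand-specified graph from explicit edge/pseudo-coordinate tables.
manual_graph <- function(edges, u, f) {
  structure(list(n_nodes = length(f), features = matrix(f, ncol = 1),
                 edges = matrix(as.integer(edges), ncol = 2),
                 u = matrix(u, ncol = 2),
                 centroids = cbind(seq_along(f), seq_along(f)),
                 labels = NULL, targets = NULL,
                 config = graph_config(downscale = 1), scale = 1),
            class = "spxgraph")
}

# Random network with randomized variances so every parameter kind is
# exercised; identity activation on the last layer, ReLU elsewhere.
rand_net <- function(seed, chain, J = 4) {
  nl <- length(chain) - 1
  layers <- lapply(seq_len(nl), function(i)
    gmm_layer(chain[i], chain[i + 1], J,
              if (i == nl) "identity" else "relu"))
  net <- init_glorot(gmm_network(layers), seed)
  set.seed(seed + 1)
  net$layers <- lapply(net$layers, function(l) {
    l$lvx <- array(runif(length(l$lvx), -0.5, 0.5), dim(l$lvx))
    l$lvy <- array(runif(length(l$lvy), -0.5, 0.5), dim(l$lvy))
    l
  })
  net
}

# Brute-force layer operation: explicit loops over nodes, edges, channel
# pairs and Gaussians, evaluating the mixture term by term.
oracle_layer <- function(layer, graph, f, transform = diag(2)) {
  K <- graph$n_nodes; M <- layer$M; N <- layer$N; J <- layer$J
  out <- matrix(0, K, M)
  for (m in seq_len(M)) {
    for (s in seq_len(K)) {
      acc <- sum(layer$b[, m])   # effective channel bias: sum of filter biases
      for (e in seq_len(nrow(graph$edges))) {
        if (graph$edges[e, 1] != s) next
        t <- graph$edges[e, 2]
        v <- as.numeric(transform %*% graph$u[e, ])
        for (n in seq_len(N)) {
          phi <- 0
          for (j in seq_len(J)) {
            q <- (v[1] - layer$mux[j, n, m])^2 / exp(layer$lvx[j, n, m]) +
                 (v[2] - layer$muy[j, n, m])^2 / exp(layer$lvy[j, n, m])
            phi <- phi + layer$g[j, n, m] * exp(-q / 2)
          }
          acc <- acc + phi * f[t, n]
        }
      }
      out[s, m] <- if (layer$activation == "relu") max(acc, 0) else acc
    }
  }
  out
}

oracle_net <- function(net, graph, f = graph$features) {
  for (l in net$layers) f <- oracle_layer(l, graph, f, net$transform)
  f
}

# Per-node oracle for the oriented-edge soft labels: scalar loop over the
# node's outgoing non-loop edges.
oracle_oriented <- function(graph, f, theta) {
  f <- as.numeric(f)
  h <- numeric(graph$n_nodes)
  for (s in seq_len(graph$n_nodes)) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(graph$edges))) {
      if (graph$edges[e, 1] != s || graph$edges[e, 2] == s) next
      alpha <- atan2(graph$u[e, 2], graph$u[e, 1])
      w <- sin(alpha - theta)
      if (w > 0) {
        num <- num + w^2 * (f[graph$edges[e, 2]] - f[s])
        den <- den + w^2
      }
    }
    h[s] <- if (den > 0) max(num / den, 0) else 0
  }
  h
}

# single 4-connected component check by flood fill
is_connected_mask <- function(mask) {
  on <- which(mask == 1)
  if (length(on) == 0) return(FALSE)
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  start <- arrayInd(on[1], dim(mask))
  queue <- list(start)
  seen[start] <- TRUE
  count <- 0
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    count <- count + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
          !seen[q[1], q[2]] && mask[q[1], q[2]] == 1) {
        seen[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- matrix(q, 1)
      }
    }
  }
  count == length(on)
}

# module invariants every superpixel graph must satisfy
expect_valid_graph <- function(g) {
  expect_false(any(duplicated(g$edges)))
  loops <- g$edges[, 1] == g$edges[, 2]
  expect_setequal(g$edges[loops, 1], seq_len(g$n_nodes))
  expect_true(all(g$u[loops, ] == 0))
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev_idx <- match(paste(g$edges[, 2], g$edges[, 1]), key)
  both <- !is.na(rev_idx)
  expect_identical(g$u[rev_idx[both], ], -g$u[both, ])
  expect_true(all(g$features >= 0 & g$features <= 1))
  if (!is.null(g$targets))
    expect_true(all(g$targets >= 0 & g$targets <= g$config$W))
  if (!is.null(g$labels)) {
    expect_identical(sort(unique(as.integer(g$labels))), seq_len(g$n_nodes))
  }
}
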