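.activations <- c(identity = 0L, relu = 1L)

#' A single continuous GMM filter
#'
#' A filter is a weighted sum of `J` axis-aligned Gaussians in the 2-D
#' pseudo-coordinate space: `phi(u) = sum_j g_j exp(-1/2 (u - mu_j)' K_j^{-1}
#' (u - mu_j))` with diagonal covariance `K_j`. Each filter therefore has
#' `J * (2d + 1)` trainable parameters (d = 2).
#'
#' @param g numeric vector of `J` weights.
#' @param mu `J x 2` matrix of means.
#' @param variance `J x 2` matrix of positive diagonal covariance entries.
#' @return an object of class `gmm_filter`.
#' @export
gmm_filter <- function(g, mu, variance) {
  g <- as.numeric(g)
  mu <- matrix(mu, length(g), 2)
  variance <- matrix(variance, length(g), 2)
  if (any(variance <= 0)) stopf("all variances must be > 0")
  structure(list(J = length(g), g = g, mu = mu, variance = variance,
                 transform = diag(2)),
            class = "gmm_filter")
}

#' Evaluate a GMM filter at pseudo-coordinates
#'
#' @param filter a [gmm_filter()], possibly rotated/mirrored.
#' @param u a length-2 vector or an `n x 2` matrix of pseudo-coordinates.
#' @return scalar (or length-`n` vector) filter response.
#' @export
filter_response <- function(filter, u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  v <- u %*% t(filter$transform)
  out <- numeric(nrow(v))
  for (j in seq_len(filter$J)) {
    q <- (v[, 1] - filter$mu[j, 1])^2 / filter$variance[j, 1] +
         (v[, 2] - filter$mu[j, 2])^2 / filter$variance[j, 2]
    out <- out + filter$g[j] * exp(-0.5 * q)
  }
  if (length(out) == 1) out[[1]] else out
}

#' A GMM convolution layer
#'
#' Holds one independent trainable filter for every (input channel n, output
#' channel m) pair and an elementwise activation. Each filter carries its own
#' bias scalar; the effective bias of output channel `m` is the sum of the
#' biases of its `N` filters, so the layer has exactly
#' `M * N * (J * (2d + 1) + 1)` trainable scalars. Parameters are created at
#' zero (variances at one); use [init_glorot()] for random initialization.
#'
#' @param N,M input and output channel counts.
#' @param J number of Gaussians per filter.
#' @param activation `"relu"` or `"identity"`.
#' @return an object of class `gmm_layer`.
#' @export
gmm_layer <- function(N, M, J = 4, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  dims <- c(J, N, M)
  structure(list(N = as.integer(N), M = as.integer(M), J = as.integer(J),
                 activation = activation,
                 g = array(0, dims), mux = array(0, dims), muy = array(0, dims),
                 lvx = array(0, dims), lvy = array(0, dims),
                 b = matrix(0, N, M)),
            class = "gmm_layer")
}

#' A sequential GMM convolutional network
#'
#' A composition of [gmm_layer()]s applied left to right; the output channel
#' count of each layer must match the input channel count of the next. The
#' network carries a 2 x 2 orthogonal `transform` applied to every edge
#' pseudo-coordinate at evaluation time; [rotate_network()] and
#' [mirror_network()] update it analytically, leaving the trained Gaussian
#' parameters untouched.
#'
#' @param layers list of [gmm_layer()]s.
#' @return an object of class `gmm_network`.
#' @export
gmm_network <- function(layers) {
  if (length(layers) < 1) stopf("need at least one layer")
  for (i in seq_along(layers)[-1]) {
    if (layers[[i]]$N != layers[[i - 1]]$M)
      stopf("layer %d expects %d input channels but layer %d outputs %d",
            i, layers[[i]]$N, i - 1, layers[[i - 1]]$M)
  }
  structure(list(layers = layers, transform = diag(2), angle = 0,
                 mirrored = FALSE),
            class = "gmm_network")
}

#' @export
print.gmm_network <- function(x, ...) {
  chain <- paste(c(x$layers[[1]]$N, vapply(x$layers, function(l) l$M, integer(1))),
                 collapse = " -> ")
  cat(sprintf("GMM convolutional network: %d layer(s), channels %s, %d parameters\n",
              length(x$layers), chain, param_count(x)))
  if (x$angle != 0 || x$mirrored)
    cat(sprintf("  transformed: angle %.4f rad%s\n", x$angle,
                if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

layers_for_cpp <- function(net) {
  lapply(net$layers, function(l) list(
    N = l$N, M = l$M, J = l$J, act = .activations[[l$activation]],
    g = as.numeric(l$g), mux = as.numeric(l$mux), muy = as.numeric(l$muy),
    lvx = as.numeric(l$lvx), lvy = as.numeric(l$lvy), b = as.numeric(l$b)))
}

net_forward_cpp <- function(net, edges, u, f, want_cache = FALSE) {
  u <- u %*% t(net$transform)
  cpp_net_forward(layers_for_cpp(net), edges[, 1] - 1L, edges[, 2] - 1L,
                  u[, 1], u[, 2], f, want_cache)
}

#' Forward pass of a single layer over a graph
#'
#' Implements `h_m(s) = act(b_m + sum_n sum_{t in N(s)} phi_{n,m}(u(s,t))
#' f_n(t))`; the loop edge contributes `phi(0, 0) * f(s)`.
#'
#' @param layer a [gmm_layer()].
#' @param graph an `spxgraph`.
#' @param f node feature matrix (`K x N`); defaults to `graph$features`.
#' @return `K x M` matrix of output features.
#' @export
layer_forward <- function(layer, graph, f = graph$features) {
  network_forward(gmm_network(list(layer)), graph, f)
}

#' Forward pass of a network over a graph
#'
#' @param net a [gmm_network()].
#' @param graph an `spxgraph`.
#' @param f node feature matrix (`K x N1`); defaults to `graph$features`.
#' @return `K x M_L` matrix of output features.
#' @export
network_forward <- function(net, graph, f = graph$features) {
  f <- as.matrix(f)
  if (ncol(f) != net$layers[[1]]$N)
    stopf("features have %d channels; network expects %d", ncol(f), net$layers[[1]]$N)
  if (nrow(f) != graph$n_nodes) stopf("features must have one row per node")
  net_forward_cpp(net, graph$edges, graph$u, f)$out
}

#' Trainable parameter count
#'
#' Each filter contributes `J * (2d + 1)` scalars (d = 2) and each layer adds
#' one bias per output channel, giving `M * N * (J * (2d + 1) + 1)` per layer.
#'
#' @param net a [gmm_network()] (or a single [gmm_layer()]).
#' @return integer number of trainable scalars.
#' @export
param_count <- function(net) {
  if (inherits(net, "gmm_layer")) net <- gmm_network(list(net))
  sum(vapply(net$layers, function(l) l$M * l$N * (l$J * 5 + 1), numeric(1)))
}

#' Glorot-style random initialization
#'
#' Gaussian weights `g` are drawn Glorot-uniform with `fan_in = N * J` and
#' `fan_out = M * J`; means are uniform in `[-1, 1]^2` (the scale of one
#' normalized hop); variances start at 1 (log-variance 0); biases at 0.
#' Deterministic given `seed`.
#'
#' @param net a [gmm_network()].
#' @param seed integer seed.
#' @return the initialized network.
#' @export
init_glorot <- function(net, seed = 1) {
  with_seed(seed, {
    net$layers <- lapply(net$layers, function(l) {
      n <- l$J * l$N * l$M
      a <- sqrt(6 / (l$N * l$J + l$M * l$J))
      l$g <- array(runif(n, -a, a), dim(l$g))
      l$mux <- array(runif(n, -1, 1), dim(l$g))
      l$muy <- array(runif(n, -1, 1), dim(l$g))
      l$lvx <- array(0, dim(l$g))
      l$lvy <- array(0, dim(l$g))
      l$b <- matrix(0, l$N, l$M)
      l
    })
  })
  net
}

# flat parameter vector <-> network; order per layer: g, mux, muy, lvx, lvy, b
params_to_vec <- function(net) {
  unlist(lapply(net$layers, function(l)
    c(l$g, l$mux, l$muy, l$lvx, l$lvy, l$b)), use.names = FALSE)
}

vec_to_params <- function(net, vec) {
  pos <- 0L
  net$layers <- lapply(net$layers, function(l) {
    n <- l$J * l$N * l$M
    take <- function(len) {
      out <- vec[(pos + 1L):(pos + len)]
      pos <<- pos + len
      out
    }
    l$g <- array(take(n), dim(l$g))
    l$mux <- array(take(n), dim(l$g))
    l$muy <- array(take(n), dim(l$g))
    l$lvx <- array(take(n), dim(l$g))
    l$lvy <- array(take(n), dim(l$g))
    l$b <- matrix(take(l$N * l$M), l$N, l$M)
    l
  })
  net
}

grads_to_vec <- function(grads) {
  unlist(lapply(grads, function(g)
    c(g$g, g$mux, g$muy, g$lvx, g$lvy, g$b)), use.names = FALSE)
}

param_names <- function(net) {
  unlist(lapply(seq_along(net$layers), function(i) {
    l <- net$layers[[i]]
    n <- l$J * l$N * l$M
    c(sprintf("l%d.g%d", i, seq_len(n)), sprintf("l%d.mux%d", i, seq_len(n)),
      sprintf("l%d.muy%d", i, seq_len(n)), sprintf("l%d.lvx%d", i, seq_len(n)),
      sprintf("l%d.lvy%d", i, seq_len(n)),
      sprintf("l%d.b%d", i, seq_len(l$N * l$M)))
  }))
}
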