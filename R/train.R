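#' Training configuration
#'
#' Mean-squared-error loss and the Adam optimizer are fixed, matching the
#' training protocol the package implements; learning rate, iteration count
#' and batching are tunable. With `batch_size = NULL` every step is a
#' full-batch step over all training graphs; otherwise each step samples
#' `batch_size` graphs without replacement (reshuffling each epoch-like
#' pass), which keeps the per-step cost bounded for larger training sets
#' while preserving the step count.
#'
#' @param learning_rate positive Adam step size (1e-3 for the oriented-edge
#'   task, 1e-4 for the detection task).
#' @param epochs number of optimizer steps.
#' @param eval_interval steps between train/validation error evaluations
#'   (model-selection checkpoints).
#' @param seed integer seed controlling batch shuffling.
#' @param batch_size graphs per step, or `NULL` for full batch.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 2000,
                         eval_interval = 50, seed = 1, batch_size = NULL,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (epochs < 0) stopf("epochs must be >= 0")
  if (eval_interval < 1) stopf("eval_interval must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 eval_interval = as.integer(eval_interval),
                 seed = as.integer(seed), batch_size = batch_size,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 loss = "mse", optimizer = "adam"),
            class = "train_config")
}

# mean over graphs of the per-graph node-mean squared error
batch_mse <- function(net, merged) {
  out <- net_forward_cpp(net, merged$edges, merged$u, merged$features)$out
  sum(merged$node_weight * rowMeans((out - merged$targets)^2))
}

#' Mean squared error of a network over a set of graphs
#'
#' The mean over graphs of the per-graph, per-node mean squared error
#' between the network output and the graphs' targets.
#'
#' @param net a [gmm_network()].
#' @param graphs list of `spxgraph`s carrying targets.
#' @return scalar MSE.
#' @export
network_mse <- function(net, graphs) {
  if (inherits(graphs, "spxgraph")) graphs <- list(graphs)
  batch_mse(net, merge_graphs(graphs))
}

#' Train a GMM convolutional network
#'
#' Fits `net` to node-level regression targets by MSE loss and Adam. Every
#' `eval_interval` steps the train and validation errors are recorded; the
#' returned model is the checkpoint with the smallest validation error
#' (smallest training error when no validation graphs are given), the
#' protocol used for model selection against overfitting. Deterministic
#' given the configuration seed.
#'
#' @param net an initialized [gmm_network()].
#' @param train_graphs list of `spxgraph`s with targets.
#' @param val_graphs optional list of validation `spxgraph`s with targets.
#' @param config a [train_config()].
#' @return an object of class `gmmnet_fit` with elements `network` (selected
#'   model), `final_network`, `history` (data frame of recorded epochs),
#'   `best_epoch` and `config`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @export
gmmnet_train <- function(net, train_graphs, val_graphs = NULL,
                         config = train_config()) {
  if (inherits(train_graphs, "spxgraph")) train_graphs <- list(train_graphs)
  if (inherits(val_graphs, "spxgraph")) val_graphs <- list(val_graphs)
  for (g in train_graphs)
    if (is.null(g$targets)) stopf("all training graphs must carry targets")
  for (g in val_graphs)
    if (is.null(g$targets)) stopf("all validation graphs must carry targets")

  full <- merge_graphs(train_graphs)
  vfull <- if (length(val_graphs)) merge_graphs(val_graphs) else NULL
  nb <- config$batch_size
  G <- length(train_graphs)

  theta <- params_to_vec(net)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon

  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  best <- list(vec = theta, err = Inf, epoch = 0L)
  recorded <- FALSE

  sched <- if (!is.null(nb) && nb < G) {
    with_seed(child_seed(config$seed, 0L, 5L), {
      n_pass <- ceiling(config$epochs * nb / G) + 1L
      unlist(lapply(seq_len(n_pass), function(i) sample.int(G)))
    })
  } else NULL
  spos <- 0L

  for (it in seq_len(config$epochs)) {
    if (is.null(sched)) {
      merged <- full
    } else {
      pick <- sched[spos + seq_len(nb)]
      spos <- spos + nb
      merged <- merge_graphs(train_graphs[pick])
    }
    cur <- vec_to_params(net, theta)
    fw <- net_forward_cpp(cur, merged$edges, merged$u, merged$features,
                          want_cache = TRUE)
    dout <- 2 * merged$node_weight * (fw$out - merged$targets) /
      ncol(fw$out)
    grads <- cpp_net_backward(layers_for_cpp(cur),
                              merged$edges[, 1] - 1L, merged$edges[, 2] - 1L,
                              (merged$u %*% t(cur$transform))[, 1],
                              (merged$u %*% t(cur$transform))[, 2],
                              fw$inputs, fw$pre, fw$z, as.matrix(dout))
    gvec <- grads_to_vec(grads)
    m <- b1 * m + (1 - b1) * gvec
    v <- b2 * v + (1 - b2) * gvec^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    theta <- theta - config$learning_rate * mh / (sqrt(vh) + eps)

    if (it %% config$eval_interval == 0) {
      cur <- vec_to_params(net, theta)
      tr <- batch_mse(cur, full)
      va <- if (!is.null(vfull)) batch_mse(cur, vfull) else NA_real_
      history <- rbind(history, data.frame(epoch = it, train_mse = tr,
                                           val_mse = va))
      sel <- if (!is.null(vfull)) va else tr
      if (sel < best$err) best <- list(vec = theta, err = sel, epoch = it)
      recorded <- TRUE
    }
  }

  if (!recorded) best <- list(vec = theta, err = NA_real_,
                              epoch = config$epochs)
  structure(list(network = vec_to_params(net, best$vec),
                 final_network = vec_to_params(net, theta),
                 history = history, best_epoch = best$epoch,
                 best_error = best$err, config = config,
                 n_train = G, n_val = length(val_graphs)),
            class = "gmmnet_fit")
}

#' @export
print.gmmnet_fit <- function(x, ...) {
  cat(sprintf("GMM graph network fit: %d training graph(s), %d step(s), lr %g\n",
              x$n_train, x$config$epochs, x$config$learning_rate))
  cat(sprintf("  selected checkpoint: step %d (%s MSE %.6g)\n", x$best_epoch,
              if (x$n_val > 0) "validation" else "training", x$best_error))
  print(x$network)
  invisible(x)
}

#' @export
summary.gmmnet_fit <- function(object, ...) {
  cat(sprintf("GMM graph network fit (%d parameters)\n", param_count(object$network)))
  cat(sprintf("  training graphs: %d, validation graphs: %d\n",
              object$n_train, object$n_val))
  cat(sprintf("  steps: %d, learning rate: %g, batch: %s\n",
              object$config$epochs, object$config$learning_rate,
              if (is.null(object$config$batch_size)) "full"
              else object$config$batch_size))
  cat(sprintf("  selected step: %d, selection error: %.6g\n",
              object$best_epoch, object$best_error))
  if (nrow(object$history) > 0) {
    cat("  recorded error trajectory (head):\n")
    print(utils::head(object$history))
  }
  invisible(object)
}

#' @export
coef.gmmnet_fit <- function(object, ...) {
  setNames(params_to_vec(object$network), param_names(object$network))
}

#' @export
predict.gmmnet_fit <- function(object, graph, f = graph$features, ...) {
  network_forward(object$network, graph, f)
}

#' @export
residuals.gmmnet_fit <- function(object, graph, ...) {
  if (is.null(graph$targets)) stopf("graph carries no targets")
  as.numeric(graph$targets) - as.numeric(predict(object, graph))
}

#' @export
plot.gmmnet_fit <- function(x, ...) {
  if (nrow(x$history) == 0) {
    warning("no recorded history to plot")
    return(invisible(x))
  }
  rng <- range(c(x$history$train_mse, x$history$val_mse), na.rm = TRUE)
  plot(x$history$epoch, x$history$train_mse, type = "l", col = "steelblue",
       xlab = "step", ylab = "MSE", ylim = rng, ...)
  if (any(!is.na(x$history$val_mse))) {
    lines(x$history$epoch, x$history$val_mse, col = "firebrick")
    legend("topright", legend = c("train", "validation"), lty = 1,
           col = c("steelblue", "firebrick"), bty = "n")
  }
  points(x$best_epoch, x$best_error, pch = 19)
  invisible(x)
}
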