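#' Angle of a graph edge
#'
#' The angle between the horizontal axis and the edge `(s, t)`, measured
#' counterclockwise in the y-up pseudo-coordinate convention, in `(-pi, pi]`.
#' Loops have no direction and raise an error.
#'
#' @param graph an `spxgraph`.
#' @param s,t node indices of a non-loop edge.
#' @return angle in radians.
#' @export
edge_angle <- function(graph, s, t) {
  if (s == t) stopf("edge angle is undefined for loop edges")
  i <- which(graph$edges[, 1] == s & graph$edges[, 2] == t)
  if (length(i) == 0) stopf("no edge (%d, %d) in graph", s, t)
  atan2(graph$u[i[1], 2], graph$u[i[1], 1])
}

#' Orientation weight of an edge relative to a target angle
#'
#' `omega = sin(alpha - theta)`: edges perpendicular to the target
#' orientation (pointing "up" across it) get weight 1, parallel edges get 0,
#' and edges pointing the other way get negative weights, which are excluded
#' from the oriented-target sums.
#'
#' @param alpha edge angle in radians.
#' @param theta target orientation in radians.
#' @return numeric weight in `[-1, 1]`.
#' @export
orientation_weight <- function(alpha, theta) sin(alpha - theta)

#' Soft labels marking outer edges at a given orientation
#'
#' For each node `s`, over its non-loop neighbours `t` with positive
#' orientation weight `omega(s, t) = sin(alpha(s, t) - theta)`:
#' `h(s) = max( sum omega^2 (f(t) - f(s)) / sum omega^2, 0 )`.
#' Nodes with no positively weighted neighbour get 0 (their normalizer would
#' be 0/0). Loops are excluded (their angle is undefined). With the y-up
#' angle convention, `theta = 0` marks nodes whose upward neighbours are
#' brighter — a horizontal boundary with intensity increasing in the +y
#' direction; on a bright blob over dark background the positive responses
#' line the blob's lower outer boundary, and `theta = pi` marks the opposite
#' side.
#'
#' @param graph an `spxgraph`.
#' @param f single-channel node features (vector or `K x 1` matrix).
#' @param theta target orientation in radians (interpreted modulo `2*pi`).
#' @return numeric vector of per-node targets, all `>= 0`.
#' @export
oriented_targets <- function(graph, f = graph$features, theta = 0) {
  f <- as.numeric(f)
  e <- graph$edges
  nonloop <- e[, 1] != e[, 2]
  s <- e[nonloop, 1]; t <- e[nonloop, 2]
  alpha <- atan2(graph$u[nonloop, 2], graph$u[nonloop, 1])
  w <- sin(alpha - theta)
  keep <- w > 0
  h <- numeric(graph$n_nodes)
  if (any(keep)) {
    s <- s[keep]; t <- t[keep]; w2 <- w[keep]^2
    num <- rowsum(w2 * (f[t] - f[s]), s)
    den <- rowsum(w2, s)
    idx <- as.integer(rownames(num))
    h[idx] <- pmax(num / den, 0)
  }
  h
}

#' Verification dataset of oriented-edge labelling tasks
#'
#' Turns binary blob masks into graph regression pairs: each mask is
#' segmented (defaults `A = 400`, `D = 1`), node features are the mean mask
#' intensity per superpixel, and node targets are the oriented-edge soft
#' labels at orientation `theta`. The first 100 masks are used and split
#' 60/20/20 into train/validation/test in the order given.
#'
#' @param masks list of at least 100 binary matrices.
#' @param theta target edge orientation in radians.
#' @param config a [graph_config()]; defaults to `A = 400`, `D = 1`.
#' @return a list with `graphs` (targets attached), `splits` (index lists
#'   `train`, `val`, `test`) and `theta`.
#' @export
make_verification_dataset <- function(masks, theta = 0,
                                      config = graph_config(A = 400, D = 1, W = 1,
                                                            downscale = 1)) {
  if (length(masks) < 100) stopf("need at least 100 masks, got %d", length(masks))
  masks <- masks[seq_len(100)]
  graphs <- lapply(masks, function(m) {
    if (!all(m %in% c(0, 1))) stopf("masks must be binary 0/1")
    g <- build_graph(m, mask = NULL, config = config)
    g$targets <- oriented_targets(g, g$features, theta)
    g
  })
  list(graphs = graphs,
       splits = list(train = 1:60, val = 61:80, test = 81:100),
       theta = theta)
}

#' Re-target a verification dataset at a new orientation
#'
#' Recomputes the oriented-edge soft labels of every graph at `theta`,
#' leaving features and structure unchanged (the family `D_theta` of the
#' orientation experiment).
#'
#' @param dataset result of [make_verification_dataset()].
#' @param theta new target orientation in radians.
#' @return the dataset with updated targets and `theta`.
#' @export
retarget_verification_dataset <- function(dataset, theta) {
  dataset$graphs <- lapply(dataset$graphs, function(g) {
    g$targets <- oriented_targets(g, g$features, theta)
    g
  })
  dataset$theta <- theta
  dataset
}
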