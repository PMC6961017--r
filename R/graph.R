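#' Graph construction parameters
#'
#' Bundles the parameters controlling how an image is turned into a directed
#' superpixel graph.
#'
#' @param A expected average superpixel area in pixels^2 (>= 4). The requested
#'   SLIC segment count is `round(H * W / A)`.
#' @param D maximum hop distance: two superpixels are connected when a path of
#'   at most `D` adjacency steps links them. Loops are always present.
#' @param W positive scaling constant applied to mask-derived node targets;
#'   large values (e.g. 100) steer training away from the all-zero local
#'   minimum.
#' @param downscale linear scale factor in (0, 1] applied to the image
#'   (bilinear) and mask (nearest) before segmentation.
#' @param compactness SLIC compactness; larger values give more regular
#'   superpixels.
#' @param coord_scale normalizer for edge pseudo-coordinates, in pixels.
#'   Default `D * sqrt(A)` so that typical 1-hop offsets have magnitude about
#'   1/D and the farthest neighbours about 1.
#' @return an object of class `graph_config`.
#' @export
graph_config <- function(A = 256, D = 2, W = 100, downscale = 1,
                         compactness = 10, coord_scale = NULL) {
  if (!is.numeric(A) || A < 4) stopf("A must be a number >= 4")
  if (!is.numeric(D) || D < 1 || D != round(D)) stopf("D must be an integer >= 1")
  if (!is.numeric(W) || W <= 0) stopf("W must be > 0")
  if (!is.numeric(downscale) || downscale <= 0 || downscale > 1)
    stopf("downscale must be in (0, 1]")
  if (is.null(coord_scale)) coord_scale <- D * sqrt(A)
  if (coord_scale <= 0) stopf("coord_scale must be > 0")
  structure(list(A = A, D = as.integer(D), W = W, downscale = downscale,
                 compactness = compactness, coord_scale = coord_scale),
            class = "graph_config")
}

#' SLIC superpixel segmentation
#'
#' Partitions a grayscale image into compact, spatially connected superpixels
#' whose expected average area is `config$A`. The requested segment count is
#' `round(H * W / A)`; the achieved count may deviate slightly, as is usual
#' for SLIC. Labels are contiguous integers `1..K` and every label occurs.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param config a [graph_config()].
#' @return integer matrix of superpixel labels, same shape as `image`.
#' @export
compute_superpixels <- function(image, config = graph_config()) {
  if (!is.matrix(image) || length(image) == 0) stopf("image must be a non-empty matrix")
  if (config$A > nrow(image) * ncol(image))
    stopf("A (%g) exceeds the image area (%d)", config$A, nrow(image) * ncol(image))
  nseg <- max(1L, as.integer(round(nrow(image) * ncol(image) / config$A)))
  cpp_slic(image, nseg, config$compactness, 10L, 0.25)
}

#' Per-superpixel mean intensity features
#'
#' @param labels integer label matrix from [compute_superpixels()].
#' @param image numeric matrix, same shape as `labels`.
#' @return a `K x 1` matrix; row `k` is the mean of `image` over superpixel `k`.
#' @export
mean_node_features <- function(labels, image) {
  if (!all(dim(labels) == dim(image))) stopf("labels and image shapes differ")
  k <- max(labels)
  sums <- rowsum(as.numeric(image), as.integer(labels))
  cnts <- rowsum(rep(1, length(labels)), as.integer(labels))
  f <- matrix(0, k, 1)
  f[as.integer(rownames(sums)), 1] <- sums / cnts
  f
}

#' Mask-derived node targets
#'
#' The target of superpixel `k` is `W` times the fraction of its pixels inside
#' the binary mask, so targets lie in `[0, W]` and need not be 0 or `W` where
#' superpixel borders do not coincide with the mask boundary.
#'
#' @param labels integer label matrix.
#' @param mask binary (0/1) matrix, same shape as `labels`.
#' @param W positive scaling constant.
#' @return numeric vector of length `K`.
#' @export
mask_to_targets <- function(labels, mask, W = 100) {
  if (!all(dim(labels) == dim(mask))) stopf("labels and mask shapes differ")
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary 0/1")
  W * as.numeric(mean_node_features(labels, mask))
}

#' Directed edges, centroids and pseudo-coordinates
#'
#' One-hop adjacency connects superpixels sharing a pixel boundary under
#' 4-connectivity; the edge set contains every ordered pair within hop
#' distance `D`, plus a loop on every node. The pseudo-coordinate of edge
#' `(s, t)` is the centroid offset of `t` relative to `s`, with x rightward
#' and y upward (image rows increase downward, so the row difference is
#' negated), divided by `coord_scale`. Loops have `u = (0, 0)`.
#'
#' @param labels integer label matrix.
#' @param D maximum hop distance (integer >= 1).
#' @param coord_scale pseudo-coordinate normalizer in pixels.
#' @return a list with `edges` (E x 2 integer matrix, ordered by (s, t)),
#'   `u` (E x 2 matrix), and `centroids` (K x 2 matrix, columns x, y in pixel
#'   coordinates of the labelled image).
#' @export
build_edges <- function(labels, D = 1, coord_scale = sqrt(256) * D) {
  if (D < 1) stopf("D must be >= 1")
  k <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  cx <- as.numeric(rowsum(as.numeric(col(labels)), as.integer(labels)) /
                     rowsum(rep(1, h * w), as.integer(labels)))
  cy <- as.numeric(rowsum(as.numeric(row(labels)), as.integer(labels)) /
                     rowsum(rep(1, h * w), as.integer(labels)))
  centroids <- cbind(x = cx, y = cy)

  pairs <- rbind(
    cbind(as.integer(labels[, -w, drop = FALSE]), as.integer(labels[, -1, drop = FALSE])),
    cbind(as.integer(labels[-h, , drop = FALSE]), as.integer(labels[-1, , drop = FALSE]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))

  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, as.vector(t(pairs)))
  dm <- igraph::distances(g)
  reach <- which(dm > 0 & dm <= D, arr.ind = TRUE)
  edges <- rbind(cbind(seq_len(k), seq_len(k)),        # loops
                 cbind(reach[, 1], reach[, 2]))
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("s", "t")

  u <- cbind(cx[edges[, 2]] - cx[edges[, 1]],
             -(cy[edges[, 2]] - cy[edges[, 1]])) / coord_scale
  u[edges[, 1] == edges[, 2], ] <- 0
  colnames(u) <- c("ux", "uy")
  list(edges = edges, u = u, centroids = centroids)
}

#' Build a superpixel graph from an image
#'
#' Composes downscaling, SLIC segmentation, mean-intensity node features,
#' hop-distance edge construction with pseudo-coordinates, and (when a mask
#' is supplied) mask-derived node targets. Deterministic given its inputs.
#'
#' @param image numeric matrix in \[0, 1\] (or an H x W x 3 array, converted to
#'   grayscale by channel averaging).
#' @param mask optional binary matrix, same shape as `image`.
#' @param config a [graph_config()].
#' @return an object of class `spxgraph`: a list with `n_nodes`, `features`
#'   (K x 1 matrix), `edges`, `u`, `centroids` (in processed-image pixels),
#'   `labels`, optional `targets`, `config` and `scale` (the downscale factor
#'   actually applied).
#' @export
build_graph <- function(image, mask = NULL, config = graph_config()) {
  if (length(dim(image)) == 3) image <- apply(image[, , 1:3, drop = FALSE], c(1, 2), mean)
  if (!is.matrix(image) || length(image) == 0) stopf("image must be a non-empty matrix")
  if (!is.null(mask) && !all(dim(mask) == dim(image)))
    stopf("image and mask shapes differ")
  img <- resize_image(image, config$downscale, "bilinear")
  img <- pmin(pmax(img, 0), 1)
  labels <- compute_superpixels(img, config)
  feats <- mean_node_features(labels, img)
  topo <- build_edges(labels, config$D, config$coord_scale)
  targets <- NULL
  if (!is.null(mask)) {
    msk <- resize_image(mask, config$downscale, "nearest")
    targets <- mask_to_targets(labels, msk, config$W)
  }
  structure(list(n_nodes = max(labels), features = feats,
                 edges = topo$edges, u = topo$u, centroids = topo$centroids,
                 labels = labels, targets = targets, config = config,
                 scale = config$downscale),
            class = "spxgraph")
}

#' @export
print.spxgraph <- function(x, ...) {
  cat(sprintf("superpixel graph: %d nodes, %d directed edges (incl. loops)\n",
              x$n_nodes, nrow(x$edges)))
  cat(sprintf("  label map %d x %d, A = %g, D = %d%s\n",
              nrow(x$labels), ncol(x$labels), x$config$A, x$config$D,
              if (is.null(x$targets)) "" else sprintf(", targets in [0, %g]", x$config$W)))
  invisible(x)
}

# Disjoint union of graphs used for (mini-)batch training. Node weights make
# the batch loss the mean over graphs of the per-graph node-mean squared
# error.
merge_graphs <- function(graphs) {
  ks <- vapply(graphs, function(g) as.integer(g$n_nodes), integer(1))
  off <- cumsum(c(0L, ks[-length(ks)]))
  edges <- do.call(rbind, Map(function(g, o) g$edges + o, graphs, off))
  u <- do.call(rbind, lapply(graphs, function(g) g$u))
  f <- do.call(rbind, lapply(graphs, function(g) g$features))
  targets <- if (all(vapply(graphs, function(g) !is.null(g$targets), logical(1))))
    unlist(lapply(graphs, function(g) g$targets)) else NULL
  wt <- unlist(Map(function(k) rep(1 / (length(graphs) * k), k), ks))
  list(edges = edges, u = u, features = f, targets = targets,
       node_weight = wt, n_nodes = sum(ks), graph_id = rep(seq_along(ks), ks))
}
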