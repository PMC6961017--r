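#' Argmax-node detection
#'
#' Selects the node (superpixel) with the highest network response; ties are
#' broken by the lowest node id. The returned centroid is expressed in
#' original-image pixel coordinates (the graph's downscale factor is undone).
#'
#' @param output per-node scalar network output (vector or `K x 1` matrix).
#' @param graph the `spxgraph` the output was computed on.
#' @param angle rotation angle of the producing network (0 for single-network
#'   detection); stored in the result.
#' @return an object of class `detection`: list with `node`, `centroid`
#'   (`c(x, y)`), `score`, `hit` (`NA` until evaluated) and `angle`.
#' @export
detect_node <- function(output, graph, angle = 0) {
  output <- as.numeric(output)
  if (length(output) == 0) stopf("empty output")
  if (length(output) != graph$n_nodes) stopf("output length != node count")
  node <- which.max(output)  # first maximum = lowest id on ties
  centroid <- graph$centroids[node, ] / graph$scale
  structure(list(node = node, centroid = c(x = unname(centroid[1]),
                                           y = unname(centroid[2])),
                 score = output[node], hit = NA, angle = angle),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("detection: node %d at (%.1f, %.1f), score %.4g, angle %.3f%s\n",
              x$node, x$centroid[1], x$centroid[2], x$score, x$angle,
              if (is.na(x$hit)) "" else sprintf(", %s", if (x$hit) "hit" else "miss")))
  invisible(x)
}

#' Evaluate a detection against an enlarged bounding box
#'
#' The tight bounding box of the target region is expanded by `enlargement`
#' pixels on each side (to absorb superpixel size, by default `sqrt(A)` of
#' the graph that produced the detection is a sensible choice) and the
#' detection counts as a hit when its centroid lies inside; the boundary
#' counts as inside.
#'
#' @param result a `detection` (or a length-2 centroid `c(x, y)`).
#' @param bbox `c(xmin, ymin, xmax, ymax)` in original-image pixels.
#' @param enlargement pixels added on every side.
#' @return logical hit; if `result` is a `detection`, the updated detection
#'   is attached as attribute `"detection"`.
#' @export
evaluate_hit <- function(result, bbox, enlargement = 16) {
  centroid <- if (inherits(result, "detection")) result$centroid else result
  hit <- centroid[1] >= bbox[1] - enlargement &&
         centroid[1] <= bbox[3] + enlargement &&
         centroid[2] >= bbox[2] - enlargement &&
         centroid[2] <= bbox[4] + enlargement
  if (inherits(result, "detection")) {
    result$hit <- hit
    attr(hit, "detection") <- result
  }
  hit
}

# networks of a bank in tie-priority order: by |angle|, then angle
bank_order <- function(bank) order(abs(bank$angles), bank$angles)

#' Rotation-bank detection by global maximum
#'
#' Runs every rotated network of the bank on the graph and returns the
#' detection of the (network, node) pair with the globally maximal output;
#' ties prefer the smallest `|angle|` (then the smaller angle, then the
#' lowest node id).
#'
#' @param bank a [rotation_bank()].
#' @param graph an `spxgraph`.
#' @return a `detection` whose `angle` is the winning network's angle.
#' @export
ensemble_detect_max <- function(bank, graph) {
  best <- NULL
  for (i in bank_order(bank)) {
    out <- network_forward(bank$networks[[i]], graph)
    det <- detect_node(out, graph, angle = bank$angles[i])
    if (is.null(best) || det$score > best$score) best <- det
  }
  best
}

#' Rotation-bank detection by any-correct rule
#'
#' `TRUE` when at least one network of the bank places its argmax node
#' inside the enlarged bounding box — the upper bound on what the bank can
#' achieve if the correct rotation angle could always be identified.
#'
#' @param bank a [rotation_bank()].
#' @param graph an `spxgraph`.
#' @param bbox tight target bounding box `c(xmin, ymin, xmax, ymax)`.
#' @param enlargement pixels added on every side of the box.
#' @return logical.
#' @export
ensemble_detect_any <- function(bank, graph, bbox, enlargement = 16) {
  for (i in seq_along(bank$networks)) {
    out <- network_forward(bank$networks[[i]], graph)
    det <- detect_node(out, graph, angle = bank$angles[i])
    if (isTRUE(evaluate_hit(det, bbox, enlargement))) return(TRUE)
  }
  FALSE
}

#' Detection accuracy
#'
#' @param hits logical vector of per-image detection outcomes.
#' @return fraction of hits.
#' @export
detection_accuracy <- function(hits) {
  if (length(hits) == 0) stopf("no detection results")
  mean(as.logical(hits))
}

#' Named network architectures
#'
#' * `verification`: 2 layers, channels 1 -> 10 -> 1 (10 groups of 1 filter,
#'   then 1 group of 10 filters), ReLU then identity; 420 parameters.
#' * `main`: 4 layers, channels 1 -> 20 -> 10 -> 5 -> 1, ReLU except an
#'   identity last layer; 5775 parameters.
#' * `main_plus`: `main` with an additional 20-group layer at the input,
#'   channels 1 -> 20 -> 20 -> 10 -> 5 -> 1.
#'
#' All filters use `J` Gaussians (default 4). Parameters are zero-valued;
#' apply [init_glorot()] before training.
#'
#' @param name one of `"verification"`, `"main"`, `"main_plus"`.
#' @param J Gaussians per filter.
#' @return a [gmm_network()].
#' @export
build_architecture <- function(name = c("verification", "main", "main_plus"),
                               J = 4) {
  name <- match.arg(name)
  chain <- switch(name,
    verification = c(1, 10, 1),
    main = c(1, 20, 10, 5, 1),
    main_plus = c(1, 20, 20, 10, 5, 1))
  nl <- length(chain) - 1
  layers <- lapply(seq_len(nl), function(i)
    gmm_layer(chain[i], chain[i + 1], J = J,
              activation = if (i == nl) "identity" else "relu"))
  gmm_network(layers)
}
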