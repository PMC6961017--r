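# Readers, writers and reporting glue. Plain-text formats (TSV/JSON/CSV) are
# the canonical on-disk representations; an RDS container is offered as the
# compact binary alternative for large graphs.

#' Read a grayscale image
#'
#' Reads PNG or TIFF, mapping 8-bit values to \[0, 1\]; color images are
#' converted to grayscale by averaging the first three channels.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s' (use PNG or TIFF)", ext))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Read a binary mask image
#'
#' As [read_image()], then thresholds at 0.5 so that 0/255 masks map to 0/1.
#'
#' @param path file path.
#' @return integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- (read_image(path) > 0.5) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write a grayscale image or mask as PNG
#'
#' @param img numeric matrix; values are clipped to \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Serialize a superpixel graph
#'
#' The `"tsv"` format writes a directory containing `nodes.tsv` (id,
#' centroid, features, optional target), `edges.tsv` (s, t, u_x, u_y),
#' `labels.tsv` (the pixel-label map) and `meta.json` (configuration and
#' scale), all plain text with full floating-point precision so the
#' round-trip is lossless. The `"rds"` format writes a single compact binary
#' file.
#'
#' @param graph an `spxgraph`.
#' @param path output directory (`"tsv"`) or file (`"rds"`).
#' @param format `"tsv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(graph, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  nodes <- data.frame(id = seq_len(graph$n_nodes),
                      cx = fmt(graph$centroids[, 1]),
                      cy = fmt(graph$centroids[, 2]))
  for (j in seq_len(ncol(graph$features)))
    nodes[[paste0("f", j)]] <- fmt(graph$features[, j])
  if (!is.null(graph$targets)) nodes$target <- fmt(graph$targets)
  write.table(nodes, file.path(path, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  edges <- data.frame(s = graph$edges[, 1], t = graph$edges[, 2],
                      ux = fmt(graph$u[, 1]), uy = fmt(graph$u[, 2]))
  write.table(edges, file.path(path, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(graph$labels, file.path(path, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(n_nodes = graph$n_nodes, n_features = ncol(graph$features),
               has_targets = !is.null(graph$targets),
               scale = graph$scale, config = unclass(graph$config))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a serialized superpixel graph
#'
#' @param path directory written by [write_graph()] (`"tsv"`) or an `.rds`
#'   file.
#' @return an `spxgraph`.
#' @export
read_graph <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path)) return(readRDS(path))
    stopf("cannot read graph from '%s'", path)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  nodes <- read.table(file.path(path, "nodes.tsv"), header = TRUE, sep = "\t")
  edges <- read.table(file.path(path, "edges.tsv"), header = TRUE, sep = "\t")
  labels <- as.matrix(read.table(file.path(path, "labels.tsv"), sep = "\t"))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  feats <- as.matrix(nodes[paste0("f", seq_len(meta$n_features))])
  dimnames(feats) <- NULL
  cfg <- do.call(graph_config, meta$config[c("A", "D", "W", "downscale",
                                             "compactness", "coord_scale")])
  em <- cbind(s = edges$s, t = edges$t)
  storage.mode(em) <- "integer"
  structure(list(n_nodes = meta$n_nodes, features = feats,
                 edges = em,
                 u = cbind(ux = edges$ux, uy = edges$uy),
                 centroids = cbind(x = nodes$cx, y = nodes$cy),
                 labels = labels,
                 targets = if (isTRUE(meta$has_targets)) nodes$target else NULL,
                 config = cfg, scale = meta$scale),
            class = "spxgraph")
}

#' Save a network checkpoint
#'
#' JSON container with the architecture descriptor (channels, Gaussian
#' counts, activations), the flat parameter arrays and the evaluation-time
#' coordinate transform, written at full floating-point precision so the
#' round-trip is exact.
#'
#' @param net a [gmm_network()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(net, path) {
  obj <- list(
    architecture = lapply(net$layers, function(l)
      list(N = l$N, M = l$M, J = l$J, activation = l$activation)),
    parameters = lapply(net$layers, function(l)
      list(g = as.numeric(l$g), mux = as.numeric(l$mux),
           muy = as.numeric(l$muy), lvx = as.numeric(l$lvx),
           lvy = as.numeric(l$lvy), b = as.numeric(l$b))),
    transform = as.numeric(net$transform),
    angle = net$angle, mirrored = net$mirrored)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path `.json` file written by [write_checkpoint()].
#' @return a [gmm_network()].
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  layers <- lapply(seq_along(obj$architecture), function(i) {
    a <- obj$architecture[[i]]
    p <- obj$parameters[[i]]
    l <- gmm_layer(a$N, a$M, a$J, a$activation)
    dims <- dim(l$g)
    l$g <- array(num(p$g), dims); l$mux <- array(num(p$mux), dims)
    l$muy <- array(num(p$muy), dims); l$lvx <- array(num(p$lvx), dims)
    l$lvy <- array(num(p$lvy), dims); l$b <- matrix(num(p$b), a$N, a$M)
    l
  })
  net <- gmm_network(layers)
  net$transform <- matrix(num(obj$transform), 2, 2)
  net$angle <- obj$angle
  net$mirrored <- obj$mirrored
  net
}

#' Save a rotation bank
#'
#' Stores the base checkpoint once plus the angle list; rotated copies are
#' reconstructed on load, so no parameters are duplicated.
#'
#' @param bank a [rotation_bank()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_checkpoint(bank$base, tmp)
  obj <- list(base = jsonlite::read_json(tmp), angles = bank$angles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a rotation bank
#'
#' @param path `.json` file written by [write_bank()].
#' @return a [rotation_bank()].
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj$base, tmp, auto_unbox = TRUE, digits = I(17))
  base <- read_checkpoint(tmp)
  angles <- unlist(obj$angles)
  networks <- lapply(angles, function(a) rotate_network(base, a))
  structure(list(base = base, angles = angles, networks = networks),
            class = "rotation_bank")
}

#' Write an accuracy report table
#'
#' Formats per-split, per-rule detection accuracies as a deterministic CSV
#' table: one row per split, one column per rule with percentages printed to
#' two decimals, plus a final cardinality column `#D`.
#'
#' @param results data frame with columns `split`, `rule`, `accuracy`
#'   (fraction in \[0, 1\]) and `n`.
#' @param path output `.csv` path.
#' @return the formatted table (data frame), invisibly.
#' @export
write_report <- function(results, path) {
  splits <- unique(results$split)
  rules <- unique(results$rule)
  tab <- data.frame(split = splits, stringsAsFactors = FALSE)
  for (r in rules) {
    col <- vapply(splits, function(s) {
      a <- results$accuracy[results$split == s & results$rule == r]
      if (length(a) == 0) NA_character_ else sprintf("%.2f%%", 100 * a[1])
    }, character(1))
    tab[[r]] <- col
  }
  tab[["#D"]] <- vapply(splits, function(s) {
    n <- results$n[results$split == s]
    if (length(n) == 0) NA_integer_ else as.integer(n[1])
  }, integer(1))
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Write an experiment manifest
#'
#' Records a configuration snapshot, the seeds in play and content
#' fingerprints (MD5) of the listed artifact files, so that a re-run can be
#' checked for bit-identical inputs and outputs.
#'
#' @param path output `.json` path.
#' @param config named list: configuration snapshot.
#' @param seeds named list or vector of seeds.
#' @param files character vector of artifact paths to fingerprint.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           files = character()) {
  fp <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(config = config, seeds = seeds, fingerprints = fp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}

#' Write a scene to disk
#'
#' Writes `<prefix>.png` (image), `<prefix>_mask.png` (binary mask) and
#' `<prefix>.json` (manifest with subject, rotation, bounding box and the
#' generating specification), the layout the graph-construction and
#' evaluation tools consume.
#'
#' @param scene a [gen_scene()] result.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return the manifest path, invisibly.
#' @export
write_scene <- function(scene, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(scene$image, file.path(dir, paste0(prefix, ".png")))
  write_image(scene$mask, file.path(dir, paste0(prefix, "_mask.png")))
  manifest <- list(subject_id = scene$subject_id, rotation = scene$rotation,
                   bbox = as.list(scene$bbox),
                   spec = unclass(scene$spec))
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load image/mask scene pairs from a directory
#'
#' Reads every `<name>.png` with a matching `<name>_mask.png` (the layout of
#' [write_scene()], and of ear datasets distributed as image + binary-mask
#' pairs). The bounding box is taken from the manifest when present,
#' otherwise recomputed from the mask.
#'
#' @param dir directory to scan.
#' @return list of `scene`-like objects (`image`, `mask`, `bbox`,
#'   `subject_id`, `rotation` when known).
#' @export
load_scene_dir <- function(dir) {
  masks <- list.files(dir, pattern = "_mask\\.png$", full.names = TRUE)
  lapply(masks, function(mp) {
    base <- sub("_mask\\.png$", "", mp)
    img <- read_image(paste0(base, ".png"))
    mask <- read_mask(mp)
    man_path <- paste0(base, ".json")
    man <- if (file.exists(man_path))
      jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
    bbox <- if (!is.null(man$bbox)) unlist(man$bbox) else {
      px <- which(mask == 1, arr.ind = TRUE)
      c(xmin = min(px[, 2]), ymin = min(px[, 1]),
        xmax = max(px[, 2]), ymax = max(px[, 1]))
    }
    structure(list(image = img, mask = mask, bbox = bbox,
                   rotation = if (!is.null(man$rotation)) man$rotation else NA,
                   subject_id = if (!is.null(man$subject_id)) man$subject_id
                                else NA,
                   spec = man$spec),
              class = "scene")
  })
}
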