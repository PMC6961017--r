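# Synthetic data generation. Two generators are provided: smooth random blob
# masks for the oriented-edge verification experiment, and profile-view
# scenes (textured background, bright head-like region, ear-like target on
# its boundary) emulating the structure of profile ear-detection imagery:
# one connected target per image, varying illumination and background, and
# in-plane rotation of the target. Everything is deterministic given seeds.

#' Generate a smooth random blob mask
#'
#' A star-shaped region around a jittered centre whose radius is a smooth
#' random harmonic function of the angle, thresholded onto the pixel grid.
#' The blob is connected (single 4-connected component) and occupies between
#' 10 and 40 percent of the frame.
#'
#' @param seed integer seed; the same seed reproduces the same mask.
#' @param size `c(H, W)` frame size in pixels.
#' @return binary (0/1) integer matrix of dimension `size`.
#' @export
gen_blob_mask <- function(seed, size = c(96, 128)) {
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    cy <- h / 2 + runif(1, -0.08, 0.08) * h
    cx <- w / 2 + runif(1, -0.08, 0.08) * w
    frac <- runif(1, 0.15, 0.35)
    r0 <- sqrt(frac * h * w / pi)
    amp <- runif(4, 0, 0.3); amp <- amp / max(1, sum(amp) / 0.3)
    phase <- runif(4, 0, 2 * pi)
    # keep the blob inside the frame with a 2 px margin
    border <- min(cy, h - cy, cx, w - cx) - 2
    rmax <- r0 * (1 + sum(amp))
    if (rmax > border) r0 <- r0 * border / rmax
    dy <- outer(seq_len(h) - cy, rep(1, w))
    dx <- outer(rep(1, h), seq_len(w) - cx)
    ang <- atan2(-dy, dx)  # y-up
    rad <- r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
      amp[k] * cos((k + 1) * ang + phase[k]))))
    mask <- (sqrt(dy^2 + dx^2) <= rad) * 1L
    storage.mode(mask) <- "integer"
    mask
  })
}

#' Scene specification
#'
#' Describes one synthetic profile-view scene. Scenes with equal
#' specifications are bit-identical; scenes sharing `subject_id` share the
#' subject's appearance (background level, head geometry, target geometry
#' and intensities), while `seed` drives per-scene noise.
#'
#' @param seed integer per-scene seed.
#' @param size `c(H, W)` in pixels, both >= 32.
#' @param rotation in-plane rotation of the target about its own centre,
#'   radians (counterclockwise, y-up).
#' @param illumination scalar multiplier applied to the whole image before
#'   clipping to \[0, 1\].
#' @param background_texture one of `"noise"`, `"flat"`, `"gradient"`.
#' @param subject_id positive integer identifying the subject.
#' @param border_margin minimum distance (pixels) from the target centre to
#'   the frame border; set small to emulate the hard border-placement case.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1, size = c(96, 128), rotation = 0,
                       illumination = 1,
                       background_texture = c("noise", "flat", "gradient"),
                       subject_id = 1, border_margin = 20) {
  if (any(size < 32)) stopf("scene size must be at least 32 x 32")
  background_texture <- match.arg(background_texture)
  structure(list(seed = as.integer(seed), size = size, rotation = rotation,
                 illumination = illumination,
                 background_texture = background_texture,
                 subject_id = as.integer(subject_id),
                 border_margin = border_margin),
            class = "scene_spec")
}

# Subject appearance parameters are a pure function of subject_id, so every
# scene of a subject shares them regardless of scene seeds.
subject_params <- function(subject_id) {
  with_seed(child_seed(727, subject_id), list(
    bg_level = runif(1, 0.12, 0.28),
    head_cx = runif(1, 0.58, 0.68), head_cy = runif(1, 0.42, 0.55),
    head_ax = runif(1, 0.30, 0.36), head_ay = runif(1, 0.40, 0.46),
    head_int = runif(1, 0.42, 0.55),
    ear_rx = runif(1, 9, 12), ear_ry = runif(1, 5.5, 7.5),
    ear_int = runif(1, 0.85, 0.95), inner_int = runif(1, 0.48, 0.60),
    ear_dy = runif(1, -0.10, 0.10),
    grad_dir = runif(1, 0, 2 * pi)
  ))
}

#' Generate a synthetic profile-view scene
#'
#' Renders the subject's background texture, a large elliptical head-like
#' region, and a bright ear-like target (ellipse with a darker inner notch)
#' on the head's left boundary, rotated by `spec$rotation` about its own
#' centre. The binary mask marks the target, and `bbox` is its tight
#' bounding box `c(xmin, ymin, xmax, ymax)` in pixel coordinates
#' (x = column, y = row).
#'
#' @param spec a [scene_spec()].
#' @return an object of class `scene`: list with `image` (matrix in
#'   \[0, 1\]), `mask` (binary matrix), `bbox`, `rotation`, `subject_id`
#'   and `spec`.
#' @export
gen_scene <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  p <- subject_params(spec$subject_id)
  rr <- row(matrix(0, h, w)); cc <- col(matrix(0, h, w))

  img <- with_seed(child_seed(spec$seed, spec$subject_id, 1L), {
    base <- switch(spec$background_texture,
      flat = matrix(p$bg_level, h, w),
      gradient = {
        proj <- (cc / w) * cos(p$grad_dir) + (rr / h) * sin(p$grad_dir)
        p$bg_level + 0.12 * (proj - mean(proj))
      },
      noise = {
        z <- matrix(rnorm(h * w), h, w)
        k <- stats::dnorm(-6:6, sd = 2.5); k <- k / sum(k)
        sm <- apply(apply(z, 2, function(col) stats::filter(col, k, circular = TRUE)),
                    1, function(row) stats::filter(row, k, circular = TRUE))
        sm <- t(sm)
        p$bg_level + 0.08 * sm / max(abs(sm))
      })
    base + matrix(rnorm(h * w, sd = 0.015), h, w)
  })

  # head
  hx <- p$head_cx * w; hy <- p$head_cy * h
  inside_head <- ((cc - hx) / (p$head_ax * w))^2 + ((rr - hy) / (p$head_ay * h))^2 <= 1
  img[inside_head] <- p$head_int

  # target centre on the head's left boundary, kept away from the frame edge
  m <- spec$border_margin
  ex <- min(max(hx - p$head_ax * w * 0.92, m), w - m)
  ey <- min(max(hy + p$ear_dy * h, m), h - m)

  # rotate evaluation coordinates by -rotation (y-up) about the target centre
  th <- spec$rotation
  dx <- cc - ex; dy <- -(rr - ey)
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  outer_e <- (xr / p$ear_rx)^2 + (yr / p$ear_ry)^2 <= 1
  inner_e <- ((xr - 0.28 * p$ear_rx) / (0.55 * p$ear_rx))^2 +
             (yr / (0.55 * p$ear_ry))^2 <= 1
  img[outer_e] <- p$ear_int
  img[outer_e & inner_e] <- p$inner_int

  img <- pmin(pmax(img * spec$illumination, 0), 1)
  mask <- outer_e * 1L
  storage.mode(mask) <- "integer"
  wpix <- which(mask == 1L, arr.ind = TRUE)
  bbox <- c(xmin = min(wpix[, 2]), ymin = min(wpix[, 1]),
            xmax = max(wpix[, 2]), ymax = max(wpix[, 1]))
  structure(list(image = img, mask = mask, bbox = bbox,
                 rotation = spec$rotation, subject_id = spec$subject_id,
                 spec = spec),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d x %d, subject %d, rotation %.3f rad, target bbox [%d,%d]x[%d,%d]\n",
              nrow(x$image), ncol(x$image), x$subject_id, x$rotation,
              x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Generate a person-disjoint scene dataset
#'
#' Subjects are partitioned into train/validation/test splits in proportions
#' 75:25:26 (rounded); all scenes of a subject land in the same split, so
#' the splits are person-disjoint. Each scene draws its rotation uniformly
#' from `rotation_range`, its illumination from `[0.85, 1.15]`, and the
#' subject's background texture is fixed.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param scenes_per_subject scenes rendered per subject.
#' @param rotation_range `c(lo, hi)` radians for per-scene target rotation.
#' @param seed integer master seed.
#' @param size scene size `c(H, W)`.
#' @return a list with `scenes` (list of [gen_scene()] results), `splits`
#'   (scene index lists `train`, `val`, `test`) and `subject_split` (named
#'   character vector, split per subject).
#' @export
gen_dataset <- function(n_subjects, scenes_per_subject = 3,
                        rotation_range = c(0, 0), seed = 1,
                        size = c(96, 128)) {
  if (n_subjects < 3) stopf("need at least 3 subjects, got %d", n_subjects)
  props <- c(train = 75, val = 25, test = 26) / 126
  n_tr <- max(1L, round(n_subjects * props[["train"]]))
  n_va <- max(1L, round(n_subjects * props[["val"]]))
  n_te <- n_subjects - n_tr - n_va
  if (n_te < 1) { n_te <- 1L; n_tr <- n_subjects - n_va - n_te }
  perm <- with_seed(child_seed(seed, 0L, 2L), sample.int(n_subjects))
  split_of <- character(n_subjects)
  split_of[perm[seq_len(n_tr)]] <- "train"
  split_of[perm[n_tr + seq_len(n_va)]] <- "val"
  split_of[perm[n_tr + n_va + seq_len(n_te)]] <- "test"
  names(split_of) <- seq_len(n_subjects)

  textures <- c("noise", "flat", "gradient")
  scenes <- list()
  idx <- 0L
  for (sid in seq_len(n_subjects)) {
    tex <- textures[1 + (sid %% 3)]
    for (k in seq_len(scenes_per_subject)) {
      idx <- idx + 1L
      sseed <- child_seed(seed, idx, 3L)
      pars <- with_seed(child_seed(sseed, 1L, 4L),
                        list(rot = runif(1, rotation_range[1], rotation_range[2]),
                             illum = runif(1, 0.85, 1.15)))
      scenes[[idx]] <- gen_scene(scene_spec(
        seed = sseed, size = size, rotation = pars$rot,
        illumination = pars$illum, background_texture = tex,
        subject_id = sid))
    }
  }
  sid_of_scene <- vapply(scenes, function(s) s$subject_id, integer(1))
  splits <- lapply(c(train = "train", val = "val", test = "test"),
                   function(sp) which(split_of[sid_of_scene] == sp))
  list(scenes = scenes, splits = splits, subject_split = split_of)
}
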