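# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and an index, kept inside the 32-bit
# integer range R requires of set.seed().
child_seed <- function(seed, index, stream = 0L) {
  (as.numeric(seed) * 100003 + as.numeric(index) * 97 + stream * 17) %%
    .Machine$integer.max
}

# 2-D counterclockwise rotation matrix (y-up convention).
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Linear image rescaling. Bilinear for continuous images, nearest-neighbour
# for label/mask images (values must not be blended).
resize_image <- function(img, factor, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (factor == 1) return(img)
  h <- nrow(img); w <- ncol(img)
  h2 <- max(1L, round(h * factor)); w2 <- max(1L, round(w * factor))
  # centres of the output pixels mapped back into input coordinates
  src_r <- (seq_len(h2) - 0.5) / factor - 0.5 + 1  # 1-based
  src_c <- (seq_len(w2) - 0.5) / factor - 0.5 + 1
  if (method == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), h)
    ci <- pmin(pmax(round(src_c), 1), w)
    return(img[ri, ci, drop = FALSE])
  }
  interp_matrix <- function(src, n) {
    lo <- pmin(pmax(floor(src), 1), n)
    hi <- pmin(lo + 1, n)
    whi <- pmin(pmax(src - lo, 0), 1)
    m <- matrix(0, length(src), n)
    idx <- seq_along(src)
    m[cbind(idx, lo)] <- m[cbind(idx, lo)] + (1 - whi)
    m[cbind(idx, hi)] <- m[cbind(idx, hi)] + whi
    m
  }
  ar <- interp_matrix(src_r, h)
  ac <- interp_matrix(src_c, w)
  ar %*% img %*% t(ac)
}
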