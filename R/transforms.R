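#' Rotate a GMM filter analytically
#'
#' The rotated filter satisfies `phi_theta(u) = phi(R(-theta) u)` where `R`
#' is the counterclockwise 2-D rotation matrix: the response pattern turns by
#' `theta` around the origin of the pseudo-coordinate system. Implemented by
#' composing the filter's evaluation-time coordinate transform, so there is
#' no interpolation error and the stored Gaussian parameters are unchanged.
#'
#' @param filter a [gmm_filter()].
#' @param theta rotation angle in radians.
#' @return a new `gmm_filter` whose response is the rotated one.
#' @export
rotate_filter <- function(filter, theta) {
  filter$transform <- filter$transform %*% rotation_matrix(-theta)
  filter
}

#' Rotate every filter of a network
#'
#' Biases, activations and Gaussian parameters are unchanged; only the
#' network's evaluation-time coordinate transform is composed with
#' `R(-theta)`. The resulting network responds to structures rotated by
#' `theta`: evaluating it on a graph whose pseudo-coordinates are rotated by
#' `theta` reproduces the base network's output on the original graph
#' exactly (up to floating point).
#'
#' @param net a [gmm_network()].
#' @param theta rotation angle in radians.
#' @return the rotated network.
#' @export
rotate_network <- function(net, theta) {
  net$transform <- net$transform %*% rotation_matrix(-theta)
  net$angle <- net$angle + theta
  net
}

#' Mirror a network across the vertical axis
#'
#' Every filter's response is reflected: `phi_m(u) = phi((-u_x, u_y))`. A
#' network trained on left-facing structures then responds to their mirror
#' images (e.g. right ears after training on left ears). Applying the mirror
#' twice restores the original responses.
#'
#' @param net a [gmm_network()].
#' @return the mirrored network.
#' @export
mirror_network <- function(net) {
  net$transform <- net$transform %*% diag(c(-1, 1))
  net$mirrored <- !net$mirrored
  net
}

#' Build a bank of rotated networks
#'
#' Returns `count` copies of `net` rotated by angles equally spaced over
#' `[-pi, pi]` (spacing `2*pi / (count - 1)`; for `count = 11` this is
#' `pi/5`). With odd `count` the angle 0 is included and that entry is
#' numerically identical to the base network. The endpoint angles `-pi` and
#' `pi` coincide modulo `2*pi`; both are kept so that the bank has exactly
#' `count` members. `count = 1` gives the single angle 0.
#'
#' @param net a trained [gmm_network()].
#' @param count number of networks in the bank (odd values recommended).
#' @return an object of class `rotation_bank` with elements `base`, `angles`
#'   and `networks`.
#' @export
rotation_bank <- function(net, count = 11) {
  if (count < 1) stopf("count must be >= 1")
  angles <- if (count == 1) 0 else seq(-pi, pi, length.out = count)
  networks <- lapply(angles, function(a) rotate_network(net, a))
  structure(list(base = net, angles = angles, networks = networks),
            class = "rotation_bank")
}

#' @export
print.rotation_bank <- function(x, ...) {
  cat(sprintf("rotation bank: %d networks, angles %s rad\n",
              length(x$angles),
              paste(sprintf("%.3f", x$angles), collapse = ", ")))
  invisible(x)
}
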