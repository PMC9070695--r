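## Binning / debinning operators: the backbone of both multiscale pyramids.
## Binning is block SUMMATION (so white-noise variance multiplies by the block
## size); debinning replicates each coarse value over its block divided by the
## block size, which makes bin(debin(x)) == x exactly and maps constants to
## constants across a bin/debin round trip.

pad_even <- function(x, axes) {
  d <- dim(x)
  pads <- integer(length(d))
  for (a in axes) {
    if (d[a] %% 2 == 1) {
      idx <- lapply(dim(x), seq_len)
      idx[[a]] <- c(seq_len(d[a]), d[a])  # edge replication
      x <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
      d <- dim(x)
      pads[a] <- 1L
    }
  }
  list(x = x, pads = pads)
}

crop_to <- function(x, shape) {
  idx <- lapply(seq_along(shape), function(a) seq_len(shape[a]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

bin_axis <- function(x, axis) {
  d <- dim(x)
  stopifnot(d[axis] %% 2 == 0)
  n <- d[axis] %/% 2L
  odd <- seq.int(1L, d[axis], by = 2L)
  idx1 <- lapply(d, seq_len); idx1[[axis]] <- odd
  idx2 <- lapply(d, seq_len); idx2[[axis]] <- odd + 1L
  do.call(`[`, c(list(x), idx1, list(drop = FALSE))) +
    do.call(`[`, c(list(x), idx2, list(drop = FALSE)))
}

debin_axis <- function(x, axis) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- rep(seq_len(d[axis]), each = 2L)
  do.call(`[`, c(list(x), idx, list(drop = FALSE))) / 2
}

#' Bin a projection stack across both displacement dimensions
#'
#' Sums 2x2 blocks across the horizontal and vertical displacement axes
#' (axes 2 and 3 of the `(angle, h, v)` convention). Each displacement extent
#' halves; the variance of white unit-variance noise becomes 4. Odd extents
#' are first padded by edge replication; the padding is recorded in the
#' `"pads"` attribute so that [debin2d()] can crop back.
#'
#' @param x 3-D numeric array `(angle, h, v)`.
#' @return 3-D array with halved displacement extents, attribute `"pads"`
#'   recording replication padding and `"orig_shape"` the input shape.
#' @export
bin2d <- function(x) {
  stopifnot(length(dim(x)) == 3)
  orig <- dim(x)
  p <- pad_even(x, c(2L, 3L))
  out <- bin_axis(bin_axis(p$x, 2L), 3L)
  attr(out, "pads") <- p$pads
  attr(out, "orig_shape") <- orig
  out
}

#' Debin across the displacement dimensions
#'
#' Default (exact) mode replicates each coarse value into its 2x2 displacement
#' block divided by 4, which guarantees `bin2d(debin2d(x, s)) == x` exactly.
#'
#' @param x 3-D coarse array.
#' @param target_shape shape of the fine array to reproduce (before padding).
#' @return 3-D array of shape `target_shape`.
#' @export
debin2d <- function(x, target_shape) {
  stopifnot(length(dim(x)) == 3, length(target_shape) == 3)
  padded <- c(target_shape[1],
              target_shape[2] + target_shape[2] %% 2,
              target_shape[3] + target_shape[3] %% 2)
  if (!all(dim(x) == c(padded[1], padded[2] %/% 2, padded[3] %/% 2))) {
    stop("coarse shape inconsistent with one 2-D binning step of target shape")
  }
  out <- debin_axis(debin_axis(x, 2L), 3L)
  crop_to(out, target_shape)
}

#' Angular binning to a target coarse angular size
#'
#' Repeatedly sums adjacent angle pairs until the angular extent is at most
#' `max(m_alpha, 32)` by default halving steps (the streak stage operates at a
#' coarse angular scale because streaks are angularly constant).
#'
#' @param x 3-D array `(angle, h, v)`.
#' @param m_alpha target angular size (default 32).
#' @return coarse array with attribute `"n_steps"` (number of halvings) and
#'   `"orig_m0"` (original angular extent).
#' @export
bin_angular <- function(x, m_alpha = 32L) {
  stopifnot(length(dim(x)) == 3)
  if (m_alpha < 1) stop("m_alpha must be >= 1")
  orig_m0 <- dim(x)[1]
  steps <- 0L
  while (dim(x)[1] > m_alpha && dim(x)[1] >= 2) {
    p <- pad_even(x, 1L)
    x <- bin_axis(p$x, 1L)
    steps <- steps + 1L
  }
  attr(x, "n_steps") <- steps
  attr(x, "orig_m0") <- orig_m0
  x
}

#' Angular debinning (inverse of the halving steps of [bin_angular()])
#'
#' @param x coarse array.
#' @param m0 original angular extent.
#' @param n_steps number of halvings performed by [bin_angular()].
#' @return fine array with angular extent `m0`.
#' @export
debin_angular <- function(x, m0, n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- attr(x, "n_steps")
  stopifnot(!is.null(n_steps))
  for (s in seq_len(n_steps)) x <- debin_axis(x, 1L)
  crop_to(x, c(m0, dim(x)[2], dim(x)[3]))
}

#' 3-D binning (2x2x2 block summation, variance of white noise times 8)
#' @param x 3-D array.
#' @return binned array with `"pads"`/`"orig_shape"` attributes.
#' @export
bin3d <- function(x) {
  stopifnot(length(dim(x)) == 3)
  orig <- dim(x)
  p <- pad_even(x, 1:3)
  out <- bin_axis(bin_axis(bin_axis(p$x, 1L), 2L), 3L)
  attr(out, "pads") <- p$pads
  attr(out, "orig_shape") <- orig
  out
}

#' 3-D debinning, exact inverse-on-coarse of [bin3d()]
#' @param x coarse array.
#' @param target_shape fine shape to reproduce.
#' @export
debin3d <- function(x, target_shape) {
  padded <- target_shape + target_shape %% 2
  if (!all(dim(x) == padded %/% 2L)) {
    stop("coarse shape inconsistent with one 3-D binning step of target shape")
  }
  out <- debin_axis(debin_axis(debin_axis(x, 1L), 2L), 3L)
  crop_to(out, target_shape)
}

#' Replace the coarse-scale components of a volume by a coarse estimate
#'
#' Computes `x - debin(bin(x)) + debin(coarse_est)`: the fine detail of `x`
#' is kept while its coarse content is swapped for `coarse_est`. With the
#' default exact debinning this telescopes: if `coarse_est == bin(x)` the
#' result is `x` unchanged.
#'
#' @param x_fine fine-scale volume.
#' @param coarse_est estimate at the binned scale.
#' @param bin_op,debin_op binning operator and matching debinning operator;
#'   `debin_op(coarse, target_shape)` signature.
#' @return array of the shape of `x_fine`.
#' @export
replace_coarse <- function(x_fine, coarse_est, bin_op = bin2d, debin_op = debin2d) {
  b <- bin_op(x_fine)
  if (!all(dim(coarse_est) == dim(b))) {
    stop("coarse_est shape ", paste(dim(coarse_est), collapse = "x"),
         " does not match binned shape ", paste(dim(b), collapse = "x"))
  }
  x_fine - debin_op(b, dim(x_fine)) + debin_op(coarse_est, dim(x_fine))
}

#' Default number of displacement scales for a given stack shape
#'
#' `K = max(1, floor(log2(min(m1, m2) / 64)))`, overridable wherever used;
#' chosen so that the usual choices for small phantoms through large detectors
#' are reachable by override.
#' @param shape 3-vector `(m0, m1, m2)`.
#' @export
default_n_scales <- function(shape) {
  max(1L, floor(log2(min(shape[2], shape[3]) / 64)))
}
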