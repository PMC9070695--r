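## Internal numerical helpers shared across modules: circular FFT convolution,
## small separable kernels, 2-D median and moving polynomial filters.

#' Embed a centered kernel into a zero array of a given shape, wrapping the
#' taps circularly so that the kernel center sits at index (1,1,...).
#' @noRd
embed_kernel <- function(kern, shape) {
  kd <- dim(kern)
  if (is.null(kd)) kd <- length(kern)
  if (length(kd) < length(shape)) {
    kd <- c(kd, rep(1L, length(shape) - length(kd)))
    dim(kern) <- kd
  }
  if (any(kd > shape)) {
    stop("kernel larger than target shape (", paste(kd, collapse = "x"),
         " vs ", paste(shape, collapse = "x"), ")")
  }
  out <- array(0, dim = shape)
  centers <- floor(kd / 2) + 1L
  idx <- lapply(seq_along(kd), function(a) {
    offs <- seq_len(kd[a]) - centers[a]
    ((offs %% shape[a]) + 1L)
  })
  out[as.matrix(expand.grid(idx))] <- kern[as.matrix(expand.grid(lapply(kd, seq_len)))]
  out
}

#' n-D transfer function (FFT) of a centered kernel on a given shape.
#' @noRd
kernel_transfer <- function(kern, shape) {
  stats::fft(embed_kernel(kern, shape))
}

#' Transfer function of a separable kernel given as one 1-D factor per axis
#' (NULL factor = identity / impulse along that axis).
#' @noRd
separable_transfer <- function(factors, shape) {
  stopifnot(length(factors) == length(shape))
  H <- array(1 + 0i, dim = shape)
  for (a in seq_along(factors)) {
    f <- factors[[a]]
    if (is.null(f)) next
    h1 <- stats::fft(embed_kernel(as.numeric(f), shape[a]))
    perm_dim <- rep(1L, length(shape))
    perm_dim[a] <- shape[a]
    H <- H * array(aperm(array(h1, dim = c(shape[a], shape[-a])),
                         order(c(a, seq_along(shape)[-a]))), dim = shape)
  }
  H
}

#' Circular convolution of an array with a centered kernel (or a precomputed
#' transfer function) via FFT.
#' @noRd
fft_convolve <- function(x, kern = NULL, transfer = NULL) {
  shape <- dim(x)
  H <- if (is.null(transfer)) kernel_transfer(kern, shape) else transfer
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / prod(shape)
}

#' Trim margins after circular convolution so only the "valid" region where
#' the kernel did not wrap remains. Guards against degenerate trims by always
#' keeping at least a quarter of each extent.
#' @noRd
trim_valid <- function(x, half_widths) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    h <- half_widths[a]
    keep_min <- max(1L, ceiling(d[a] / 4))
    if (d[a] - 2 * h < keep_min) h <- max(0L, floor((d[a] - keep_min) / 2))
    seq.int(1L + h, d[a] - h)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' 1-D Gaussian kernel, truncated at +/- 3 sigma, unit Euclidean norm.
#' @noRd
gauss1d <- function(sigma, max_len = Inf) {
  if (sigma <= 0) return(1)
  r <- max(1L, floor(3 * sigma))
  len <- 2L * r + 1L
  if (len > max_len) {
    r <- max(0L, floor((max_len - 1) / 2))
    len <- 2L * r + 1L
  }
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sqrt(sum(g^2))
}

#' Daubechies db3 decomposition high-pass filter
#'
#' The 6-tap unit-norm high-pass used by every estimation probe. Taps are
#' derived from the standard db3 scaling coefficients via the
#' quadrature-mirror relation `g[n] = (-1)^n h[5-n]`.
#' @return numeric vector of length 6 with zero sum and unit Euclidean norm.
#' @export
db3_highpass_taps <- function() db3_highpass()

#' @noRd
db3_highpass <- function() {
  h <- c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132,
         -0.13501102001039084, -0.08544127388224149, 0.03522629188210562)
  n <- 0:5
  g <- (-1)^n * h[6 - n]
  g <- g - mean(g)        # enforce exact zero DC
  g / sqrt(sum(g^2))      # and exact unit Euclidean norm
}

#' 2-D median filter with replicate padding (square window, odd width).
#' @noRd
medfilt2 <- function(img, width = 5L) {
  stopifnot(width %% 2 == 1)
  r <- (width - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)
  pad <- img[ri, ci, drop = FALSE]
  stack <- array(NA_real_, dim = c(nr, nc, width * width))
  s <- 1L
  for (i in seq_len(width)) {
    for (j in seq_len(width)) {
      stack[, , s] <- pad[(i):(i + nr - 1L), (j):(j + nc - 1L)]
      s <- s + 1L
    }
  }
  apply(stack, c(1, 2), stats::median)
}

#' Moving 2-D quadratic (Savitzky-Golay) smoothing: local least-squares fit of
#' 1, x, y, x^2, xy, y^2 over a square window; returns the fitted surface.
#' Equivalent to convolution with the SG kernel; replicate padding at edges.
#' @noRd
sg2d_smooth <- function(img, width = 15L) {
  stopifnot(width %% 2 == 1)
  r <- (width - 1L) %/% 2L
  offs <- -r:r
  gx <- rep(offs, times = width)
  gy <- rep(offs, each = width)
  X <- cbind(1, gx, gy, gx^2, gx * gy, gy^2)
  w <- solve(crossprod(X), t(X))[1, ]       # central-value SG weights
  kern <- matrix(w, nrow = width)           # column-major matches gx fast, gy slow
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(width)) {
    for (j in seq_len(width)) {
      out <- out + kern[i, j] * pad[(i):(i + nr - 1L), (j):(j + nc - 1L)]
    }
  }
  out
}

#' Gaussian-smoothed 3-D low-pass used in the multiscale recombination.
#' @noRd
gauss_smooth3d <- function(x, sigma) {
  g <- gauss1d(sigma)
  g <- g / sum(g)  # unit DC gain for smoothing
  H <- separable_transfer(list(g, g, g), dim(x))
  fft_convolve(x, transfer = H)
}
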