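## Stationary correlated noise represented interchangeably by a correlation
## kernel g (noise = g convolved with unit white Gaussian noise) or by its
## power spectral density Psi.
##
## Fourier convention: unnormalized forward transform, 1/|X| inverse; the PSD
## of noise g (*) nu on a domain X is Psi(f) = |X| * |F(g)(f)|^2, so that
## mean(Psi) = |X| * (per-pixel noise variance) and a unit impulse kernel has
## the flat PSD Psi == |X| (unit white noise).

fftshift_array <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    s <- floor(n / 2)
    c(seq.int(n - s + 1L, n), seq_len(n - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Euclidean norm of a correlation kernel
#' @param g numeric array of kernel taps.
#' @export
kernel_norm <- function(g) sqrt(sum(g^2))

#' Power spectral density induced by a correlation kernel
#'
#' `psd = |X| * |F(g)|^2` with the kernel zero-padded and centered in the
#' target shape. A unit impulse kernel yields the flat PSD `|X|` (unit-variance
#' white noise); in general `mean(psd) / |X|` equals the per-pixel noise
#' variance `sum(g^2)` (Parseval).
#'
#' @param g kernel taps (1-, 2- or 3-D array, treated as centered).
#' @param shape extents of the volume the PSD describes.
#' @return nonnegative array of dimension `shape`.
#' @export
psd_from_kernel <- function(g, shape) {
  H <- kernel_transfer(g, shape)  # errors if kernel larger than shape
  prod(shape) * (Mod(H)^2)
}

#' Zero-phase correlation kernel from a power spectral density
#'
#' Inverse Fourier transform of `sqrt(psd / |X|)`; returned fftshifted so that
#' the kernel center sits at the middle of the array, matching the centered
#' kernel convention of [psd_from_kernel()]. Round trip
#' `psd_from_kernel(kernel_from_psd(psd), dim(psd))` is the identity on
#' nonnegative PSDs.
#'
#' @param psd nonnegative array.
#' @return real array of the same shape, the zero-phase kernel.
#' @export
kernel_from_psd <- function(psd) {
  if (any(psd < 0)) stop("PSD must be nonnegative")
  n <- prod(dim(psd))
  g <- Re(stats::fft(sqrt(psd / n), inverse = TRUE)) / n
  fftshift_array(g)
}

#' Correlation kernels of the three angularly constant streak components
#'
#' The streak noise at scale `k` is approximated by three angularly constant
#' components distinct in the displacement: `w` is white across both
#' displacement dimensions, `u` is constant across horizontal displacement,
#' and `v` is constant across vertical displacement. Each kernel is constant
#' along its long axes, an impulse along the others, normalized to unit
#' Euclidean norm at scale 0 and scaled by `2^k` at scale `k` (2-D binning
#' sums along two dimensions, so the coarser-scale variance is four times the
#' finer one).
#'
#' @param k scale index (>= 0).
#' @param shape extents `(m0, m1, m2)` of the scale-`k` volume.
#' @return object of class `"streak_components"`: list with kernels `g_w`,
#'   `g_u`, `g_v`, the `scale` and the `shape`.
#' @export
make_streak_kernels <- function(k, shape) {
  stopifnot(k >= 0, length(shape) == 3)
  m0 <- shape[1]; m1 <- shape[2]; m2 <- shape[3]
  s <- 2^k
  g_w <- array(s / sqrt(m0), dim = c(m0, 1, 1))
  g_u <- array(s / sqrt(m0 * m1), dim = c(m0, m1, 1))
  g_v <- array(s / sqrt(m0 * m2), dim = c(m0, 1, m2))
  structure(list(g_w = g_w, g_u = g_u, g_v = g_v,
                 scale = k, shape = shape),
            class = "streak_components")
}

#' Squared transfer of the equivalent low-pass of bin-then-debin
#'
#' Pairwise binning followed by exact debinning acts (up to shift variance)
#' as convolution with the two-tap averaging kernel `[1/2, 1/2]` along each
#' binned axis; this returns `|F(h)|^2` for one axis of length `n`.
#' @noRd
pair_average_power <- function(n) {
  f <- seq_len(n) - 1
  cos(pi * f / n)^2
}

#' Residual kernel of 2-D binning of white noise
#'
#' The residual `eta - debin(bin(eta))` of 2-D unit white noise `eta` is
#' characterized (in the stationary approximation) by a 2-D kernel `q` whose
#' transfer is `F(q) = sqrt(max(0, 1 - |F(h)|^2))`, `h` being the equivalent
#' 2x2 averaging low-pass of the bin/debin round trip. Computed in closed
#' form; validated against the Monte-Carlo residual in the test suite.
#'
#' @param shape_2d extents `(n1, n2)` (even; the formula holds for any size).
#' @return 2-D real kernel array of dimension `shape_2d` (fftshift-centered).
#' @export
binning_residual_kernel <- function(shape_2d) {
  stopifnot(length(shape_2d) == 2)
  Q <- binning_residual_power(shape_2d)
  n <- prod(shape_2d)
  q <- Re(stats::fft(sqrt(Q), inverse = TRUE)) / n
  dim(q) <- shape_2d
  fftshift_array(q)
}

#' Squared transfer `|F(q)|^2` of the 2-D binning residual kernel.
#' @noRd
binning_residual_power <- function(shape_2d) {
  p1 <- pair_average_power(shape_2d[1])
  p2 <- pair_average_power(shape_2d[2])
  pmax(0, 1 - outer(p1, p2))
}

#' Streak PSD of a scale from component strengths
#'
#' Builds the scale-`k` streak PSD as the sum over components `p` of
#' `varsigma_p^2` times the PSD induced by the component kernel `g_{k,p}`,
#' optionally multiplied by the binning-residual transfer: at every scale
#' except the coarsest, the coarse content has been replaced by the (treated
#' as perfectly denoised) coarser estimate, so only the residual
#' `eta - debin(bin(eta))` of each component remains. For the angularly
#' constant components the residual profile is the 2-D residual `q` for the
#' white component and the 1-D pair-averaging residual along the non-constant
#' displacement axis for the `u`/`v` components (binning preserves constants
#' exactly along their constant axes). The result is nonzero only on the
#' angular-DC plane.
#'
#' @param params list or numeric with nonnegative `varsigma_w`, `varsigma_u`,
#'   `varsigma_v` (see [streak_params()]).
#' @param set `"streak_components"` object from [make_streak_kernels()].
#' @param shape volume extents; must equal `set$shape`.
#' @param residual if `TRUE` (the non-coarsest scales), compose the binning
#'   residual PSDs instead of the full component PSDs.
#' @return PSD array of dimension `shape`.
#' @export
compose_scale_psd <- function(params, set, shape = set$shape, residual = FALSE) {
  p <- streak_params(params)
  if (any(unlist(p) < 0)) stop("streak strengths must be nonnegative")
  stopifnot(all(shape == set$shape))
  m0 <- shape[1]; m1 <- shape[2]; m2 <- shape[3]
  n <- prod(shape)
  s2 <- 4^set$scale
  dc <- matrix(0, m1, m2)  # angular-DC plane across displacement frequencies
  if (p$varsigma_w > 0) {
    prof <- if (residual) binning_residual_power(c(m1, m2)) else 1
    dc <- dc + p$varsigma_w^2 * s2 * m0 * n * prof
  }
  if (p$varsigma_u > 0) {
    prof <- if (residual) pmax(0, 1 - pair_average_power(m2)) else rep(1, m2)
    line <- p$varsigma_u^2 * s2 * m0 * m1 * n * prof
    dc[1, ] <- dc[1, ] + line
  }
  if (p$varsigma_v > 0) {
    prof <- if (residual) pmax(0, 1 - pair_average_power(m1)) else rep(1, m1)
    line <- p$varsigma_v^2 * s2 * m0 * m2 * n * prof
    dc[, 1] <- dc[, 1] + line
  }
  psd <- array(0, dim = shape)
  psd[1, , ] <- dc
  psd
}

#' Streak strength triple
#' @param varsigma_w,varsigma_u,varsigma_v nonnegative scalars, or a single
#'   numeric vector/list of length 3 passed as the first argument.
#' @return list with elements `varsigma_w`, `varsigma_u`, `varsigma_v`.
#' @export
streak_params <- function(varsigma_w = 0, varsigma_u = 0, varsigma_v = 0) {
  if (is.list(varsigma_w) || length(varsigma_w) == 3) {
    v <- unlist(varsigma_w)
    return(list(varsigma_w = v[[1]], varsigma_u = v[[2]], varsigma_v = v[[3]]))
  }
  list(varsigma_w = varsigma_w, varsigma_u = varsigma_u, varsigma_v = varsigma_v)
}

#' Frequency support removed by the streak stage
#'
#' Logical mask of the frequencies the streak filtering acts on: the
#' angular-DC plane restricted to displacement frequencies below the Nyquist
#' of the coarsest streak scale (streak filtering operates on binned, i.e.
#' low, displacement frequencies of the angular-DC plane).
#'
#' @param shape volume extents.
#' @param n_scales number of displacement binning scales `K` of the streak
#'   stage.
#' @return logical array of dimension `shape`.
#' @export
streak_support_mask <- function(shape, n_scales = default_n_scales(shape)) {
  m1 <- shape[2]; m2 <- shape[3]
  lim1 <- m1 / 2^(n_scales + 1)
  lim2 <- m2 / 2^(n_scales + 1)
  f1 <- pmin(seq_len(m1) - 1, m1 - (seq_len(m1) - 1))
  f2 <- pmin(seq_len(m2) - 1, m2 - (seq_len(m2) - 1))
  plane <- outer(f1 <= lim1, f2 <= lim2, `&`)
  mask <- array(FALSE, dim = shape)
  mask[1, , ] <- plane
  mask
}

#' Flat PSD for the stabilized Poisson stage, notched at streak frequencies
#'
#' The stabilized Poisson noise is approximately white, but the preceding
#' streak stage is assumed to have removed all streak-frequency content
#' (including that of the Poisson component). The PSD is therefore flat at
#' `c * |X|` (`c` the per-pixel variance of the stabilized noise) and zeroed
#' on the streak support. With an empty support this reduces to the flat
#' white PSD used when no streak removal precedes the Poisson stage.
#'
#' @param shape volume extents.
#' @param c per-pixel noise variance (>= 0).
#' @param streak_support logical mask as from [streak_support_mask()], or
#'   `NULL` for no notch.
#' @return PSD array of dimension `shape`.
#' @export
poisson_stage_psd <- function(shape, c, streak_support = NULL) {
  if (c < 0) stop("c must be nonnegative")
  psd <- array(c * prod(shape), dim = shape)
  if (!is.null(streak_support)) psd[streak_support] <- 0
  psd
}

#' Draw stationary correlated noise with a given PSD
#'
#' Synthesizes `g (*) nu` for unit white Gaussian `nu` by spectral coloring;
#' used by the Monte-Carlo checks of the variance bookkeeping.
#' @param psd nonnegative PSD array.
#' @return real array of the same shape.
#' @export
draw_correlated_noise <- function(psd) {
  shape <- dim(psd)
  n <- prod(shape)
  nu <- array(stats::rnorm(n), dim = shape)
  Re(stats::fft(stats::fft(nu) * sqrt(psd / n), inverse = TRUE)) / n
}
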