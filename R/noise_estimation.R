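## Self-calibration of noise strength: robust (MAD-based) standard-deviation
## probes through anisotropic separable kernels, and non-negative least
## squares unmixing of the probe responses into the three streak components.

#' Robust standard deviation of filtered noise via the MAD
#'
#' Convolves `z` with the probe kernel `g_d` (circularly, then trims the
#' wrapped margins) and computes
#' `1.4826 * median(|r - median(r)|)` on the valid region. The factor 1.4826
#' calibrates the median absolute deviation to the standard deviation of
#' normally distributed noise. The sample median is subtracted first so the
#' estimate is robust to a nonzero-mean filtered signal (the high-pass probe
#' factors make the mean approximately zero anyway).
#'
#' @param z 3-D array.
#' @param g_d probe kernel: either an array of taps or a list of three 1-D
#'   factors (separable probe; `NULL` factor = impulse).
#' @param prob quantile of the absolute deviations used as the scale
#'   statistic. The default 0.5 is the MAD with its normal-consistency
#'   constant `1.4826 = 1/qnorm(3/4)`; lower quantiles (calibrated by
#'   `1/qnorm((1+prob)/2)`) are more robust when signal contaminates more
#'   than half of the probe response, at the price of higher estimator
#'   variance.
#' @return nonnegative scalar estimate of `sd(z (*) g_d)`.
#' @export
mad_std <- function(z, g_d, prob = 0.5) {
  shape <- dim(z)
  if (is.list(g_d)) {
    half <- vapply(seq_along(g_d), function(a) {
      if (is.null(g_d[[a]])) 0L else as.integer(length(g_d[[a]]) %/% 2)
    }, integer(1))
    if (any(vapply(seq_along(g_d), function(a)
      !is.null(g_d[[a]]) && length(g_d[[a]]) > shape[a], logical(1)))) {
      stop("volume smaller than probe kernel")
    }
    r <- fft_convolve(z, transfer = separable_transfer(g_d, shape))
  } else {
    kd <- dim(g_d); if (is.null(kd)) kd <- length(g_d)
    kd <- c(kd, rep(1L, 3 - length(kd)))
    if (any(kd > shape)) stop("volume smaller than probe kernel")
    half <- as.integer(kd %/% 2)
    r <- fft_convolve(z, kern = g_d)
  }
  r <- trim_valid(r, half)
  dev <- abs(r - stats::median(r))
  if (prob == 0.5) {
    1.4826 * stats::median(dev)
  } else {
    stats::quantile(dev, prob, names = FALSE) / stats::qnorm((1 + prob) / 2)
  }
}

#' Component strength from a filtered-noise standard deviation
#'
#' If the noise is `varsigma * (g_s (*) nu)` then the standard deviation of
#' the probe response is `varsigma * ||g_s (*) g_d||`, so
#' `varsigma_hat = sigma_hat / ||g_s (*) g_d||`.
#'
#' @param sigma_hat probe-response standard deviation (e.g. from [mad_std()]).
#' @param g_s unscaled component kernel (array of taps).
#' @param g_d probe kernel (array or separable factor list).
#' @param shape volume extents over which the convolution norm is evaluated.
#' @return nonnegative scalar estimate of `varsigma`.
#' @export
scale_from_std <- function(sigma_hat, g_s, g_d, shape) {
  nrm <- sqrt(convolved_norm2(g_s, g_d, shape))
  if (nrm <= 0) stop("probe is orthogonal to the component (zero response norm)")
  sigma_hat / nrm
}

#' `||g_s (*) g_d||^2` over a finite domain, computed spectrally.
#' @noRd
convolved_norm2 <- function(g_s, g_d, shape) {
  n <- prod(shape)
  Hs <- kernel_transfer(g_s, shape)
  Hd <- if (is.list(g_d)) separable_transfer(g_d, shape) else kernel_transfer(g_d, shape)
  sum(Mod(Hs)^2 * Mod(Hd)^2) / n
}

#' Build the anisotropic probe kernel bank for streak estimation
#'
#' Three separable probes, each a tensor product of three 1-D factors chosen
#' by the noise statistics along each dimension: a Gaussian low-pass
#' `phi_0` along the angle (sd `m0/8`) preserves the angularly constant
#' streaks while averaging out signal and white noise; Gaussian low-passes
#' `phi_1`, `phi_2` (sd `m1/12`, `m2/12`) preserve displacement-constant
#' streaks; the 6-tap Daubechies db3 high-pass `psi` suppresses smooth signal
#' along the remaining axes. The probes target
#' high-frequency streaks (`g_w = phi_0 x psi x psi`), horizontally
#' low-frequency streaks (`g_u = phi_0 x phi_1 x psi`) and vertically
#' low-frequency streaks (`g_v = phi_0 x psi x phi_2`). Gaussians are
#' truncated at 3 sd; every factor has unit Euclidean norm.
#'
#' @param shape volume extents `(m0, m1, m2)`, each at least 8.
#' @return object of class `"probe_bank"`: named list of separable factor
#'   lists `g_w`, `g_u`, `g_v` (streak probes), `g_pi` (an all-axes
#'   high-pass probe targeting 3-D white noise, used as a nuisance channel
#'   so that Poissonian noise in the data does not inflate the streak
#'   estimates) plus the `shape`.
#' @export
build_probe_bank <- function(shape) {
  if (any(shape < 8)) stop("degenerate dimensions: all extents must be >= 8")
  m0 <- shape[1]; m1 <- shape[2]; m2 <- shape[3]
  phi0 <- gauss1d(m0 / 8, max_len = m0)
  phi1 <- gauss1d(m1 / 12, max_len = m1)
  phi2 <- gauss1d(m2 / 12, max_len = m2)
  psi <- db3_highpass()
  structure(list(
    g_w = list(phi0, psi, psi),
    g_u = list(phi0, phi1, psi),
    g_v = list(phi0, psi, phi2),
    g_pi = list(psi, psi, psi),
    shape = shape
  ), class = "probe_bank")
}

#' Probe response matrix `M[q, p] = ||g_{k,p} (*) g_probe_q||^2`
#'
#' Row `q`, column `p`: squared response norm of probe `q` to the unit-strength
#' streak component `p`, evaluated over the volume; with `residual = TRUE` the
#' binning-residual component PSDs are used instead of the full ones. The
#' white streak component overlaps in frequency with the low-frequency probes,
#' so the matrix is far from diagonal; the unmixing accounts for this leakage.
#'
#' @param set `"streak_components"` from [make_streak_kernels()].
#' @param bank `"probe_bank"` from [build_probe_bank()].
#' @param shape volume extents.
#' @param residual use residual component PSDs (non-coarsest scales).
#' @return 4x4 matrix, rows `(w, u, v, pi)` probes, columns
#'   `(w, u, v, white)` components; the `white` column is the response to
#'   unit-variance 3-D white noise (exactly 1 for every unit-norm probe).
#' @export
probe_response_matrix <- function(set, bank, shape = set$shape, residual = FALSE) {
  n <- prod(shape)
  comps <- c("varsigma_w", "varsigma_u", "varsigma_v")
  M <- matrix(0, 4, 4, dimnames = list(c("w", "u", "v", "pi"),
                                       c("w", "u", "v", "white")))
  Hq <- lapply(1:4, function(q) Mod(separable_transfer(bank[[q]], shape))^2)
  for (p in 1:3) {
    unit <- as.list(c(0, 0, 0)); names(unit) <- comps
    unit[[p]] <- 1
    psd_p <- compose_scale_psd(unit, set, shape, residual = residual)
    for (q in 1:4) {
      # ||g_p (*) g_q||^2 = (1/n^2) sum Psi_p |F(g_q)|^2
      M[q, p] <- sum(psd_p * Hq[[q]]) / n^2
    }
  }
  for (q in 1:4) M[q, 4] <- sum(Hq[[q]]) / n  # unit flat PSD -> ||g_q||^2 = 1
  M
}

#' Unmix probe standard deviations into streak component strengths
#'
#' Solves the non-negative least-squares problem
#' `min_{x >= 0} || M x - sigma_hat^2 ||` on the `varsigma^2` scale, where
#' `M` is the probe response matrix, by enumerating all active sets of this
#' small problem (exact at this size); ties and degeneracy resolve toward
#' the white-streak and 3-D white components. The fourth unknown absorbs
#' 3-D white (Poissonian) noise so it does not inflate the streak
#' strengths; it is reported as `varsigma_white` but takes no part in the
#' streak PSD. Returns `varsigma = sqrt(x)`.
#'
#' @param sigma_hat numeric length 4: probe response sds `(w, u, v, pi)`
#'   (length 3 accepted: the white channel is then dropped from the system).
#' @param set,bank,shape,residual as in [probe_response_matrix()], or pass a
#'   precomputed matrix via `M`.
#' @param M optional precomputed response matrix.
#' @return [streak_params()] list with an extra `varsigma_white` element.
#' @export
unmix_components <- function(sigma_hat, set = NULL, bank = NULL,
                             shape = set$shape, residual = FALSE, M = NULL) {
  stopifnot(length(sigma_hat) %in% c(3, 4), all(sigma_hat >= 0))
  if (is.null(M)) M <- probe_response_matrix(set, bank, shape, residual)
  nv <- length(sigma_hat)
  M <- M[seq_len(nv), seq_len(nv), drop = FALSE]
  b <- sigma_hat^2
  best <- NULL; best_rss <- Inf
  # all active sets, larger first, ties resolved toward w (1) and white (4)
  supports <- lapply(0:(2^nv - 1), function(m) which(bitwAnd(m, 2^(seq_len(nv) - 1)) > 0))
  pref <- vapply(supports, function(s) {
    -(length(s) * 10 + (1 %in% s) * 2 + (nv %in% s))
  }, numeric(1))
  supports <- supports[order(pref)]
  for (s in supports) {
    x <- numeric(nv)
    if (length(s) > 0) {
      Ms <- M[, s, drop = FALSE]
      sol <- tryCatch(qr.solve(crossprod(Ms), crossprod(Ms, b)),
                      error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) next
      x[s] <- sol
    }
    rss <- sum((M %*% x - b)^2)
    if (is.finite(rss) &&
        (!is.finite(best_rss) || rss < best_rss - 1e-15 * (1 + best_rss))) {
      best_rss <- rss; best <- x
    }
  }
  if (is.null(best)) best <- numeric(nv)
  out <- streak_params(sqrt(pmax(best[1:3], 0)))
  out$varsigma_white <- if (nv == 4) sqrt(max(best[4], 0)) else NA_real_
  out
}

#' Estimate streak strengths from one volume segment
#'
#' Composition of the probe MAD estimates and the non-negative unmixing,
#' applied to a single (sub)volume: each segment is treated as stationary and
#' gets its own parameter triple.
#'
#' @param segment 3-D array.
#' @param set `"streak_components"` for the segment's scale (shapes need not
#'   match the segment; the response matrix is evaluated on the segment
#'   shape).
#' @param bank probe bank built for the segment shape (rebuilt if shapes
#'   differ).
#' @param residual use residual component PSDs.
#' @param prob quantile passed to [mad_std()]; the pipeline default 0.25
#'   trades estimator variance for robustness against signal contamination
#'   of the probe responses (on small binned volumes the signal response can
#'   cover more than half of the voxels, which breaks the plain MAD).
#' @return [streak_params()] list.
#' @export
estimate_segment_params <- function(segment, set, bank = NULL, residual = FALSE,
                                    prob = 0.25) {
  shape <- dim(segment)
  if (is.null(bank) || !all(bank$shape == shape)) bank <- build_probe_bank(shape)
  seg_set <- make_streak_kernels(set$scale, shape)
  sig <- vapply(1:4, function(q) mad_std(segment, bank[[q]], prob = prob), numeric(1))
  unmix_components(sig, seg_set, bank, shape, residual = residual)
}
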