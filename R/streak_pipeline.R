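## Stage 1: extreme-streak pre-attenuation, then coarse-to-fine multiscale
## streak removal with per-segment adaptive PSDs. Streaks are angularly
## constant, so the whole stage operates at a coarse angular scale; only the
## angularly-binned subspace of the input is ever modified.

#' Streak-stage configuration
#'
#' @param n_scales number of 2-D displacement binning scales `K`
#'   (default [default_n_scales()] of the input shape).
#' @param m_alpha target coarse angular size (default 32).
#' @param seg_size displacement extents of the denoising segments (default
#'   `c(256, 256)`; segments always span the full angular extent because
#'   streaks are angularly constant).
#' @param overlap segment overlap fraction (default 0.5).
#' @param profile [filter_profile()] for the collaborative filter.
#' @param extreme_tau threshold multiplier of the extreme-streak detector.
#' @export
streak_config <- function(n_scales = NULL, m_alpha = 32L,
                          seg_size = c(256L, 256L), overlap = 0.5,
                          profile = filter_profile(), extreme_tau = 4) {
  list(n_scales = n_scales, m_alpha = as.integer(m_alpha),
       seg_size = as.integer(seg_size), overlap = overlap,
       profile = profile, extreme_tau = extreme_tau)
}

#' 1-D segment layout with raised-cosine windows forming a partition of unity
#' @noRd
segment_axis <- function(n, seg, overlap = 0.5) {
  if (seg >= n) {
    return(list(list(idx = seq_len(n), win = rep(1, n))))
  }
  step <- max(1L, as.integer(round(seg * (1 - overlap))))
  starts <- seq.int(1L, n - seg + 1L, by = step)
  if (starts[length(starts)] != n - seg + 1L) starts <- c(starts, n - seg + 1L)
  segs <- lapply(starts, function(s) {
    idx <- s:(s + seg - 1L)
    w <- 0.01 + sin(pi * (seq_len(seg) - 0.5) / seg)^2  # floored Hann
    list(idx = idx, win = w)
  })
  # rescale to a partition of unity
  tot <- numeric(n)
  for (sg in segs) tot[sg$idx] <- tot[sg$idx] + sg$win
  lapply(segs, function(sg) {
    sg$win <- sg$win / tot[sg$idx]
    sg
  })
}

#' Segment-wise denoising with windowed recombination
#'
#' Splits the volume into overlapping displacement segments (full angular
#' extent), denoises each segment as a separate stationary volume via
#' `denoiser`, and recombines the segment estimates with raised-cosine
#' windows rescaled to a partition of unity.
#'
#' @param volume 3-D array `(angle, h, v)`.
#' @param denoiser function taking a segment (3-D array) and returning its
#'   denoised version (typically: estimate per-segment parameters, build the
#'   segment PSD, run [denoise_volume()]).
#' @param seg_size displacement extents of the segments.
#' @param overlap overlap fraction.
#' @return denoised volume.
#' @export
segment_denoise <- function(volume, denoiser, seg_size = c(256L, 256L),
                            overlap = 0.5) {
  d <- dim(volume)
  segs_h <- segment_axis(d[2], min(seg_size[1], d[2]), overlap)
  segs_v <- segment_axis(d[3], min(seg_size[2], d[3]), overlap)
  out <- array(0, dim = d)
  for (sh in segs_h) {
    for (sv in segs_v) {
      sub <- volume[, sh$idx, sv$idx, drop = FALSE]
      est <- denoiser(sub)
      w <- outer(sh$win, sv$win)
      wa <- aperm(array(w, dim = c(length(sh$idx), length(sv$idx), d[1])),
                  c(3, 1, 2))
      out[, sh$idx, sv$idx] <- out[, sh$idx, sv$idx] + est * wa
    }
  }
  out
}

#' Attenuate extreme streaks from scintillator defects
#'
#' Streaks caused by defective detector pixels can be far stronger than the
#' stationary streak model allows and are removed before the multiscale
#' stage: the angular-median image `M(h, v)` is compared with a smooth local
#' quadratic (moving 15x15 Savitzky-Golay) fit; detector pixels deviating by
#' more than `tau` robust standard deviations are flagged and their full
#' angular column is replaced, per angle, by the median over the 3x3
#' displacement neighborhood. Two additional conditions keep signal
#' structure from being treated as defects: the pixel must spike against its
#' own 3x3 neighborhood median (defects are point-like, signal edges form
#' ridges), and the deviation from the neighborhood must be consistent
#' across the angle (a defect offsets its detector pixel by the same amount
#' at every angle, whereas thin sinogram features vary strongly with it).
#'
#' @param Z log-domain stack `(angle, h, v)`.
#' @param tau threshold multiplier (default 4).
#' @param fit_window Savitzky-Golay window width (default 15).
#' @param max_flag_frac upper bound on the fraction of detector pixels that
#'   may be flagged (default 0.01): defects are sparse by nature, and the
#'   cap prevents mass replacement when sharp signal structure inflates the
#'   fit residuals (only the strongest spikes are kept).
#' @return stack with extreme streak columns replaced; attribute
#'   `"n_flagged"` gives the number of detector pixels treated.
#' @export
attenuate_extreme_streaks <- function(Z, tau = 4, fit_window = 15L,
                                      max_flag_frac = 0.01) {
  d <- dim(Z)
  M <- apply(Z, c(2, 3), stats::median)
  Mhat <- sg2d_smooth(M, min(fit_window, 2L * (min(d[2:3]) %/% 2L) - 1L))
  resid <- M - Mhat
  # robust scales floored at a small fraction of the dynamic range: on
  # majority-constant data the MAD is exactly zero and would declare
  # numerically tiny deviations "extreme"
  floor_s <- 1e-3 * max(diff(stats::quantile(M, c(0.05, 0.95), names = FALSE)),
                        .Machine$double.eps)
  s <- max(1.4826 * stats::median(abs(resid - stats::median(resid))), floor_s)
  med3 <- medfilt2(M, 3L)
  spike <- M - med3                   # point defects spike against neighbors
  s2 <- max(1.4826 * stats::median(abs(spike - stats::median(spike))), floor_s)
  crit <- abs(resid) > tau * s & abs(spike) > tau * s2
  # the local fit is unreliable inside the padded border: no flags there
  mar <- (min(fit_window, dim(M)[1], dim(M)[2]) - 1L) %/% 2L
  if (mar > 0) {
    crit[c(seq_len(min(mar, d[2])), seq.int(max(1L, d[2] - mar + 1L), d[2])), ] <- FALSE
    crit[, c(seq_len(min(mar, d[3])), seq.int(max(1L, d[3] - mar + 1L), d[3]))] <- FALSE
  }
  cand <- which(crit, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    consistent <- vapply(seq_len(nrow(cand)), function(r) {
      h <- cand[r, 1]; v <- cand[r, 2]
      hs <- max(1L, h - 1L):min(d[2], h + 1L)
      vs <- max(1L, v - 1L):min(d[3], v + 1L)
      nb <- matrix(Z[, hs, vs], d[1])
      dev <- Z[, h, v] - apply(nb, 1, stats::median)
      spread <- 1.4826 * stats::median(abs(dev - stats::median(dev)))
      abs(stats::median(dev)) > 1.5 * (spread + floor_s)
    }, logical(1))
    cand <- cand[consistent, , drop = FALSE]
  }
  flagged <- cand
  cap <- max(1L, floor(max_flag_frac * prod(d[2:3])))
  if (nrow(flagged) > cap) {
    keep <- order(abs(spike[flagged]), decreasing = TRUE)[seq_len(cap)]
    flagged <- flagged[keep, , drop = FALSE]
  }
  if (nrow(flagged) > 0) {
    for (r in seq_len(nrow(flagged))) {
      h <- flagged[r, 1]; v <- flagged[r, 2]
      hs <- max(1L, h - 1L):min(d[2], h + 1L)
      vs <- max(1L, v - 1L):min(d[3], v + 1L)
      nb <- Z[, hs, vs, drop = FALSE]
      Z[, h, v] <- apply(matrix(nb, d[1]), 1, stats::median)
    }
  }
  attr(Z, "n_flagged") <- nrow(flagged)
  Z
}

#' Multiscale streak denoising (stage 1 core)
#'
#' Coarse-to-fine recursion: (i) angular binning to the coarse angular scale;
#' (ii) a pyramid of 2-D displacement binnings `Z_0..Z_K`; (iii) the coarsest
#' volume is denoised first; (iv) descending the pyramid, the coarse content
#' of each `Z_k` is replaced by the (treated as perfectly denoised) coarser
#' estimate before denoising with a PSD modeling only the fine streak
#' components plus binning residuals; (v) finally only the coarse angular
#' components of the full stack are replaced by the finest-scale estimate, so
#' the high-frequency angular residual of the input passes through untouched.
#' Each denoising call is segment-wise with per-segment strengths estimated
#' from that segment.
#'
#' @param Z log-domain stack `(angle, h, v)`.
#' @param cfg [streak_config()].
#' @param denoiser optional override of the per-segment denoiser, a function
#'   `(segment, scale, residual) -> estimate`; `NULL` uses the PSD-adaptive
#'   collaborative filter (pass `function(s, k, r) s` for the identity).
#' @return estimate of the streak-free stack, with attribute `"params"`:
#'   per-scale list of per-segment strength triples.
#' @export
multiscale_streak_denoise <- function(Z, cfg = streak_config(), denoiser = NULL) {
  d <- dim(Z)
  K <- if (is.null(cfg$n_scales)) default_n_scales(d) else cfg$n_scales
  Za <- bin_angular(Z, cfg$m_alpha)
  n_steps <- attr(Za, "n_steps")

  pyramid <- vector("list", K + 1)
  pyramid[[1]] <- Za
  for (k in seq_len(K)) pyramid[[k + 1]] <- bin2d(pyramid[[k]])

  params_log <- vector("list", K + 1)
  denoise_scale <- function(vol, k, residual) {
    seg_params <- list()
    fn <- if (is.null(denoiser)) {
      function(seg) {
        set <- make_streak_kernels(k, dim(seg))
        p <- estimate_segment_params(seg, set, residual = residual)
        seg_params[[length(seg_params) + 1L]] <<- p
        psd <- compose_scale_psd(p, set, residual = residual)
        denoise_volume(seg, psd, cfg$profile)
      }
    } else {
      function(seg) {
        seg_params[[length(seg_params) + 1L]] <<- NULL
        denoiser(seg, k, residual)
      }
    }
    est <- segment_denoise(vol, fn, cfg$seg_size, cfg$overlap)
    params_log[[k + 1]] <<- seg_params
    est
  }

  est <- denoise_scale(pyramid[[K + 1]], K, residual = FALSE)
  for (k in rev(seq_len(K) - 1L)) {  # k = K-1 .. 0
    zt <- replace_coarse(pyramid[[k + 1]], est, bin2d, debin2d)
    est <- denoise_scale(zt, k, residual = TRUE)
  }

  out <- replace_coarse(
    Z, est,
    bin_op = function(x) bin_angular(x, cfg$m_alpha),
    debin_op = function(co, ts) debin_angular(co, ts[1], n_steps)
  )
  attr(out, "params") <- params_log
  out
}

#' Full streak stage: extreme-streak pre-attenuation + multiscale denoising
#' @param Z log-domain stack.
#' @param cfg [streak_config()].
#' @return streak-free estimate `Yhat`.
#' @export
streak_stage <- function(Z, cfg = streak_config()) {
  Z2 <- attenuate_extreme_streaks(Z, cfg$extreme_tau)
  multiscale_streak_denoise(Z2, cfg)
}
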