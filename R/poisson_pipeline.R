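## Stage 2: undo the bright-field-induced variance scaling, estimate and
## apply a data-driven variance-stabilizing transform (VST), denoise the
## stabilized stack at multiple 3-D scales with a streak-notched flat PSD,
## invert the VST (exact-unbiased), and remove the field.

#' Poisson-stage configuration
#'
#' @param k_poi number of 3-D binning scales (default 1).
#' @param vst_degree degree of the variance polynomial `F` (default 2,
#'   up to 5 supported).
#' @param recomb_sigma Gaussian low-pass sd (pixels) used when recombining
#'   scales: only the low frequencies of the coarser estimate are kept,
#'   because its high frequencies are commonly estimated worse.
#' @param notch zero the streak-frequency support of the PSD (assumes the
#'   streak stage removed those frequencies); `FALSE` gives the flat white
#'   PSD used when no streak removal precedes this stage.
#' @param notch_scales number of streak-stage displacement scales defining
#'   the notch support (`NULL`: [default_n_scales()] of the input).
#' @param profile [filter_profile()].
#' @export
poisson_config <- function(k_poi = 1L, vst_degree = 2L, recomb_sigma = 1.2,
                           notch = TRUE, notch_scales = NULL,
                           profile = filter_profile()) {
  list(k_poi = as.integer(k_poi), vst_degree = as.integer(vst_degree),
       recomb_sigma = recomb_sigma, notch = isTRUE(notch),
       notch_scales = notch_scales, profile = profile)
}

#' 2-D Gaussian smoothing with replicate padding.
#' @noRd
gauss_smooth2d <- function(img, sigma) {
  g <- gauss1d(sigma); g <- g / sum(g)
  r <- (length(g) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)
  pad <- img[ri, ci, drop = FALSE]
  out <- matrix(0, nr + 2 * r, nc)
  for (j in seq_along(g)) out <- out + g[j] * pad[, (j):(j + nc - 1L)]
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(g)) out2 <- out2 + g[i] * out[(i):(i + nr - 1L), ]
  out2
}

#' Smoothed log-field model for the Poisson stage
#'
#' `I_L = ln(I_B - I_D)` carries the bright-field-induced variance scaling;
#' a median filter removes extreme outliers (broken pixels) and a Gaussian
#' blur ensures smoothness, so that no spurious field structure is
#' reintroduced when the field correction is undone after denoising.
#'
#' @param I_B,I_D 2-D calibration fields.
#' @param med_window median filter window (default 5).
#' @param gauss_sigma Gaussian sd in pixels (default 3).
#' @return object of class `"field_model"`: list with `I_L` (raw log-field)
#'   and `I_L_smooth`.
#' @export
build_field <- function(I_B, I_D, med_window = 5L, gauss_sigma = 3) {
  diff <- I_B - I_D
  if (all(diff <= 0)) stop("bright-field minus dark-field is nowhere positive")
  pos <- diff[diff > 0]
  diff <- pmax(diff, max(stats::quantile(pos, 1e-5, names = FALSE),
                         1e-6 * stats::median(I_B)))
  I_L <- log(diff)
  I_L_smooth <- gauss_smooth2d(medfilt2(I_L, med_window), gauss_sigma)
  structure(list(I_L = I_L, I_L_smooth = I_L_smooth,
                 med_window = med_window, gauss_sigma = gauss_sigma),
            class = "field_model")
}

#' Field model for synthetic data with no bright-fielding (I_B = 1, I_D = 0)
#' @param shape_hv displacement extents `(m1, m2)`.
#' @export
null_field <- function(shape_hv) {
  z <- matrix(0, shape_hv[1], shape_hv[2])
  structure(list(I_L = z, I_L_smooth = z, med_window = 0L, gauss_sigma = 0),
            class = "field_model")
}

#' Undo bright-field-induced variance scaling
#'
#' `S = Yhat + I_L_smooth` (broadcast over angle): adding back the log-field
#' makes `S` the log-scale version of a homogeneous Poisson process, so a
#' single variance function `F(E[S])` applies to every pixel.
#'
#' @param Yhat log-domain stack (streak-free estimate or raw stack).
#' @param field [build_field()] result.
#' @param undo subtract instead of add (the inverse operation).
#' @return stack of the same shape.
#' @export
field_correct <- function(Yhat, field, undo = FALSE) {
  if (!all(dim(Yhat)[2:3] == dim(field$I_L_smooth))) {
    stop("field shape does not match stack displacement dimensions")
  }
  sweep(Yhat, 2:3, field$I_L_smooth, if (undo) `-` else `+`)
}

#' Fit a data-driven variance-stabilizing transform
#'
#' Estimates local (mean, variance) pairs from small blocks — the variance
#' from second differences along the angle (which annihilate smooth trends),
#' robustly — and fits `var(S) = F(E[S])` by iteratively reweighted
#' polynomial regression. The stabilizer is
#' `f(s) = integral from s0 to s of F(t)^(-1/2) dt` (numerical quadrature on
#' a fine grid) and the exact-unbiased inverse is tabulated as
#' `m -> E[f(m + sqrt(F(m)) xi)]` over the fit range with a Gaussian
#' surrogate, `xi` taken as stratified normal quantiles (a deterministic
#' Monte-Carlo table), then inverted by monotone interpolation.
#'
#' @param S 3-D array of field-corrected log-domain data.
#' @param degree polynomial degree of `F` (default 2).
#' @param block block side length for the local estimates (default 5).
#' @param n_grid quadrature / table grid size.
#' @param n_draws surrogate draws per table point.
#' @return object of class `"vst_model"` with functions `F_fun`, `f_fun`,
#'   `finv_fun` (exact-unbiased inverse), the polynomial `coef` and fit
#'   `range`.
#' @export
fit_vst <- function(S, degree = 2L, block = 5L, n_grid = 1000L, n_draws = 2000L) {
  d <- dim(S)
  if (d[1] < 3) stop("need at least 3 angles for the variance pseudo-residuals")
  # second differences along the angle: kill smooth trends, keep noise
  r <- (S[-c(1, d[1]), , , drop = FALSE] -
          0.5 * S[-c(d[1] - 1, d[1]), , , drop = FALSE] -
          0.5 * S[-c(1, 2), , , drop = FALSE]) / sqrt(1.5)
  Sm <- S[-c(1, d[1]), , , drop = FALSE]
  # block partition
  dd <- dim(r)
  bi <- lapply(1:3, function(a) ((seq_len(dd[a]) - 1L) %/% block))
  blk <- bi[[1]][slice.index(r, 1)] +
    (max(bi[[1]]) + 1L) * (bi[[2]][slice.index(r, 2)] +
                             (max(bi[[2]]) + 1L) * bi[[3]][slice.index(r, 3)])
  ms <- as.numeric(tapply(as.vector(Sm), blk, mean))
  vs <- as.numeric(tapply(as.vector(r), blk, function(x) stats::median(x^2) / 0.4549364))
  ns <- as.numeric(tapply(as.vector(r), blk, length))
  keep <- ns >= max(8, block^3 / 4)
  ms <- ms[keep]; vs <- vs[keep]; ws <- ns[keep]
  if (length(ms) < 10 * (degree + 1)) stop("too few blocks to fit the variance model")
  # degenerate intensity range (signal variation below the noise scale):
  # a polynomial slope is unidentifiable, fall back to constant variance
  if (diff(range(ms)) < 0.5 * sqrt(stats::median(vs))) {
    degree <- 0L
  }
  fit_once <- function(m, v, w) {
    X <- outer(m, 0:degree, `^`)
    stats::lm.fit(X * sqrt(w), v * sqrt(w))$coefficients
  }
  cf <- fit_once(ms, vs, ws)
  for (it in 1:2) {  # robust refit: trim gross outlier blocks (edges, defects)
    pred <- drop(outer(ms, 0:degree, `^`) %*% cf)
    res <- vs - pred
    s <- 1.4826 * stats::median(abs(res - stats::median(res)))
    ok <- abs(res) <= 3 * s + .Machine$double.eps
    if (sum(ok) < 10 * (degree + 1)) break
    cf <- fit_once(ms[ok], vs[ok], ws[ok])
  }
  rng <- stats::quantile(S, c(0.001, 0.999), names = FALSE)
  if (diff(rng) <= 0) rng <- range(S) + c(-0.5, 0.5)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  eps <- max(1e-12, 1e-6 * stats::median(vs))
  F_eval <- function(s) pmax(drop(outer(s, 0:degree, `^`) %*% cf), eps)
  Fg <- F_eval(grid)
  if (mean(drop(outer(grid, 0:degree, `^`) %*% cf) <= 0) > 0.5) {
    stop("fitted variance polynomial is nonpositive over most of the range; reduce degree")
  }
  # quadrature for f = int F^(-1/2)
  integrand <- Fg^(-0.5)
  h <- diff(grid)
  fg <- c(0, cumsum(0.5 * (integrand[-1] + integrand[-n_grid]) * h))
  f_fun_raw <- stats::approxfun(grid, fg, rule = 2)
  f_fun <- function(s) f_fun_raw(pmin(pmax(s, rng[1]), rng[2]))
  # exact-unbiased inverse table on a coarser grid
  mgrid <- seq(rng[1], rng[2], length.out = 400L)
  xi <- stats::qnorm((seq_len(n_draws) - 0.5) / n_draws)
  Ef <- vapply(mgrid, function(m) {
    mean(f_fun(m + sqrt(F_eval(m)) * xi))
  }, numeric(1))
  o <- order(Ef)
  finv_raw <- stats::approxfun(Ef[o], mgrid[o], rule = 2)
  finv_alg <- stats::approxfun(fg, grid, rule = 2)  # algebraic inverse of f
  structure(list(coef = cf, F_fun = F_eval, f_fun = f_fun,
                 finv_fun = finv_raw, finv_alg = finv_alg, range = rng,
                 degree = degree, n_blocks = length(ms)),
            class = "vst_model")
}

#' Apply the forward stabilizer of a VST model elementwise
#' @param vst `"vst_model"`; @param S array.
#' @export
vst_forward <- function(vst, S) {
  out <- vst$f_fun(as.vector(S)); dim(out) <- dim(S); out
}

#' Apply the exact-unbiased inverse of a VST model elementwise
#' @param vst `"vst_model"`; @param D array of stabilized-domain values.
#' @export
vst_inverse <- function(vst, D) {
  out <- vst$finv_fun(as.vector(D)); dim(out) <- dim(D); out
}

#' Multiscale denoising of the stabilized Poisson component (stage 2 core)
#'
#' Stabilizes `S = Yhat + field`, builds `k_poi` 3-D binned scales, denoises
#' each scale independently (per-segment flat PSD with the streak-frequency
#' notch, strength `c` estimated by a MAD probe through the 3-D db3 high-pass
#' tensor), recombines coarse to fine keeping only Gaussian-low-passed
#' content of the coarser estimates, and finally applies the exact-unbiased
#' inverse VST and removes the field.
#'
#' @param Yhat streak-free log-domain stack (or raw stack for
#'   [poisson_only_mode()]).
#' @param field [build_field()] / [null_field()] result.
#' @param cfg [poisson_config()].
#' @param vst optional pre-fitted `"vst_model"` (fitted from `S` otherwise).
#' @return estimate `Dhat` of the underlying log-projections, with
#'   attribute `"c_hat"`: per-scale list of estimated noise variances.
#' @export
multiscale_poisson_denoise <- function(Yhat, field, cfg = poisson_config(),
                                       vst = NULL) {
  S <- field_correct(Yhat, field)
  if (is.null(vst)) vst <- fit_vst(S, cfg$vst_degree)
  fs <- vst_forward(vst, S)

  K <- cfg$k_poi
  vols <- vector("list", K + 1)
  vols[[1]] <- fs
  for (k in seq_len(K)) vols[[k + 1]] <- bin3d(vols[[k]])

  notch_scales <- if (is.null(cfg$notch_scales)) default_n_scales(dim(Yhat)) else cfg$notch_scales
  psi <- db3_highpass()
  c_log <- vector("list", K + 1)
  est <- vector("list", K + 1)
  for (k in 0:K) {
    vol <- vols[[k + 1]]
    seg_size <- pmax(cfg$profile$cube, ceiling(2 * dim(vol)[2:3] / 3))
    cs <- list()
    est[[k + 1]] <- segment_denoise(vol, function(seg) {
      sigma <- mad_std(seg, list(psi, psi, psi))
      cs[[length(cs) + 1L]] <<- sigma^2
      mask <- if (cfg$notch) streak_support_mask(dim(seg), notch_scales) else NULL
      psd <- poisson_stage_psd(dim(seg), sigma^2, mask)
      denoise_volume(seg, psd, cfg$profile)
    }, seg_size = seg_size, overlap = 0.5)
    c_log[[k + 1]] <- cs
  }

  comb <- est[[K + 1]]
  for (k in rev(seq_len(K) - 1L)) {  # k = K-1 .. 0
    fine <- est[[k + 1]]
    lowp_fine <- gauss_smooth3d(debin3d(bin3d(fine), dim(fine)), cfg$recomb_sigma)
    lowp_coarse <- gauss_smooth3d(debin3d(comb, dim(fine)), cfg$recomb_sigma)
    comb <- fine - lowp_fine + lowp_coarse
  }

  out <- field_correct(vst_inverse(vst, comb), field, undo = TRUE)
  attr(out, "c_hat") <- c_log
  attr(out, "vst") <- vst
  out
}

#' Poisson denoising without preceding streak removal
#'
#' Identical to [multiscale_poisson_denoise()] but with an un-notched flat
#' PSD: prior to streak attenuation the Poisson noise is approximately white
#' at all frequencies.
#'
#' @param Z log-domain stack.
#' @param field field model.
#' @param cfg [poisson_config()] (its `notch` flag is overridden).
#' @export
poisson_only_mode <- function(Z, field, cfg = poisson_config()) {
  cfg$notch <- FALSE
  multiscale_poisson_denoise(Z, field, cfg)
}
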