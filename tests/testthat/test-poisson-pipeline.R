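test_that("build_field smooths and survives dead pixels", {
  IB <- matrix(1000, 40, 30)
  ID <- matrix(50, 40, 30)
  f <- build_field(IB, ID)
  expect_equal(f$I_L_smooth, matrix(log(950), 40, 30), tolerance = 1e-9)
  # dead pixel: clamped, removed by the median filter
  IB2 <- IB; IB2[20, 15] <- 0
  f2 <- build_field(IB2, ID)
  expect_lt(abs(f2$I_L_smooth[20, 15] - log(950)) / log(950), 0.05)
  # smooth vignetting: smoothed field close to the raw log-field
  vig <- 1000 * outer(dnorm(seq(-1, 1, length.out = 40), 0, 2),
                      dnorm(seq(-1, 1, length.out = 30), 0, 2)) * 15
  f3 <- build_field(vig, ID * 0)
  # deviation limited to the Gaussian-blur tolerance of this curvature
  expect_lt(max(abs(f3$I_L_smooth - f3$I_L)), 0.2 * diff(range(f3$I_L)))
  # and the median filter contributes nothing on a smooth field: the
  # smoothed field is itself smooth (bounded local variation)
  expect_lt(max(abs(diff(f3$I_L_smooth))), max(abs(diff(f3$I_L))) * 1.5)
  expect_error(build_field(ID * 0, ID), "positive")
})

test_that("field_correct round-trips and collapses two-field variance curves", {
  set.seed(1)
  Y <- array(rnorm(6 * 10 * 8), c(6, 10, 8))
  fld <- build_field(matrix(exp(2), 10, 8), matrix(0, 10, 8), gauss_sigma = 0.1)
  S <- field_correct(Y, fld)
  expect_equal(field_correct(S, fld, undo = TRUE), Y, tolerance = 1e-12)
  zero <- null_field(c(10, 8))
  expect_equal(field_correct(Y, zero), Y)
  # Poisson counts divided by two different bright-fields: after correction
  # the variance-vs-mean relation collapses to one curve
  lam <- 2000
  draws <- function(bf) {
    counts <- matrix(rpois(40 * 2000, lam), 2000, 40)
    log(counts / bf)  # normalized then logged
  }
  s_hi <- draws(4) + log(4)   # field_correct adds back ln(bright-field)
  s_lo <- draws(1) + log(1)
  expect_equal(var(as.vector(s_hi)), var(as.vector(s_lo)), tolerance = 0.1)
})

test_that("fit_vst stabilizes log-Poisson data and is consistent", {
  set.seed(2)
  # constant-variance Gaussian input: F constant, f affine with slope c^(-1/2)
  cst <- array(5 + rnorm(32 * 24 * 20, 0, 0.3), c(32, 24, 20))
  v <- fit_vst(cst, degree = 2)
  mid <- seq(quantile(cst, 0.2), quantile(cst, 0.8), length.out = 9)
  expect_equal(v$F_fun(mid), rep(0.09, 9), tolerance = 0.25)
  slopes <- diff(v$f_fun(mid)) / diff(mid)
  expect_equal(slopes, rep(1 / 0.3, 8), tolerance = 0.25)
  # log-Poisson: fitted F decreasing in S (variance ~ 1/mean asymptotically)
  lam <- aperm(array(seq(600, 3000, length.out = 48 * 32), c(48, 32, 40)), c(3, 1, 2))
  S <- log(pmax(rpois(length(lam), lam), 0.5)); dim(S) <- dim(lam)
  vp <- fit_vst(S, degree = 2)
  xs <- seq(vp$range[1], vp$range[2], length.out = 20)
  expect_lt(vp$F_fun(xs[18]), vp$F_fun(xs[3]))
  # algebraic inverse consistency within 0.1% over the fit range
  err <- max(abs(vp$finv_alg(vp$f_fun(xs)) - xs))
  expect_lt(err, 1e-3 * max(abs(vp$range)))
  # exact-unbiased inverse agrees to first order
  expect_lt(max(abs(vst_inverse(vp, vp$f_fun(xs[3:18])) - xs[3:18])), 0.05)
})

test_that("stabilized binned data are near-normal at moderate peaks", {
  set.seed(3)
  lam <- array(800, c(32, 24, 24))
  S <- log(pmax(rpois(length(lam), lam), 0.5)); dim(S) <- dim(lam)
  v <- fit_vst(S, degree = 2)
  fs <- bin3d(vst_forward(v, S))
  x <- as.vector(fs) - mean(fs)
  skew <- mean(x^3) / sd(x)^3
  expect_lt(abs(skew), 0.2)
})

test_that("multiscale Poisson denoising improves fixtures and respects K_poi = 0", {
  fx <- default_fixture(seed = 17, streak_std = 0, peak = 2560)
  fld <- null_field(dim(fx$Z)[2:3])
  out <- multiscale_poisson_denoise(fx$Z, fld, poisson_config(notch = FALSE))
  expect_gt(snr(fx$lnA, out), snr(fx$lnA, fx$Z) + 3)
  out0 <- multiscale_poisson_denoise(fx$Z, fld,
                                     poisson_config(k_poi = 0, notch = FALSE))
  expect_gt(snr(fx$lnA, out0), snr(fx$lnA, fx$Z))
})

test_that("poisson_only_mode: strong white-noise reduction, near-identity when clean", {
  set.seed(4)
  sh <- c(32, 48, 32)
  sig <- make_smooth_signal(sh, 2) + 5
  z <- sig + array(rnorm(prod(sh), 0, 0.3), sh)
  out <- poisson_only_mode(z, null_field(sh[2:3]), poisson_config(k_poi = 0))
  expect_lt(mean((out - sig)^2), 0.2 * mean((z - sig)^2))  # >= 80% MSE removed
  # near-clean volume: output close to input
  z2 <- sig + array(rnorm(prod(sh), 0, 1e-3), sh)
  out2 <- poisson_only_mode(z2, null_field(sh[2:3]), poisson_config(k_poi = 0))
  expect_lt(sd(out2 - z2) / sd(z2), 0.05)
})
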