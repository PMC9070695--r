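test_that("segment windows form a partition of unity", {
  for (n in c(40, 96, 256, 300)) {
    segs <- streakless:::segment_axis(n, 96, 0.5)
    tot <- numeric(n)
    for (s in segs) tot[s$idx] <- tot[s$idx] + s$win
    expect_equal(tot, rep(1, n), tolerance = 1e-12)
  }
})

test_that("segment_denoise: single segment equals the direct call, constants pass", {
  set.seed(1)
  vol <- array(rnorm(8 * 20 * 16), c(8, 20, 16))
  f <- function(seg) seg * 2
  expect_equal(segment_denoise(vol, f, seg_size = c(64, 64)), vol * 2,
               tolerance = 1e-12)
  # overlapping segments of a constant volume recombine to the constant
  cv <- array(3, c(8, 40, 40))
  expect_equal(segment_denoise(cv, identity, seg_size = c(24, 24)), cv,
               tolerance = 1e-12)
})

test_that("extreme streak detector: specificity and sensitivity", {
  # white noise: false-flag rate below 0.1%
  set.seed(2)
  zn <- array(rnorm(64 * 96 * 64, 0, 0.02), c(64, 96, 64))
  expect_lt(attr(attenuate_extreme_streaks(zn), "n_flagged"), 0.001 * 96 * 64)
  # smooth signal gradient only: zero flags
  grad <- aperm(array(outer(seq(0, 1, length.out = 96),
                            seq(0, 0.5, length.out = 64), `+`),
                      c(96, 64, 16)), c(3, 1, 2))
  out <- attenuate_extreme_streaks(grad)
  expect_equal(attr(out, "n_flagged"), 0L)
  expect_equal(out, grad, ignore_attr = TRUE)
  # planted 10-sigma column is flagged and removed
  set.seed(3)
  z <- grad[rep(1, 48), , ] + array(rnorm(48 * 96 * 64, 0, 0.02), c(48, 96, 64))
  z[, 40, 30] <- z[, 40, 30] + 10 * 0.02
  fixed <- attenuate_extreme_streaks(z)
  expect_gte(attr(fixed, "n_flagged"), 1)
  expect_lt(abs(mean(fixed[, 40, 30] - grad[1, 40, 30])), 3 * 0.02 / sqrt(48) * 5)
})

test_that("identity telescoping: identity denoiser reproduces the input exactly", {
  fx <- default_fixture(seed = 17, streak_std = 0.02, peak = Inf)
  idn <- multiscale_streak_denoise(fx$Z, streak_config(),
                                   denoiser = function(s, k, r) s)
  expect_equal(idn, fx$Z, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("only the angularly-binned subspace is modified", {
  fx <- default_fixture(seed = 17, streak_std = 0.02, peak = Inf)
  cfg <- streak_config()
  yh <- multiscale_streak_denoise(fx$Z, cfg)
  hf_in <- fx$Z - debin_angular(bin_angular(fx$Z, cfg$m_alpha), dim(fx$Z)[1])
  hf_out <- yh - debin_angular(bin_angular(unclass(yh), cfg$m_alpha), dim(yh)[1])
  expect_equal(hf_out, hf_in, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("multiscale streak denoising earns a large SNR gain", {
  gains <- sapply(c(17, 5, 23), function(seed) {
    fx <- default_fixture(seed = seed, streak_std = 0.02, peak = Inf)
    yh <- multiscale_streak_denoise(fx$Z, streak_config())
    snr(fx$Y, yh) - snr(fx$Y, fx$Z)
  })
  expect_true(all(gains >= 8))
})

test_that("noise-free input passes nearly unchanged", {
  fx <- default_fixture(seed = 5, streak_std = 0, peak = Inf)
  yh <- multiscale_streak_denoise(fx$Z, streak_config())
  expect_lt(sd(yh - fx$Z) / sd(fx$Z), 0.01)
})

test_that("segmentwise PSDs adapt to spatially varying strength", {
  set.seed(6)
  sh <- c(24, 192, 48)
  sig <- make_smooth_signal(sh, 1)
  noise <- make_streak_noise(sh, 0.05, 0, 0)
  noise[, 97:192, ] <- 2 * noise[, 97:192, ]
  z <- sig + noise
  cfg <- streak_config(n_scales = 1, seg_size = c(96, 96))
  den <- function(seg, k, r) {
    set <- make_streak_kernels(k, dim(seg))
    p <- estimate_segment_params(seg, set, residual = r)
    denoise_volume(seg, compose_scale_psd(p, set, residual = r), cfg$profile)
  }
  yh <- multiscale_streak_denoise(z, cfg, denoiser = den)
  err <- yh - sig
  e1 <- mean(err[, 1:96, ]^2)
  e2 <- mean(err[, 97:192, ]^2)
  # residual energies of the two halves within 4x of each other (the right
  # half holds 4x the injected energy)
  expect_lt(e2 / e1, 4)
})
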