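test_that("subband variances: flat, zero and structured PSDs", {
  prof <- filter_profile()
  sh <- c(16, 16, 16)
  flat <- array(2.5 * prod(sh), sh)   # white noise, variance 2.5
  v <- subband_variances(flat, prof)
  expect_equal(as.vector(v), rep(2.5, prof$cube^3), tolerance = 1e-10)
  expect_true(all(subband_variances(array(0, sh), prof) == 0))
  # angular-DC plane PSD: variance concentrated in angularly-DC subbands,
  # validated against Monte-Carlo cube statistics
  psd <- compose_scale_psd(streak_params(0.5, 0, 0), make_streak_kernels(0, sh))
  v <- subband_variances(psd, prof)
  expect_gt(sum(v[1, , ]), 0.99 * sum(v))  # concentration in angular-DC subbands
  # Parseval: mean subband variance equals the per-pixel noise variance
  expect_equal(mean(v), mean(psd) / prod(sh), tolerance = 1e-10)
  # Monte-Carlo oracle for the full-DC coefficient: value = sum(cube) / L^(3/2)
  set.seed(1)
  L <- prof$cube
  dc <- replicate(600, sum(draw_correlated_noise(psd)[1:L, 1:L, 1:L]) / L^1.5)
  expect_equal(var(dc), v[1, 1, 1], tolerance = 0.2)
})

test_that("zero-noise identity and linearity under scaling", {
  set.seed(2)
  z <- array(rnorm(14 * 18 * 12), c(14, 18, 12))
  expect_equal(denoise_volume(z, array(0, dim(z))), z, tolerance = 1e-12)
  psd <- array(0.5 * prod(dim(z)), dim(z))
  a <- 3
  d1 <- denoise_volume(a * z, a^2 * psd)
  d2 <- a * denoise_volume(z, psd)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("aggregation covers every voxel with finite output", {
  set.seed(3)
  z <- array(rnorm(11 * 13 * 17), c(11, 13, 17))  # awkward extents
  out <- denoise_volume(z, array(prod(dim(z)), dim(z)))
  expect_all_finite(out)
  expect_equal(dim(out), dim(z))
  expect_error(denoise_volume(z[, , 1:2, drop = FALSE], array(0, c(11, 13, 2))),
               "smaller")
})

test_that("white-noise regression: output MSE below input MSE", {
  prof <- filter_profile()
  for (seed in 1:10) {
    set.seed(seed)
    sh <- c(24, 32, 24)
    sig <- make_smooth_signal(sh, amplitude = 2)
    noise <- array(rnorm(prod(sh), 0, 0.5), sh)
    z <- sig + noise
    psd <- poisson_stage_psd(sh, 0.25)
    out <- denoise_volume(z, psd, prof)
    expect_lt(mean((out - sig)^2), mean((z - sig)^2))
  }
})

test_that("pure white noise is strongly attenuated", {
  set.seed(11)
  sh <- c(32, 32, 32)
  z <- array(rnorm(prod(sh)), sh)
  out <- denoise_volume(z, poisson_stage_psd(sh, 1))
  expect_lt(var(as.vector(out)), 0.05)  # >= 95% of noise energy removed
})

test_that("block matching: ties, planted patterns, whitening", {
  prof <- filter_profile(search_rad = 3L)
  # constant volume: reference first, raster-order ties, zero distances
  z <- array(1, c(12, 12, 12))
  g <- block_match(c(5, 5, 5), z, prof)
  expect_equal(unname(g[1, ]), c(5, 5, 5))
  expect_equal(nrow(g), prof$max_group)  # 7^3 = 343 candidates -> full group
  # two identical textured regions are matched across displacement
  set.seed(4)
  z <- array(rnorm(12 * 16 * 12, 0, 0.01), c(12, 16, 12))
  patt <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  z[5:8, 3:6, 5:8] <- patt
  z[5:8, 9:12, 5:8] <- patt
  g <- block_match(c(5, 3, 5), z, filter_profile(search_rad = c(3, 8, 3)))
  expect_true(any(g[, 2] == 9 & g[, 1] == 5 & g[, 3] == 5))
  # pure streak noise with whitening: matches not exclusively angular
  set.seed(5)
  zs <- make_streak_noise(c(24, 24, 24), 1, 0, 0)
  psd <- compose_scale_psd(streak_params(1, 0, 0), make_streak_kernels(0, dim(zs)))
  g <- block_match(c(9, 9, 9), zs, filter_profile(), psd)
  angular_only <- mean(g[, 2] == 9 & g[, 3] == 9)
  expect_lt(angular_only, 0.7)
})

test_that("matched streak PSD yields a large SNR gain on a synthetic fixture", {
  set.seed(6)
  sh <- c(24, 48, 32)
  sig <- make_smooth_signal(sh, amplitude = 1)
  noise <- 0.1 * make_streak_noise(sh, 1, 0, 0)
  z <- sig + noise
  psd <- compose_scale_psd(streak_params(0.1, 0, 0), make_streak_kernels(0, sh))
  out <- denoise_volume(z, psd)
  gain <- 10 * log10(mean((z - sig)^2) / mean((out - sig)^2))
  expect_gt(gain, 5)
})
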