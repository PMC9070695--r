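test_that("mad_std estimates the filtered-noise sd robustly", {
  set.seed(1)
  z <- array(rnorm(100 * 100 * 100), c(100, 100, 100))
  expect_equal(mad_std(z, array(1, c(1, 1, 1))), 1, tolerance = 0.01)
  expect_equal(mad_std(array(5, c(8, 8, 8)), array(1, c(1, 1, 1))), 0)
  # scale equivariance
  s1 <- mad_std(z[1:32, 1:32, 1:32], list(db3_highpass_taps(), NULL, NULL))
  s2 <- mad_std(3 * z[1:32, 1:32, 1:32], list(db3_highpass_taps(), NULL, NULL))
  expect_equal(s2, 3 * s1, tolerance = 1e-12)
  expect_error(mad_std(array(0, c(4, 4, 4)), array(1, c(9, 1, 1))), "smaller")
})

test_that("scale_from_std divides by the convolved norm", {
  sh <- c(16, 16, 16)
  g_s <- array(1, c(1, 1, 1))     # impulse component
  g_d <- array(2, c(1, 1, 1))     # scaled impulse probe: norm 2
  expect_equal(scale_from_std(2, g_s, g_d, sh), 1)
  # synthetic: varsigma * g_s (x) nu with matched probe
  set.seed(2)
  sh <- c(24, 48, 48)
  est <- replicate(10, {
    z <- 0.02 * make_streak_noise(sh, 1, 0, 0)
    bank <- build_probe_bank(sh)
    sig <- mad_std(z, bank$g_w)
    scale_from_std(sig, make_streak_kernels(0, sh)$g_w, bank$g_w, sh)
  })
  expect_gt(median(est), 0.018)
  expect_lt(median(est), 0.022)
  # orthogonal probe/component -> error: a full-extent constant probe only
  # passes the DC, which the two-tap difference kernel has none of
  expect_error(scale_from_std(1, array(c(1, -1), c(2, 1, 1)),
                              list(rep(1 / 4, 16), NULL, NULL), c(16, 8, 8)),
               "orthogonal")
})

test_that("probe bank has the stated structure", {
  bank <- build_probe_bank(c(32, 96, 64))
  expect_length(db3_highpass_taps(), 6)   # db3 high-pass: exactly 6 taps
  expect_equal(sum(db3_highpass_taps()), 0, tolerance = 1e-12)
  expect_equal(sum(db3_highpass_taps()^2), 1, tolerance = 1e-12)
  # each probe factor has unit Euclidean norm
  for (q in 1:4) {
    for (f in bank[[q]]) expect_equal(sum(f^2), 1, tolerance = 1e-12)
  }
  # response to a constant volume is zero (high-pass factor kills DC)
  const <- array(7, c(32, 96, 64))
  for (q in 1:4) expect_lt(mad_std(const, bank[[q]]), 1e-10)
  expect_error(build_probe_bank(c(4, 96, 64)), "degenerate")
})

test_that("probes separate the streak components", {
  set.seed(3)
  sh <- c(32, 96, 64)
  bank <- build_probe_bank(sh)
  z_w <- make_streak_noise(sh, 1, 0, 0)
  z_u <- make_streak_noise(sh, 0, 1, 0)
  r_ww <- mad_std(z_w, bank$g_w)
  r_wu <- mad_std(z_u, bank$g_w)
  expect_gt(r_ww / max(r_wu, 1e-12), sqrt(10))  # variance ratio > 10
})

test_that("unmix_components attributes leakage correctly", {
  sh <- c(32, 96, 64)
  set <- make_streak_kernels(0, sh)
  bank <- build_probe_bank(sh)
  M <- probe_response_matrix(set, bank, sh)
  # zero responses -> zero strengths
  p0 <- unmix_components(rep(0, 4), M = M)
  expect_equal(unlist(p0[1:3]), c(varsigma_w = 0, varsigma_u = 0, varsigma_v = 0))
  # pure white streaks: sigma_u, sigma_v responses are pure leakage
  set.seed(4)
  ests <- t(replicate(5, {
    z <- make_streak_noise(sh, 0.02, 0, 0)
    p <- estimate_segment_params(z, set)
    c(p$varsigma_w, p$varsigma_u, p$varsigma_v)
  }))
  expect_equal(median(ests[, 1]), 0.02, tolerance = 0.1)
  expect_lt(median(ests[, 2]), 0.004)
  expect_lt(median(ests[, 3]), 0.004)
  # nonnegativity invariant under random inputs
  set.seed(5)
  for (i in 1:20) {
    p <- unmix_components(runif(4, 0, 0.1), M = M)
    expect_true(all(unlist(p) >= 0))
  }
})

test_that("estimate_segment_params adapts to nonstationary strength", {
  set.seed(6)
  sh <- c(24, 96, 48)
  set <- make_streak_kernels(0, sh)
  # homogeneous noise: two disjoint segments agree within sampling error
  z <- make_streak_noise(c(sh[1], 2 * sh[2], sh[3]), 0.02, 0, 0)
  p1 <- estimate_segment_params(z[, 1:96, , drop = FALSE], set)
  p2 <- estimate_segment_params(z[, 97:192, , drop = FALSE], set)
  expect_equal(p1$varsigma_w, p2$varsigma_w, tolerance = 0.25)
  # 2x strength in one half -> per-segment ratio approximately 2
  zl <- make_streak_noise(sh, 0.02, 0, 0)
  zr <- make_streak_noise(sh, 0.04, 0, 0)
  pl <- estimate_segment_params(zl, set)
  pr <- estimate_segment_params(zr, set)
  expect_equal(pr$varsigma_w / pl$varsigma_w, 2, tolerance = 0.3)
  # zero-noise segment -> zero parameters
  pz <- estimate_segment_params(array(0, sh), set)
  expect_equal(unlist(pz[1:3]),
               c(varsigma_w = 0, varsigma_u = 0, varsigma_v = 0))
})

test_that("estimates are robust to a smooth strong signal", {
  set.seed(7)
  sh <- c(32, 96, 64)
  set <- make_streak_kernels(0, sh)
  noise <- make_streak_noise(sh, 0.02, 0, 0)
  blob <- make_smooth_signal(sh, amplitude = 10 * 0.02)
  p_plain <- estimate_segment_params(noise, set)
  p_blob <- estimate_segment_params(noise + blob, set)
  expect_lt(abs(p_blob$varsigma_w - p_plain$varsigma_w) / p_plain$varsigma_w, 0.15)
})

test_that("estimator consistency improves with segment size", {
  set.seed(8)
  err_for <- function(m1) {
    median(replicate(6, {
      sh <- c(24, m1, 48)
      z <- make_streak_noise(sh, 0.02, 0, 0)
      abs(estimate_segment_params(z, make_streak_kernels(0, sh))$varsigma_w - 0.02)
    }))
  }
  e_small <- err_for(32)
  e_large <- err_for(128)
  expect_lt(e_large, e_small + 0.002)
  expect_lt(e_large / 0.02, 0.1)
})
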