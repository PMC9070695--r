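sym_psd <- function(p) {
  # a PSD of real noise must satisfy Psi(f) = Psi(-f)
  idx <- lapply(dim(p), function(n) c(1, n:2))
  (p + do.call(`[`, c(list(p), idx))) / 2
}

test_that("psd_from_kernel: white, streak, and general kernels", {
  # unit impulse -> flat PSD with mean/|X| = 1
  p <- psd_from_kernel(array(1, c(1, 1, 1)), c(8, 8, 8))
  expect_true(all(abs(p - 512) < 1e-9))
  # angularly constant kernel -> PSD supported only on the angular-DC plane
  g0w <- make_streak_kernels(0, c(8, 8, 8))$g_w
  pw <- psd_from_kernel(g0w, c(8, 8, 8))
  expect_true(all(pw[2:8, , ] < 1e-9 * max(pw)))
  expect_true(all(pw[1, , ] > 0))
  # arbitrary kernel: mean(psd)/|X| equals sum(g^2) (Monte-Carlo oracle)
  set.seed(1)
  g <- array(rnorm(3 * 3 * 3), c(3, 3, 3)) / 5
  ps <- psd_from_kernel(g, c(16, 16, 16))
  expect_equal(mean(ps) / prod(dim(ps)), sum(g^2), tolerance = 1e-10)
  vmc <- mean(replicate(50, var(as.vector(draw_correlated_noise(ps)))))
  expect_equal(vmc, sum(g^2), tolerance = 0.05)
  expect_error(psd_from_kernel(array(1, c(20, 1, 1)), c(8, 8, 8)), "larger")
})

test_that("kernel_from_psd round-trips and reproduces structure", {
  set.seed(2)
  psd <- sym_psd(array(abs(rnorm(8 * 6 * 4))^2, c(8, 6, 4)))
  g <- kernel_from_psd(psd)
  expect_equal(psd_from_kernel(g, dim(psd)), psd, tolerance = 1e-10)
  # flat PSD -> impulse kernel
  flat <- array(prod(c(8, 6, 4)), c(8, 6, 4))
  k <- kernel_from_psd(flat)
  expect_equal(max(abs(k)), 1, tolerance = 1e-12)
  expect_equal(sum(abs(k) > 1e-9), 1L)
  # PSD of g_{0,u} -> kernel constant along angle and horizontal
  sh <- c(8, 6, 4)
  pu <- psd_from_kernel(make_streak_kernels(0, sh)$g_u, sh)
  ku <- kernel_from_psd(pu)
  expect_lt(max(abs(sweep(ku, 3, ku[1, 1, ]))), 1e-12)
  expect_error(kernel_from_psd(flat - 2 * max(flat)), "nonnegative")
})

test_that("streak component kernels follow the 2^k scale law exactly", {
  sh <- c(16, 24, 20)
  for (k in 0:2) {
    set <- make_streak_kernels(k, sh)
    for (g in list(set$g_w, set$g_u, set$g_v)) {
      expect_equal(kernel_norm(g), 2^k, tolerance = 1e-12)
    }
  }
  # realization of g_{0,w} (x) nu: constant along angle, unit variance across
  set.seed(3)
  p <- psd_from_kernel(make_streak_kernels(0, sh)$g_w, sh)
  r <- draw_correlated_noise(p)
  expect_lt(max(abs(sweep(r, 2:3, r[1, , ]))), 1e-10)  # angularly constant
  expect_equal(var(as.vector(r[1, , ])), 1, tolerance = 0.25)
})

test_that("binning residual kernel matches the Monte-Carlo residual", {
  sh2 <- c(16, 16)
  q <- binning_residual_kernel(sh2)
  qvar <- sum(q^2)
  # Monte-Carlo: residual of bin/debin on 2-D white noise
  set.seed(4)
  resvar <- mean(replicate(300, {
    eta <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
    r <- eta - debin2d(bin2d(eta), dim(eta))
    var(as.vector(r))
  }))
  expect_equal(qvar, resvar, tolerance = 0.02)
  # residual is orthogonal to the retained coarse part (on average)
  set.seed(5)
  ips <- replicate(300, {
    eta <- array(rnorm(1 * 16 * 16), c(1, 16, 16))
    low <- debin2d(bin2d(eta), dim(eta))
    sum((eta - low) * low)
  })
  expect_lt(abs(mean(ips)) / sd(ips), 0.2)
  # constants have zero residual
  const <- array(1, c(2, 8, 8))
  expect_lt(max(abs(const - debin2d(bin2d(const), dim(const)))), 1e-12)
})

test_that("compose_scale_psd: zeros, single component, variance bookkeeping", {
  sh <- c(16, 24, 20)
  set0 <- make_streak_kernels(0, sh)
  expect_true(all(compose_scale_psd(streak_params(0, 0, 0), set0) == 0))
  pw <- compose_scale_psd(streak_params(1, 0, 0), set0)
  expect_equal(pw, psd_from_kernel(set0$g_w, sh), tolerance = 1e-10)
  expect_error(compose_scale_psd(streak_params(-1, 0, 0), set0), "nonnegative")
  # mixed strengths at scale 1: mean(psd)/|X| equals total variance
  set1 <- make_streak_kernels(1, sh)
  pm <- compose_scale_psd(streak_params(0.3, 0.1, 0.2), set1)
  expect_true(all(pm[2:16, , ] == 0))  # angular-DC plane only
  expect_equal(mean(pm) / prod(sh), (0.3^2 + 0.1^2 + 0.2^2) * 4, tolerance = 1e-10)
  set.seed(6)
  vmc <- mean(replicate(200, var(as.vector(draw_correlated_noise(pm)))))
  expect_equal(vmc, (0.3^2 + 0.1^2 + 0.2^2) * 4, tolerance = 0.1)
  # residual composition: variance bookkeeping via Monte-Carlo
  pr <- compose_scale_psd(streak_params(0.5, 0.2, 0), set0, residual = TRUE)
  set.seed(7)
  vres <- mean(replicate(300, {
    eta <- make_streak_noise(sh, 0.5, 0.2, 0)
    var(as.vector(eta - debin2d(bin2d(eta), sh)))
  }))
  expect_equal(mean(pr) / prod(sh), vres, tolerance = 0.1)
})

test_that("poisson_stage_psd is flat with a streak notch", {
  sh <- c(12, 16, 16)
  expect_true(all(poisson_stage_psd(sh, 0) == 0))
  flat <- poisson_stage_psd(sh, 2)
  expect_true(all(flat == 2 * prod(sh)))
  mask <- streak_support_mask(sh, n_scales = 1)
  notched <- poisson_stage_psd(sh, 2, mask)
  expect_true(all(notched[mask] == 0))
  expect_true(all(notched[!mask] == 2 * prod(sh)))
  # zeroed fraction equals the mask area
  expect_equal(sum(notched == 0) / prod(sh), mean(mask))
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] == 1))  # angular-DC only
  expect_error(poisson_stage_psd(sh, -1), "nonnegative")
})
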