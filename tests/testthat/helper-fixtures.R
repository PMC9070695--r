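# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

# Angularly constant streak noise field with component strengths (sw, su, sv):
# white across displacement, constant across horizontal, constant across
# vertical, broadcast along the angle.
make_streak_noise <- function(shape, sw = 0, su = 0, sv = 0) {
  m0 <- shape[1]; m1 <- shape[2]; m2 <- shape[3]
  ehv <- sw * matrix(rnorm(m1 * m2), m1, m2) +
    su * matrix(rnorm(m2), m1, m2, byrow = TRUE) +
    sv * matrix(rnorm(m1), m1, m2)
  aperm(array(ehv, c(m1, m2, m0)), c(3, 1, 2))
}

# Small smooth phantom-like signal (separable bumps), same value repeated
# along the angle like a slowly varying sinogram.
make_smooth_signal <- function(shape, amplitude = 1) {
  g <- outer(exp(-((seq_len(shape[2]) - shape[2] / 2)^2) / (shape[2]^2 / 18)),
             exp(-((seq_len(shape[3]) - shape[3] / 2)^2) / (shape[3]^2 / 24)))
  aperm(array(amplitude * g, c(shape[2], shape[3], shape[1])), c(3, 1, 2))
}

# Cached default synthetic fixture (used by several files).
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function(seed = 17, streak_std = 0.02, peak = Inf) {
  key <- paste(seed, streak_std, peak, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_stack(
      synthetic_config(seed = seed, streak_std = streak_std, peak = peak))
  }
  .fixture_cache[[key]]
}

expect_all_finite <- function(x) {
  testthat::expect_true(all(is.finite(x)))
}
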