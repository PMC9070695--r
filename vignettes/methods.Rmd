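---
title: "Sinogram-domain streak and Poisson denoising: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sinogram-domain streak and Poisson denoising: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(streakless)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` do not themselves
compute.

## The noise model

Projections from a photon-counting detector, normalized by bright/dark
fields and log-transformed, carry two distinct corruptions:

* **streak noise** `eta`: normally distributed detector-response error,
  constant (or extremely slowly varying) along the acquisition angle. In a
  reconstructed tomogram it becomes a ring. It is *not* white: its
  correlation is long-range by construction.
* **Poissonian noise** `pi`: white counting noise whose log-domain variance
  is signal-dependent (asymptotically inversely proportional to the mean)
  and spatially modulated by the bright-fielding.

Both are treated as instances of one model: noisy volume
`z = y + g (*) nu` with `nu` unit white Gaussian and correlation kernel `g`,
equivalently PSD `Psi = |X| |F(g)|^2`. With this convention `mean(Psi)/|X|`
is the per-pixel noise variance, which every constructed PSD in the package
is tested against by Monte-Carlo (`draw_correlated_noise()`).

### The three streak components

Streaks may also be long-range correlated *across displacement* (along a
detector axis). The model therefore splits `eta` into angularly constant
components: white across both displacement dimensions (`w`), constant
across horizontal displacement (`u`), constant across vertical (`v`). Their
kernels are constant along the long axes with unit norm at scale 0 and norm
`2^k` at binning scale `k` — 2-D summation binning preserves both whiteness
and constancy and multiplies variance by 4 per scale, so the same three
shapes describe every scale with only scalar strengths
`(varsigma_w, varsigma_u, varsigma_v)` to estimate.

Below the coarsest pyramid scale, the coarse content of each volume has been
replaced by the (treated as exact) coarser estimate, so the remaining noise
is the *binning residual* of each component. Its PSD is composed in closed
form with `F(q) = sqrt(max(0, 1 - |F(h)|^2))`, `h` the equivalent 2x2
averaging low-pass of bin-then-debin (1-D along the varying axis for the
`u`/`v` components, whose constant axes are preserved exactly by binning).
The bin/debin pair is shift-variant, so this stationary description is an
approximation; the test suite checks its total-variance bookkeeping against
the Monte-Carlo residual within a few percent.

## Self-calibration

Strengths are estimated per scale and per overlapping segment (raised-cosine
windows rescaled to a partition of unity; segments span the full angular
extent because streaks do). Each probe is a tensor product of a 1-D Gaussian
low-pass `phi` (sd `m0/8` along the angle, `m/12` along displacement axes)
and the 6-tap Daubechies db3 high-pass `psi`; the probe responses are turned
into robust standard deviations and unmixed into component strengths by
exact enumeration of the non-negative least-squares active sets on the
`varsigma^2` scale.

Two extensions of the basic recipe, both forced by desk-scale volumes
and verified by the recovery tests:

* **Calibrated quantile instead of the plain MAD.** `mad_std()` keeps the
  `1.4826 * median` form as its default, but the pipeline estimates use the
  25th percentile of absolute deviations calibrated by `1/qnorm(0.625)`.
  On small binned volumes the *signal's* probe response covers more than
  half the voxels, which biases the median upward by an order of magnitude
  on a clean phantom; a lower quantile restores robustness at a modest
  variance cost. On pure noise both estimators agree (criterion 5 recovers
  `(0.02, 0.005, 0)` within 10%).
* **A fourth, white unmixing component.** The three streak probes all
  respond to 3-D white (Poisson) noise with unit gain; with only three
  unknowns that response is attributed to the streaks and the stage
  over-filters when streaks are weak and counts are low. A fourth unknown
  (3-D white, probed by the all-axes db3 tensor) absorbs it and is then
  discarded; it never enters the streak PSD.

## The collaborative filter

BM4D-style: groups of up to 32 similar 4x4x4 cubes, separable orthonormal
DCT on cubes, orthonormal Haar across the group, hard-threshold
(`lambda = 2.7`) then empirical Wiener with the first stage as pilot,
aggregation weighted by inverse retained noise energy. Three elements make
it PSD-aware (each flagged `CORRELATED-NOISE-ENHANCEMENT` in the code):

1. **Exact subband variances.** The noise variance of every cube-DCT
   coefficient is computed from the PSD and the transform basis
   (`subband_variances()`), diagonal-covariance approximation in the
   transform domain; for a flat PSD all variances equal the pixel variance
   (Parseval, tested).
2. **Cross-cube covariance of angularly-DC subbands.** Cubes at the same
   detector position displaced along the angle carry *identical* streak
   noise. Treating group members as independent under-thresholds the
   group-DC coefficients by up to `sqrt(G)`; measured on fixtures, 87% of
   the streak amplitude survived. The filter instead tabulates the exact
   cross-cube covariance of each angle-DC subband over all cube offsets
   reachable in the search window and takes the diagonal of its
   Haar-transformed Gram matrix as the per-group-index variances. This is
   the single most important element for streak removal and our
   concretization of "dealing with long-range noise correlation".
3. **Prefiltered matching.** Distances are computed on a copy whitened by a
   Wiener-type gain `sqrt(v/(v + Psi/|X|))` and smoothed anisotropically
   ((3, 1, 1) px): shared streak structure must not drive the grouping, and
   neither must white noise, because the covariance model of (2) only helps
   when the grouping follows the signal. The search window is elongated
   along the angle ((8, 3, 3) half-widths) for the same reason.

Determinism: the filter has no RNG; ties in matching break by raster order.
Zero PSD makes both stages exact identities (tested to 1e-12), and
`denoise(a z, a^2 Psi) = a denoise(z, Psi)`.

## Multiscale plumbing

Binning is summation; debinning replicates divided by the block size, so
`bin(debin(x)) == x` exactly and the full pyramid with identity denoisers is
the identity map (tested bit-exactly) — the recursion is lossless where the
filter chooses to do nothing. Only the angularly binned subspace of the
input can differ in the output (tested). Angular binning targets 32 coarse
angles; the displacement scale count defaults to
`K = max(1, floor(log2(min(m1, m2)/64)))` — K = 1 for the 64x96x64 fixture.
Forcing deeper pyramids on desk-scale data is counterproductive: a 24x16
coarse plane is signal-dominated and the estimates degrade; K = 2 and
beyond belong to much larger detectors and phantoms.

### Extreme streaks

Scintillator defects produce streaks far outside the stationary model. The
detector compares the angular-median image with a moving 15x15 quadratic
(Savitzky-Golay) fit and replaces flagged detector pixels, per angle, by
their 3x3 displacement-neighborhood median. The residual threshold
(`tau = 4` robust sds) alone is not specific on small volumes — robust
scales collapse to zero on majority-constant data and sharp signal edges
look extreme — so the detector additionally requires, as design decisions:
a dynamic-range floor on the robust scales; a 3x3 spike condition (defects
are points, edges are ridges); angular consistency (a defect offsets its
pixel by the same amount at every angle, a thin sinogram feature does not);
a 1% sparsity cap (defects are rare by nature); and no flags inside the
fit-window border, where the local fit is unreliable. With these, a planted
10-sigma column is detected exactly and white noise yields no false flags;
on a noise-free phantom with sharp edges up to ~0.5% of pixels can still be
flagged — the residual cost is bounded by the neighborhood-median
replacement and measured at under 2% relative deviation end-to-end.

## The Poisson stage

`S = Yhat + smoothed ln(I_B - I_D)` restores count-domain homogeneity; the
smoothing (5x5 median + Gaussian sd 3 px) keeps bright-field outliers and
noise from being reintroduced when the correction is undone. The variance
function `F` is fitted as a polynomial (default degree 2, degree 5
available) to block-wise (mean, variance) pairs, the variance measured
robustly from second differences along the angle — which annihilate both
smooth trends and the angle-constant streaks. Iteratively reweighted fitting
trims gross outlier blocks (edges). If the block-mean spread is below half
the noise scale the model falls back to constant variance (a slope is
unidentifiable); a fitted `F` nonpositive over most of the range errors with
advice to reduce the degree.

The stabilizer is `f(s) = integral of F^{-1/2}` by trapezoidal quadrature on
a 1000-point grid. Two inverses are exposed: the algebraic inverse (tested
to the 0.1% round-trip invariant) and the exact-unbiased inverse
`m -> E[f(m + sqrt(F(m)) xi)]`, tabulated with *stratified* normal quantiles
(400 points x 2000 strata) rather than random draws — deterministic and
lower-variance than naive Monte-Carlo; the two differ by the unbiasedness
correction, which is the point of having both. The Gaussian surrogate is a
choice: the true conditional law of `S` is unavailable without the original
counts, and after stabilization the surrogate error is second-order.

Denoising runs at `K_poi + 1` scales (default `K_poi = 1`) of 3-D summation
binning, each scale independently with a flat PSD whose level is the
segment-wise MAD estimate through the all-axes db3 tensor probe and which is
notched on the streak support (angular-DC plane up to the coarsest streak
scale's Nyquist) — the streak stage is assumed to have removed those
frequencies of the Poisson noise too. Without a preceding streak stage
(`poisson_only_mode()`), the notch is dropped. Scales recombine coarse to
fine keeping only Gaussian-low-passed (sd 1.2 px) content of the coarser
estimate, whose high frequencies are generally estimated worse.

## The synthetic world

The generator reproduces the structure of a classic phantom validation
experiment at desk scale: a 64x96x64 stack (angle x h x v) of analytic parallel-beam
projections of 5-10 random ellipsoids (chord lengths in closed form; the
external anatomical phantom of the original experiment is not
redistributable, so no attempt is made to reproduce any externally reported
SNR value numerically — the acceptance suite checks the analytic constants and the
ordering/benefit structure instead). Counts are scaled to `[peak/2, peak]`
with peaks 640-5120 or infinity; streak stds 0.005-0.05; corruption is
count-domain `Poisson(A) * exp(eta)` with the streak-free-but-noisy
reference `Y = ln(Poisson(A))` defined by common random numbers. What a
green test establishes is therefore: correct noise anatomy (exact angular
constancy, Poisson law within 10%, realized streak std within 10%) and
correct relative behavior of the pipeline on it; what it does not establish
is performance on real detector data with dead pixels, beam hardening or
scatter, none of which are simulated.

## Numerical choices and limitations

* All computation in doubles; file I/O in 32-bit floats (lossless round
  trip at that precision, tested bit-exactly).
* FFT convolutions are circular; estimation trims the wrapped margins
  (never below a quarter of each extent).
* The NNLS enumeration resolves ties toward the white-streak and white
  components; strengths are clipped at zero.
* The filter's `preserve_var` hook (white noise belonging to the stage-1
  target added to the Wiener signal spectrum) is exposed but defaults to
  zero: on fixtures it traded streak suppression for Poisson preservation
  at roughly break-even.
* Runtime scales linearly in voxels; the 64x96x64 full pipeline runs in
  ~20 s single-threaded. Real detector stacks are segment-parallel in
  principle; no parallel path is implemented.
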