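## Bright/dark-field normalization and log transform: raw detector counts to
## the additive-noise log domain. Axis convention throughout the package:
## (angle, horizontal displacement, vertical displacement).

#' Average repeated calibration field acquisitions
#'
#' Detectors are typically calibrated from several bright- and dark-field
#' exposures; the per-pixel arithmetic mean is used (no outlier rejection:
#' defective pixels are handled downstream by the median-based stages).
#'
#' @param field_samples list of 2-D arrays of equal shape.
#' @return 2-D array, the elementwise mean.
#' @export
average_fields <- function(field_samples) {
  if (length(field_samples) == 0) {
    stop("no calibration field samples supplied")
  }
  d <- dim(field_samples[[1]])
  for (f in field_samples) {
    if (!all(dim(f) == d)) stop("calibration field samples differ in shape")
  }
  Reduce(`+`, field_samples) / length(field_samples)
}

#' Bright/dark-field normalization of raw projections
#'
#' Computes `(P_raw - I_D) / (I_B - I_D)` with the fields broadcast over the
#' angular axis. Real detectors can produce nonpositive values in either the
#' numerator or the denominator; both are clamped to a small positive floor
#' before division so that the subsequent logarithm is defined.
#'
#' @param P_raw 3-D array of counts `(angle, h, v)`.
#' @param I_B,I_D 2-D bright- and dark-field `(h, v)`.
#' @param floor_quantile quantile of the positive values used as clamping
#'   floor (default `1e-5`); the floor is never below `1e-6` times the
#'   bright-field median.
#' @param max_bad_fraction error if more than this fraction of `I_B - I_D`
#'   is nonpositive (unusable calibration).
#' @return 3-D array of normalized transmission values, strictly positive.
#' @export
bright_field_normalize <- function(P_raw, I_B, I_D,
                                   floor_quantile = 1e-5,
                                   max_bad_fraction = 0.05) {
  stopifnot(length(dim(P_raw)) == 3)
  if (!all(dim(P_raw)[2:3] == dim(I_B)) || !all(dim(I_B) == dim(I_D))) {
    stop("field shapes do not match projection displacement dimensions")
  }
  denom <- I_B - I_D
  bad <- mean(denom <= 0)
  if (bad > max_bad_fraction) {
    stop(sprintf("unusable calibration: %.1f%% of bright-dark field is nonpositive",
                 100 * bad))
  }
  # only nonpositive values are replaced (real detectors produce them); the
  # floor is a small positive value tied to the data scale
  clamp_pos <- function(x) {
    pos <- x[x > 0]
    fl <- if (length(pos) == 0) {
      max(1e-6 * abs(stats::median(I_B)), .Machine$double.xmin)
    } else {
      max(stats::quantile(pos, floor_quantile, names = FALSE),
          1e-6 * stats::median(I_B))
    }
    x[x <= 0] <- fl
    x
  }
  denom <- clamp_pos(denom)
  m0 <- dim(P_raw)[1]
  num <- sweep(P_raw, 2:3, I_D, `-`)
  num <- clamp_pos(num)
  sweep(num, 2:3, denom, `/`)
}

#' Natural-logarithm transform of normalized projections
#'
#' Elementwise natural log. In the log domain the multiplicative streak
#' component becomes additive (the log acts as a variance-stabilizing
#' transform for it) and noise-free data equal `ln(A)`. The sign convention
#' keeps ln of transmission (nonpositive for absorbing samples); any sign
#' change belongs to the reconstruction step, not here.
#'
#' @param P_norm strictly positive 3-D array.
#' @return 3-D array of log-domain values.
#' @export
log_transform <- function(P_norm) {
  if (any(P_norm <= 0)) {
    stop("log_transform requires strictly positive input; clamp upstream")
  }
  log(P_norm)
}

#' Full normalization front end: fields, clamping and log transform
#' @param P_raw raw projections `(angle, h, v)`.
#' @param I_B,I_D single or list-of 2-D calibration fields.
#' @param ... passed to [bright_field_normalize()].
#' @return log-domain projection stack `Z`.
#' @export
normalize_stack <- function(P_raw, I_B, I_D, ...) {
  if (is.list(I_B)) I_B <- average_fields(I_B)
  if (is.list(I_D)) I_D <- average_fields(I_D)
  log_transform(bright_field_normalize(P_raw, I_B, I_D, ...))
}
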