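#' Phasor population codes for 2D vectors
#'
#' A 2D vector is represented as the amplitude (length) and phase (angle) of a
#' sinusoidal activity profile across N columnar units with evenly spaced
#' preferred directions, mirroring the columnar compartments of the insect
#' protocerebral bridge. With a positive baseline rate the profile stays
#' non-negative for any magnitude up to the baseline, so rates remain
#' physiologically interpretable.
#'
#' @name phasor
NULL

#' Construct a phasor activity object
#'
#' Low-level constructor; most users should call [phasor_encode()].
#'
#' @param rates numeric vector of N column rates.
#' @param baseline scalar offset rate subtracted before decoding.
#' @param validate check invariants.
#' @return an object of class `"phasor"`.
#' @export
phasor <- function(rates, baseline = 1, validate = TRUE) {
  p <- structure(
    list(rates = as.numeric(rates), baseline = baseline,
         n_columns = length(rates)),
    class = "phasor")
  if (validate) {
    stopifnot(is.numeric(p$rates), length(p$rates) >= 3L,
              is.finite(baseline), all(is.finite(p$rates)))
  }
  p
}

#' Preferred directions of the phasor columns
#'
#' @param n_columns number of columns N.
#' @return numeric vector theta_i = 2*pi*i/N for i = 0..N-1.
#' @export
phasor_axes <- function(n_columns) {
  2 * pi * (seq_len(n_columns) - 1L) / n_columns
}

#' Encode a 2D vector as sinusoidal column activity
#'
#' Column i fires at `baseline + magnitude * cos(angle - theta_i)` where the
#' preferred directions theta_i are spaced 2*pi/N apart (45 degrees for the
#' default N = 8, one column per protocerebral-bridge compartment).
#'
#' @param angle vector angle, radians CCW from +x.
#' @param magnitude vector length; must not exceed `baseline` (saturation).
#' @param n_columns number of columns (>= 3 so the phase is recoverable).
#' @param baseline baseline rate.
#' @return a [phasor] object.
#' @export
#' @examples
#' p <- phasor_encode(pi / 4, 0.5)
#' phasor_decode(p)
phasor_encode <- function(angle, magnitude, n_columns = 8L, baseline = 1) {
  if (n_columns < 3L)
    stop("phasor_encode: n_columns must be >= 3 (phase not recoverable)",
         call. = FALSE)
  if (magnitude < 0)
    stop("phasor_encode: magnitude must be >= 0", call. = FALSE)
  if (magnitude > baseline + 1e-12)
    stop(sprintf(
      "phasor_encode: saturation (magnitude %.6g exceeds baseline %.6g)",
      magnitude, baseline), call. = FALSE)
  theta <- phasor_axes(n_columns)
  phasor(baseline + magnitude * cos(angle - theta), baseline = baseline,
         validate = FALSE)
}

#' Decode a phasor into (angle, magnitude)
#'
#' Projects the baseline-subtracted rates onto the fundamental Fourier
#' component. A zero-magnitude phasor has no defined phase; it is returned
#' with `angle = 0` and `undefined = TRUE` rather than raising, because the
#' path-integration home vector is legitimately zero at the nest.
#'
#' @param p a [phasor] object.
#' @param zero_tol magnitudes below this are flagged undefined.
#' @return list with `angle` (radians), `magnitude`, `undefined` (logical).
#' @export
phasor_decode <- function(p, zero_tol = 1e-12) {
  stopifnot(inherits(p, "phasor"))
  theta <- phasor_axes(p$n_columns)
  z <- sum((p$rates - p$baseline) * exp(1i * theta)) * 2 / p$n_columns
  mag <- Mod(z)
  if (mag < zero_tol) {
    list(angle = 0, magnitude = 0, undefined = TRUE)
  } else {
    list(angle = Arg(z), magnitude = mag, undefined = FALSE)
  }
}

#' Add two phasors (vector addition in the population code)
#'
#' Elementwise rate sum minus one baseline: the result decodes to the complex
#' (2D vector) sum of the operands. This is the population-level
#' implementation of vector addition used throughout the central complex.
#'
#' @param a,b [phasor] objects with equal `n_columns` and `baseline`.
#' @return a [phasor] decoding to `decode(a) + decode(b)`.
#' @export
phasor_add <- function(a, b) {
  stopifnot(inherits(a, "phasor"), inherits(b, "phasor"))
  if (a$n_columns != b$n_columns)
    stop("phasor_add: mismatched n_columns", call. = FALSE)
  if (abs(a$baseline - b$baseline) > 1e-12)
    stop("phasor_add: mismatched baselines", call. = FALSE)
  phasor(a$rates + b$rates - a$baseline, baseline = a$baseline,
         validate = FALSE)
}

#' Scale a phasor's encoded magnitude
#'
#' @param p a [phasor].
#' @param gain scalar multiplier applied to the baseline-subtracted profile.
#' @return a [phasor] decoding to `gain` times the original vector.
#' @export
phasor_scale <- function(p, gain) {
  stopifnot(inherits(p, "phasor"))
  phasor(p$baseline + gain * (p$rates - p$baseline), baseline = p$baseline,
         validate = FALSE)
}

#' Negate the vector encoded by a phasor
#'
#' @param p a [phasor].
#' @return a [phasor] decoding to minus the original vector.
#' @export
phasor_negate <- function(p) phasor_scale(p, -1)

#' Rotate the vector encoded by a phasor
#'
#' Implemented by resampling the sinusoid at shifted phases (exact for the
#' first harmonic, which is all a valid phasor carries).
#'
#' @param p a [phasor].
#' @param dtheta rotation angle, radians CCW.
#' @return a rotated [phasor].
#' @export
phasor_rotate <- function(p, dtheta) {
  d <- phasor_decode(p)
  phasor_encode_raw(d$angle + dtheta, d$magnitude, p$n_columns, p$baseline)
}

# Unchecked encode used internally where magnitudes may exceed the baseline
# (e.g. CPU4 accumulation before the saturation check fires).
phasor_encode_raw <- function(angle, magnitude, n_columns, baseline) {
  theta <- phasor_axes(n_columns)
  phasor(baseline + magnitude * cos(angle - theta), baseline = baseline,
         validate = FALSE)
}

#' @export
print.phasor <- function(x, ...) {
  d <- phasor_decode(x)
  cat(sprintf(
    "<phasor> %d columns, baseline %.3g: angle %.4f rad, magnitude %.4g%s\n",
    x$n_columns, x$baseline, d$angle, d$magnitude,
    if (d$undefined) " (phase undefined)" else ""))
  invisible(x)
}

#' Convert a phasor to Cartesian components
#'
#' @param p a [phasor].
#' @return numeric `c(x, y)`.
#' @export
phasor_xy <- function(p) {
  d <- phasor_decode(p)
  d$magnitude * c(cos(d$angle), sin(d$angle))
}

#' Encode Cartesian components as a phasor
#'
#' @param x,y Cartesian components.
#' @inheritParams phasor_encode
#' @param check saturation check (default TRUE).
#' @return a [phasor].
#' @export
phasor_from_xy <- function(x, y, n_columns = 8L, baseline = 1, check = TRUE) {
  mag <- sqrt(x^2 + y^2)
  ang <- if (mag == 0) 0 else atan2(y, x)
  if (check) phasor_encode(ang, mag, n_columns, baseline)
  else phasor_encode_raw(ang, mag, n_columns, baseline)
}
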