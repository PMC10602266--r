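#' Single-cycle waveform containers
#'
#' `raw_waveform()` wraps one cardiac cycle of pressure samples, in arbitrary
#' units and at an arbitrary (possibly nonuniform) sampling rate, together
#' with the cycle duration `T` and the dicrotic-notch time `T0` (both in
#' seconds). The notch time is always supplied metadata -- it is never
#' inferred from the samples. `scaled_waveform()` wraps the dimensionless
#' standard form every downstream routine consumes: exactly 500 values on
#' the uniform grid `tau_k = k/499` spanning `[0, 1]`, min--max normalized
#' so the minimum is exactly 0 and the maximum exactly 1, plus the notch
#' fraction `T0_hat` in `(0, 1)`.
#'
#' @param time Sample times in seconds; strictly increasing, starting at 0,
#'   with the last sample at or before `cycle_duration`.
#' @param value Pressure samples in arbitrary units; at least 8 samples, not
#'   all equal.
#' @param cycle_duration Cardiac cycle length `T` in seconds.
#' @param notch_time Dicrotic-notch time `T0` in seconds, `0 < T0 < T`.
#'
#' @return A tibble of samples (`time`/`value`, or `tau`/`value` for the
#'   scaled form) with class `raw_waveform` (resp. `scaled_waveform`) and
#'   the timing metadata stored as attributes.
#' @examples
#' t <- seq(0, 0.8, length.out = 60)
#' w <- raw_waveform(t, 80 + 40 * sin(2 * pi * t / 0.8)^2,
#'                   cycle_duration = 0.8, notch_time = 0.3)
#' prepare_waveform(w)
#' @export
raw_waveform <- function(time, value, cycle_duration, notch_time) {
  time <- as.double(time)
  value <- as.double(value)
  check_number(cycle_duration, "cycle_duration", positive = TRUE)
  check_number(notch_time, "notch_time")
  if (length(time) != length(value)) {
    stop_invalid("`time` and `value` must have the same length.")
  }
  if (length(time) < 8) {
    stop_invalid("A raw waveform needs at least 8 samples.")
  }
  if (any(diff(time) <= 0)) stop_invalid("`time` must be strictly increasing.")
  if (time[1] != 0) stop_invalid("The first sample must be at time 0.")
  if (time[length(time)] > cycle_duration) {
    stop_invalid("Samples must not extend past `cycle_duration`.")
  }
  if (notch_time <= 0 || notch_time >= cycle_duration) {
    stop_invalid("`notch_time` must satisfy 0 < T0 < T.")
  }
  if (max(value) == min(value)) {
    stop_invalid("Waveform values are all equal; range must be positive.")
  }
  out <- tibble(time = time, value = value)
  attr(out, "cycle_duration") <- cycle_duration
  attr(out, "notch_time") <- notch_time
  class(out) <- c("raw_waveform", class(out))
  out
}

#' @param x For `scaled_waveform()`, 500 dimensionless values on the standard
#'   grid; for `as_scaled_waveform()`, a `scaled_waveform`, a numeric vector,
#'   or a data frame with a `value` column.
#' @param notch_fraction Notch time as a fraction of the cycle, in `(0, 1)`.
#' @rdname raw_waveform
#' @export
scaled_waveform <- function(x, notch_fraction) {
  x <- as.double(x)
  check_number(notch_fraction, "notch_fraction")
  if (length(x) != 500) {
    stop_invalid("A standard-form waveform has exactly 500 samples.")
  }
  if (abs(min(x)) > 1e-9 || abs(max(x) - 1) > 1e-9) {
    stop_invalid("Standard-form values must span [0, 1] exactly.")
  }
  if (notch_fraction <= 0 || notch_fraction >= 1) {
    stop_invalid("`notch_fraction` must lie strictly inside (0, 1).")
  }
  new_scaled_waveform(x, notch_fraction)
}

# Internal constructor without the exact-[0,1] check; used for synthetic
# waveforms, whose analytic values are intentionally not re-normalized.
new_scaled_waveform <- function(values, notch_fraction) {
  out <- tibble(tau = seq(0, 1, length.out = length(values)),
                value = as.double(values))
  attr(out, "notch_fraction") <- as.double(notch_fraction)
  class(out) <- c("scaled_waveform", class(out))
  out
}

#' @rdname raw_waveform
#' @export
as_scaled_waveform <- function(x, notch_fraction = NULL) {
  if (inherits(x, "scaled_waveform")) return(x)
  if (is.data.frame(x)) x <- x$value
  if (is.null(notch_fraction)) {
    stop_invalid("`notch_fraction` is required when `x` is not a scaled_waveform.")
  }
  if (length(x) != 500) {
    stop_invalid("A standard-form waveform has exactly 500 samples.")
  }
  if (notch_fraction <= 0 || notch_fraction >= 1) {
    stop_invalid("`notch_fraction` must lie strictly inside (0, 1).")
  }
  new_scaled_waveform(as.double(x), notch_fraction)
}

notch_fraction_of <- function(w) {
  nf <- attr(w, "notch_fraction")
  if (is.null(nf)) stop_invalid("Waveform carries no `notch_fraction`.")
  nf
}

#' Waveform normalization and resampling
#'
#' Three composable steps take an arbitrary-unit, arbitrary-rate waveform to
#' the dimensionless standard form:
#'
#' 1. `normalize_amplitude()` maps values to
#'    `(P - Pmin)/(Pmax - Pmin)`, so the minimum is 0 and the maximum 1.
#' 2. `normalize_time()` rescales time by the cycle duration, `tau = t/T`,
#'    and converts the notch time to a fraction `T0_hat = T0/T`.
#' 3. `resample_to_standard()` interpolates onto the uniform 500-point grid
#'    with a natural cubic spline (no extrapolation; a grid that stops short
#'    of `tau = 1` is padded by repeating the last sample there, consistent
#'    with a periodic cycle), then applies one final min--max pass so the
#'    exact `[0, 1]` range holds despite any spline overshoot.
#'
#' `prepare_waveform()` composes the three in that order. The result is
#' invariant under affine changes of the value unit and rescalings of the
#' time unit, and preparing a waveform already in standard form returns it
#' unchanged.
#'
#' @param w A waveform: [raw_waveform()] output for the first two steps, or
#'   any data frame with `tau` and `value` columns (plus a `notch_fraction`
#'   attribute) for `resample_to_standard()`.
#' @param cycle_duration,notch_time Timing metadata for `normalize_time()`;
#'   taken from the `raw_waveform` attributes when omitted.
#' @param n Number of standard grid samples (500).
#'
#' @return `normalize_amplitude()` returns its input with rescaled values;
#'   `normalize_time()` a tibble with `tau`/`value` and a `notch_fraction`
#'   attribute; `resample_to_standard()` and `prepare_waveform()` a
#'   [scaled_waveform()].
#' @examples
#' t <- seq(0, 0.9, length.out = 80)
#' w <- raw_waveform(t, 70 + 50 * exp(-5 * t) * sin(8 * t)^2,
#'                   cycle_duration = 0.9, notch_time = 0.33)
#' s <- prepare_waveform(w)
#' range(s$value)
#' @export
normalize_amplitude <- function(w) {
  if (!is.data.frame(w) || !"value" %in% names(w)) {
    stop_invalid("`w` must be a data frame with a `value` column.")
  }
  rng <- max(w$value) - min(w$value)
  if (rng <= 0) stop_invalid("Waveform is flat; value range must be positive.")
  w$value <- (w$value - min(w$value)) / rng
  w
}

#' @rdname normalize_amplitude
#' @export
normalize_time <- function(w, cycle_duration = attr(w, "cycle_duration"),
                           notch_time = attr(w, "notch_time")) {
  if (!is.data.frame(w) || !all(c("time", "value") %in% names(w))) {
    stop_invalid("`w` must be a data frame with `time` and `value` columns.")
  }
  if (is.null(cycle_duration) || cycle_duration <= 0) {
    stop_invalid("`cycle_duration` must be > 0.")
  }
  if (is.null(notch_time)) stop_invalid("`notch_time` is required.")
  out <- tibble(tau = w$time / cycle_duration, value = w$value)
  attr(out, "notch_fraction") <- notch_time / cycle_duration
  out
}

#' @rdname normalize_amplitude
#' @export
resample_to_standard <- function(w, n = 500) {
  if (!is.data.frame(w) || !all(c("tau", "value") %in% names(w))) {
    stop_invalid("`w` must be a data frame with `tau` and `value` columns.")
  }
  nf <- notch_fraction_of(w)
  tau <- w$tau
  val <- w$value
  m <- length(tau)
  if (m < 4) stop_invalid("Cubic spline resampling needs at least 4 samples.")
  if (min(tau) < -1e-12 || max(tau) > 1 + 1e-12) {
    stop_invalid("`tau` must lie within [0, 1]; extrapolation is not supported.")
  }
  last <- tau[m]
  if (last < 1) {
    if (1 - last > 1 / (2 * m)) {
      # grid stops well short of the cycle end: repeat the last sample at
      # tau = 1 (periodic-cycle padding)
      tau <- c(tau, 1)
      val <- c(val, val[m])
    } else {
      tau[m] <- 1
    }
  }
  if (tau[1] > 0) {
    tau <- c(0, tau)
    val <- c(val[1], val)
  } else {
    tau[1] <- 0
  }
  grid <- seq(0, 1, length.out = n)
  fit <- stats::splinefun(tau, val, method = "natural")
  out <- fit(grid)
  rng <- max(out) - min(out)
  if (rng <= 0) stop_invalid("Resampled waveform is flat.")
  out <- (out - min(out)) / rng
  new_scaled_waveform(out, nf)
}

#' @rdname normalize_amplitude
#' @export
prepare_waveform <- function(w, n = 500) {
  if (!inherits(w, "raw_waveform")) {
    stop_invalid("`w` must be a raw_waveform.")
  }
  w |>
    normalize_amplitude() |>
    normalize_time() |>
    resample_to_standard(n = n)
}

#' @export
print.scaled_waveform <- function(x, ...) {
  cat(sprintf(
    "<scaled_waveform: %d samples on [0, 1], notch at %.4f, range [%.3f, %.3f]>\n",
    nrow(x), attr(x, "notch_fraction"), min(x$value), max(x$value)))
  invisible(x)
}

#' @export
print.raw_waveform <- function(x, ...) {
  cat(sprintf("<raw_waveform: %d samples, T = %g s, T0 = %g s>\n",
              nrow(x), attr(x, "cycle_duration"), attr(x, "notch_time")))
  invisible(x)
}
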