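#' Intrinsic-frequency parameter tables
#'
#' The intrinsic-frequency (IF) model represents one cardiac cycle of an
#' arterial pressure waveform as two constant-envelope sinusoids joined
#' continuously at the dicrotic notch and periodic over the cycle: a systolic
#' regime with angular frequency `omega1` (the coupled heart--aorta system)
#' and a diastolic regime with `omega2` (the decoupled aorta). `ifpulse`
#' stores parameter sets as plain tibbles, one record per row, in one of two
#' equivalent forms:
#'
#' * **Cartesian** -- columns `a1, b1, a2, b2, c, omega1, omega2` (plus
#'   `T0`, `T`): the waveform is
#'   `a*cos(omega*t) + b*sin(omega*t) + c` on each regime.
#' * **Phase** -- columns `omega1, omega2, Rs, Rd, phi1, phi2, c` (plus `T0`,
#'   `T`): each regime is `R*sin(omega*t + phi) + c`, with envelope `R >= 0`
#'   and initial phase `phi` in `(-pi, pi]`.
#'
#' Dimensionless ("scaled") parameter tables use hatted column names
#' (`omega1_hat`, ..., `T0_hat`) and refer to the standard waveform form:
#' values min--max normalized to `[0, 1]` and time normalized to a unit
#' cardiac cycle, so scaled frequencies are radians per cycle. `if_params()`
#' builds a scaled phase-form table, completing the diastolic phase and
#' envelope analytically via [recover_diastolic()] when they are omitted, and
#' appending the envelope ratio `ER_hat = Rs_hat / Rd_hat`.
#'
#' @param omega1_hat,omega2_hat Scaled systolic and diastolic intrinsic
#'   frequencies (radians per cardiac cycle), positive.
#' @param Rs_hat Scaled systolic envelope (dimensionless, `>= 0`).
#' @param phi1_hat Systolic initial phase (radians).
#' @param c_hat Scaled fitting constant (dimensionless).
#' @param T0_hat Dicrotic-notch time as a fraction of the cycle, in `(0, 1)`.
#' @param phi2_hat,Rd_hat Diastolic phase and envelope; computed from the
#'   continuity and periodicity constraints when `NULL`.
#'
#' @return A tibble with columns `omega1_hat`, `omega2_hat`, `Rs_hat`,
#'   `Rd_hat`, `phi1_hat`, `phi2_hat`, `c_hat`, `T0_hat`, `ER_hat`.
#'
#' @examples
#' if_params(omega1_hat = 8, omega2_hat = 5, Rs_hat = 0.4,
#'           phi1_hat = -0.6, c_hat = 0.4, T0_hat = 0.37)
#' @export
if_params <- function(omega1_hat, omega2_hat, Rs_hat, phi1_hat, c_hat, T0_hat,
                      phi2_hat = NULL, Rd_hat = NULL) {
  p <- tibble(
    omega1_hat = as.double(omega1_hat),
    omega2_hat = as.double(omega2_hat),
    Rs_hat = as.double(Rs_hat),
    phi1_hat = as.double(phi1_hat),
    c_hat = as.double(c_hat),
    T0_hat = as.double(T0_hat)
  )
  if (any(p$omega1_hat <= 0) || any(p$omega2_hat <= 0)) {
    stop_invalid("Intrinsic frequencies must be positive.")
  }
  if (any(p$T0_hat <= 0 | p$T0_hat >= 1)) {
    stop_invalid("`T0_hat` must lie strictly inside (0, 1).")
  }
  if (is.null(phi2_hat) || is.null(Rd_hat)) {
    rec <- recover_diastolic(p$omega1_hat, p$omega2_hat, p$Rs_hat,
                             p$phi1_hat, p$T0_hat)
    phi2_hat <- rec$phi2_hat
    Rd_hat <- rec$Rd_hat
  }
  p$phi2_hat <- as.double(phi2_hat)
  p$Rd_hat <- as.double(Rd_hat)
  p$ER_hat <- ifelse(p$Rd_hat > 0, p$Rs_hat / p$Rd_hat, NA_real_)
  p[, c("omega1_hat", "omega2_hat", "Rs_hat", "Rd_hat", "phi1_hat",
        "phi2_hat", "c_hat", "T0_hat", "ER_hat")]
}

#' Convert between Cartesian and phase parameterizations
#'
#' The two parameterizations are related by `a = R*sin(phi)`,
#' `b = R*cos(phi)`, so that `a*cos(w*t) + b*sin(w*t) = R*sin(w*t + phi)`.
#' The phase form is canonicalized to `R >= 0` with `phi` in `(-pi, pi]`,
#' using the two-argument arctangent (the printed one-argument `atan(a/b)`
#' relation is quadrant-ambiguous). A zero-amplitude regime maps to
#' `R = 0, phi = 0` by convention.
#'
#' @param params A data frame with Cartesian columns `a1, b1, a2, b2`
#'   (for `cartesian_to_phase()`) or phase columns `Rs, Rd, phi1, phi2`
#'   (for `phase_to_cartesian()`). Frequency, constant, and timing columns
#'   (`omega1`, `omega2`, `c`, `T0`, `T`, or their hatted variants) are
#'   passed through unchanged.
#'
#' @return A tibble in the other parameterization.
#' @examples
#' p <- tibble::tibble(a1 = 1, b1 = 0, a2 = 0.3, b2 = 0.4,
#'                     c = 0.5, omega1 = 8, omega2 = 5)
#' cartesian_to_phase(p)
#' @export
cartesian_to_phase <- function(params) {
  params <- as_tibble(params)
  need <- c("a1", "b1", "a2", "b2")
  if (!all(need %in% names(params))) {
    stop_invalid("`params` must contain columns a1, b1, a2, b2.")
  }
  ang <- function(a, b) ifelse(a == 0 & b == 0, 0, atan2(a, b))
  out <- params[, setdiff(names(params), need), drop = FALSE]
  out$Rs <- sqrt(params$a1^2 + params$b1^2)
  out$Rd <- sqrt(params$a2^2 + params$b2^2)
  out$phi1 <- wrap_angle(ang(params$a1, params$b1))
  out$phi2 <- wrap_angle(ang(params$a2, params$b2))
  as_tibble(out)
}

#' @rdname cartesian_to_phase
#' @export
phase_to_cartesian <- function(params) {
  params <- as_tibble(params)
  need <- c("Rs", "Rd", "phi1", "phi2")
  if (!all(need %in% names(params))) {
    stop_invalid("`params` must contain columns Rs, Rd, phi1, phi2.")
  }
  out <- params[, setdiff(names(params), need), drop = FALSE]
  out$a1 <- params$Rs * sin(params$phi1)
  out$b1 <- params$Rs * cos(params$phi1)
  out$a2 <- params$Rd * sin(params$phi2)
  out$b2 <- params$Rd * cos(params$phi2)
  as_tibble(out)
}

#' Analytic recovery of the diastolic phase and envelope
#'
#' Given the five scaled parameters `(omega1_hat, omega2_hat, Rs_hat,
#' phi1_hat, T0_hat)`, the remaining diastolic pair `(phi2_hat, Rd_hat)` is
#' determined analytically by the two model constraints on the unit cycle:
#' continuity at the notch,
#' `Rs*sin(w1*T0 + phi1) = Rd*sin(w2*T0 + phi2)`, and periodicity,
#' `Rs*sin(phi1) = Rd*sin(w2 + phi2)`. Dividing the two gives a tangent
#' equation for `phi2`; `Rd` then follows from the periodicity constraint.
#' The result is canonicalized to `Rd_hat >= 0` (shifting `phi2_hat` by `pi`
#' if needed) and `phi2_hat` in `(-pi, pi]`.
#'
#' The geometry degenerates when `|sin(omega2_hat + phi2_hat)| < 1e-10`
#' (the periodicity constraint would make the envelope unbounded) or when
#' `Rs_hat*sin(phi1_hat) = 0` while the continuity constraint demands a
#' nonzero diastolic value. With `strict = TRUE` (default) such inputs raise
#' an error; with `strict = FALSE` they are returned flagged in the
#' `degenerate` column with `NA` results, which is how the synthetic
#' generator rejects them.
#'
#' @param omega1_hat,omega2_hat,Rs_hat,phi1_hat,T0_hat Scaled IF parameters
#'   (vectors are recycled to a common length).
#' @param strict Error on degenerate geometry (default) or flag it.
#' @param tol Degeneracy threshold on the relevant sine magnitudes.
#'
#' @return A tibble with columns `phi2_hat`, `Rd_hat`, `degenerate`.
#' @examples
#' recover_diastolic(2 * pi, 2 * pi, 1, -0.5, 0.37)
#' @export
recover_diastolic <- function(omega1_hat, omega2_hat, Rs_hat, phi1_hat,
                              T0_hat, strict = TRUE, tol = 1e-10) {
  n <- max(length(omega1_hat), length(omega2_hat), length(Rs_hat),
           length(phi1_hat), length(T0_hat))
  w1 <- rep_len(as.double(omega1_hat), n)
  w2 <- rep_len(as.double(omega2_hat), n)
  Rs <- rep_len(as.double(Rs_hat), n)
  phi1 <- rep_len(as.double(phi1_hat), n)
  T0 <- rep_len(as.double(T0_hat), n)

  A <- sin(w1 * T0 + phi1)   # continuity requirement (per unit Rs)
  B <- sin(phi1)             # periodicity requirement (per unit Rs)
  num <- B * sin(w2 * T0) - A * sin(w2)
  den <- A * cos(w2) - B * cos(w2 * T0)
  phi2 <- atan2(num, den)
  s2 <- sin(w2 + phi2)
  Rd <- Rs * B / s2

  flat <- Rs == 0 | (abs(A) < tol & abs(B) < tol)
  phi2[flat] <- 0
  Rd[flat] <- 0

  degenerate <- !flat & (abs(s2) < tol | (abs(B) < tol & abs(A) >= tol))
  phi2[degenerate] <- NA_real_
  Rd[degenerate] <- NA_real_

  neg <- !degenerate & !is.na(Rd) & Rd < 0
  Rd[neg] <- -Rd[neg]
  phi2[neg] <- phi2[neg] + pi
  phi2 <- wrap_angle(phi2)

  if (strict && any(degenerate)) {
    abort(
      sprintf("Degenerate diastolic geometry for %d of %d parameter tuples.",
              sum(degenerate), n),
      class = "ifpulse_degenerate"
    )
  }
  tibble(phi2_hat = phi2, Rd_hat = Rd, degenerate = degenerate)
}

#' Constraint residuals of a scaled IF parameter set
#'
#' Evaluates the continuity and periodicity constraints in phase form on the
#' unit cycle and returns left-minus-right residuals:
#' `continuity = Rs*sin(w1*T0 + phi1) - Rd*sin(w2*T0 + phi2)` and
#' `periodicity = Rs*sin(phi1) - Rd*sin(w2 + phi2)`. Parameters produced by
#' [recover_diastolic()] or [solve_if()] satisfy both to better than `1e-9`.
#'
#' @param params A scaled phase-form parameter table (see [if_params()]).
#' @return A tibble with columns `continuity`, `periodicity`.
#' @export
constraint_residuals <- function(params) {
  params <- as_tibble(params)
  with(params, tibble(
    continuity = Rs_hat * sin(omega1_hat * T0_hat + phi1_hat) -
      Rd_hat * sin(omega2_hat * T0_hat + phi2_hat),
    periodicity = Rs_hat * sin(phi1_hat) -
      Rd_hat * sin(omega2_hat + phi2_hat)
  ))
}

#' Evaluate the piecewise-sinusoid IF model
#'
#' `if_eval()` evaluates the scaled IF model at arbitrary normalized times;
#' `reconstruct()` evaluates it on the standard uniform grid
#' `tau_k = k/(n-1)`. Systole is the half-open interval `[0, T0_hat)` and
#' diastole is `[T0_hat, 1]`:
#' `value(tau) = c_hat + Rs_hat*sin(omega1_hat*tau + phi1_hat)` for
#' `tau < T0_hat` and
#' `value(tau) = c_hat + Rd_hat*sin(omega2_hat*tau + phi2_hat)` otherwise.
#'
#' @param params A scaled phase-form parameter table, one or more rows.
#' @param tau Normalized times at which to evaluate.
#' @param n Number of uniform grid samples for `reconstruct()`.
#'
#' @return A numeric matrix with one row per parameter record and one column
#'   per time point (a plain vector when `params` has a single row).
#' @examples
#' p <- if_params(8, 5, 0.4, phi1_hat = -0.6, c_hat = 0.4, T0_hat = 0.37)
#' w <- reconstruct(p)
#' length(w)
#' @export
if_eval <- function(params, tau) {
  params <- as_tibble(params)
  tau <- as.double(tau)
  sys_val <- params$c_hat +
    params$Rs_hat * sin(outer(params$omega1_hat, tau) + params$phi1_hat)
  dia_val <- params$c_hat +
    params$Rd_hat * sin(outer(params$omega2_hat, tau) + params$phi2_hat)
  dia <- outer(params$T0_hat, tau, function(t0, tt) tt >= t0)
  out <- ifelse(dia, dia_val, sys_val)
  if (nrow(params) == 1) as.vector(out) else out
}

#' @rdname if_eval
#' @export
reconstruct <- function(params, n = 500) {
  if (n < 2) stop_invalid("`n` must be at least 2.")
  if_eval(params, seq(0, 1, length.out = n))
}

#' Scale IF parameters to the dimensionless standard form (and back)
#'
#' A waveform in original units (pressure range `[Pmin, Pmax]`, cycle length
#' `T` seconds) and its unscaled phase-form IF parameters map to the
#' dimensionless standard form by `omega_hat = omega * T` (radians per
#' cycle), `c_hat = (c - Pmin)/(Pmax - Pmin)`, `R_hat = R/(Pmax - Pmin)`,
#' `T0_hat = T0/T`, with phases unchanged. `denormalize_parameters()` is the
#' exact inverse.
#'
#' @param params Unscaled phase-form table with columns `omega1, omega2, Rs,
#'   Rd, phi1, phi2, c, T0` (for `normalize_parameters()`), or a scaled
#'   table (see [if_params()]) for `denormalize_parameters()`.
#' @param Pmin,Pmax Waveform minimum and maximum in original units
#'   (`Pmax > Pmin`).
#' @param T Cardiac cycle duration in original time units (`> 0`).
#'
#' @return A tibble of scaled (resp. unscaled) phase-form parameters.
#' @examples
#' u <- tibble::tibble(omega1 = 10, omega2 = 6, Rs = 20, Rd = 10,
#'                     phi1 = -0.5, phi2 = 0.2, c = 90, T0 = 0.3)
#' s <- normalize_parameters(u, Pmin = 50, Pmax = 130, T = 0.8)
#' denormalize_parameters(s, Pmin = 50, Pmax = 130, T = 0.8)
#' @export
normalize_parameters <- function(params, Pmin, Pmax, T) {
  check_scaling(Pmin, Pmax, T)
  params <- as_tibble(params)
  rng <- Pmax - Pmin
  out <- tibble(
    omega1_hat = params$omega1 * T,
    omega2_hat = params$omega2 * T,
    Rs_hat = params$Rs / rng,
    Rd_hat = params$Rd / rng,
    phi1_hat = params$phi1,
    phi2_hat = params$phi2,
    c_hat = (params$c - Pmin) / rng,
    T0_hat = params$T0 / T
  )
  out$ER_hat <- ifelse(out$Rd_hat > 0, out$Rs_hat / out$Rd_hat, NA_real_)
  out
}

#' @rdname normalize_parameters
#' @export
denormalize_parameters <- function(params, Pmin, Pmax, T) {
  check_scaling(Pmin, Pmax, T)
  params <- as_tibble(params)
  rng <- Pmax - Pmin
  out <- tibble(
    omega1 = params$omega1_hat / T,
    omega2 = params$omega2_hat / T,
    Rs = params$Rs_hat * rng,
    Rd = params$Rd_hat * rng,
    phi1 = params$phi1_hat,
    phi2 = params$phi2_hat,
    c = params$c_hat * rng + Pmin,
    T0 = params$T0_hat * T
  )
  out$ER <- ifelse(out$Rd > 0, out$Rs / out$Rd, NA_real_)
  out
}

check_scaling <- function(Pmin, Pmax, T) {
  check_number(Pmin, "Pmin")
  check_number(Pmax, "Pmax")
  check_number(T, "T", positive = TRUE)
  if (Pmax <= Pmin) stop_invalid("`Pmax` must exceed `Pmin`.")
  invisible(NULL)
}
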