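# Shared fixtures and independent oracles, all built in code.

# Draw n full scaled parameter tables uniformly inside an interval table,
# completing the diastolic pair; independent of sample_parameters()'s
# filtering logic (no value-band or ratio filters).
draw_tuples <- function(n, seed, ranges = parameter_ranges("table3")) {
  iv <- ranges$intervals
  withr::with_seed(seed, {
    draw <- lapply(stats::setNames(nm = iv$parameter), function(par) {
      i <- match(par, iv$parameter)
      stats::runif(n, iv$lower[i], iv$upper[i])
    })
    tibble::as_tibble(draw)
  })
}

# Smallest-magnitude difference between two angles.
wrap_err <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# A smooth, slowly oscillating pulse in exact standard form (values
# min-max normalized), used where spline resampling accuracy matters.
smooth_standard_pulse <- function() {
  p <- if_params(omega1_hat = 7.5, omega2_hat = 4, Rs_hat = 0.42,
                 phi1_hat = -0.55, c_hat = 0.45, T0_hat = 0.37)
  v <- reconstruct(p)
  v <- (v - min(v)) / (max(v) - min(v))
  as_scaled_waveform(v, notch_fraction = 0.37)
}

# Dense KKT solve of the equality-constrained least-squares subproblem:
# an oracle for fit_linear_given_frequencies built directly from the
# stationarity conditions, sharing no code with the implementation.
kkt_objective <- function(w, omega1_hat, omega2_hat) {
  T0 <- attr(w, "notch_fraction")
  tau <- w$tau
  P <- w$value
  sys <- tau < T0
  X <- matrix(0, length(tau), 5)
  X[sys, 1] <- cos(omega1_hat * tau[sys])
  X[sys, 2] <- sin(omega1_hat * tau[sys])
  X[!sys, 3] <- cos(omega2_hat * tau[!sys])
  X[!sys, 4] <- sin(omega2_hat * tau[!sys])
  X[, 5] <- 1
  C <- rbind(
    c(cos(omega1_hat * T0), sin(omega1_hat * T0),
      -cos(omega2_hat * T0), -sin(omega2_hat * T0), 0),
    c(1, 0, -cos(omega2_hat), -sin(omega2_hat), 0)
  )
  K <- rbind(cbind(2 * crossprod(X), t(C)),
             cbind(C, matrix(0, 2, 2)))
  sol <- solve(K, c(2 * crossprod(X, P), 0, 0))
  theta <- sol[1:5]
  sum((P - drop(X %*% theta))^2)
}

# Network-input view of a dataset, built independently of the package's
# internal accessor.
surrogate_inputs_for_test <- function(ds) {
  cbind(ds$params$T0_hat, ds$waveforms)
}

# Tiny x/y regression set with a constant target, for degenerate training
# checks. Inputs are random so only the bias terms matter.
constant_target_set <- function(n, width, seed) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(n * width), n, width)
    y <- cbind(rep(2, n) + stats::rnorm(n, 0, 1e-4),
               rep(-1, n) + stats::rnorm(n, 0, 1e-4))
    list(x = x, y = y)
  })
}
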