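test_that("cartesian/phase conversion uses the quadrant-aware convention", {
  # pure sine: a = 0, b = 1 -> R = 1, phi = 0
  p <- cartesian_to_phase(tibble::tibble(a1 = 0, b1 = 1, a2 = 0, b2 = 1))
  expect_equal(c(p$Rs, p$phi1), c(1, 0))
  # pure cosine: a = 1, b = 0 -> R = 1, phi = pi/2
  p <- cartesian_to_phase(tibble::tibble(a1 = 1, b1 = 0, a2 = 1, b2 = 0))
  expect_equal(c(p$Rs, p$phi1), c(1, pi / 2))
  # degenerate envelope maps back to the origin regardless of phase
  z <- phase_to_cartesian(tibble::tibble(Rs = 0, Rd = 0, phi1 = 2, phi2 = -2))
  expect_equal(unlist(z[, c("a1", "b1", "a2", "b2")], use.names = FALSE),
               rep(0, 4))
})

test_that("phase/cartesian round trip is exact over random draws", {
  withr::with_seed(11, {
    cart <- tibble::tibble(
      a1 = stats::rnorm(1000), b1 = stats::rnorm(1000),
      a2 = stats::rnorm(1000), b2 = stats::rnorm(1000)
    )
  })
  back <- phase_to_cartesian(cartesian_to_phase(cart))
  for (col in c("a1", "b1", "a2", "b2")) {
    expect_equal(back[[col]], cart[[col]], tolerance = 1e-12)
  }
  # and the identity a*cos + b*sin = R*sin(. + phi) holds pointwise
  ph <- cartesian_to_phase(cart[1:50, ])
  t <- seq(0, 1, length.out = 7)
  for (i in 1:50) {
    expect_equal(cart$a1[i] * cos(3 * t) + cart$b1[i] * sin(3 * t),
                 ph$Rs[i] * sin(3 * t + ph$phi1[i]), tolerance = 1e-12)
  }
})

test_that("recover_diastolic satisfies both constraints on random tuples", {
  draw <- draw_tuples(1000, seed = 23)
  rec <- recover_diastolic(draw$omega1_hat, draw$omega2_hat, draw$Rs_hat,
                           draw$phi1_hat, draw$T0_hat, strict = FALSE)
  ok <- !rec$degenerate
  expect_gt(mean(ok), 0.95)
  p <- if_params(draw$omega1_hat[ok], draw$omega2_hat[ok], draw$Rs_hat[ok],
                 draw$phi1_hat[ok], draw$c_hat[ok], draw$T0_hat[ok],
                 phi2_hat = rec$phi2_hat[ok], Rd_hat = rec$Rd_hat[ok])
  res <- constraint_residuals(p)
  expect_lt(max(abs(res$continuity)), 1e-9)
  expect_lt(max(abs(res$periodicity)), 1e-9)
  expect_true(all(p$Rd_hat >= 0))
  expect_true(all(p$phi2_hat > -pi & p$phi2_hat <= pi))
})

test_that("equal frequencies and phases reduce to a single sinusoid", {
  rec <- recover_diastolic(2 * pi, 2 * pi, 1, -0.5, 0.37)
  # the recovered diastole must coincide with the systolic sinusoid up to
  # the (R, phi) ~ (-R, phi + pi) identification
  same <- (abs(rec$Rd_hat - 1) < 1e-9 &&
             abs(wrap_err(rec$phi2_hat, -0.5)) < 1e-9)
  flipped <- (abs(rec$Rd_hat - 1) < 1e-9 &&
                abs(wrap_err(rec$phi2_hat, -0.5 + pi)) < 1e-9)
  expect_true(same || flipped)
  p <- if_params(2 * pi, 2 * pi, 1, -0.5, 0.5, 0.37,
                 phi2_hat = rec$phi2_hat, Rd_hat = rec$Rd_hat)
  res <- constraint_residuals(p)
  expect_lt(abs(res$continuity), 1e-9)
  expect_lt(abs(res$periodicity), 1e-9)
})

test_that("degenerate diastolic geometry is flagged or raised", {
  # zero systolic envelope: flat diastole by convention
  rec <- recover_diastolic(8, 5, 0, -0.5, 0.4)
  expect_equal(c(rec$phi2_hat, rec$Rd_hat), c(0, 0))

  # sin(phi1) = 0 with a nonzero continuity requirement has no solution
  expect_error(
    recover_diastolic(8, 5, 0.5, phi1_hat = 0, T0_hat = 0.37),
    class = "ifpulse_degenerate"
  )
  flagged <- recover_diastolic(8, 5, 0.5, 0, 0.37, strict = FALSE)
  expect_true(flagged$degenerate)
  expect_true(is.na(flagged$Rd_hat))
})

test_that("constraint residuals react to perturbations and vanish for flat sets", {
  p <- if_params(8, 5, 0.4, -0.6, 0.4, 0.37)
  base <- constraint_residuals(p)
  expect_lt(max(abs(unlist(base))), 1e-9)
  bump <- p
  bump$phi2_hat <- bump$phi2_hat + 0.1
  expect_gt(abs(constraint_residuals(bump)$continuity), 1e-3)

  flat <- p
  flat$Rs_hat <- 0
  flat$Rd_hat <- 0
  expect_equal(unlist(constraint_residuals(flat), use.names = FALSE), c(0, 0))
})

test_that("reconstruction follows the piecewise formula and is continuous", {
  flat <- if_params(8, 5, 0, -0.6, 0.42, 0.37, phi2_hat = 0, Rd_hat = 0)
  expect_equal(reconstruct(flat), rep(0.42, 500))

  p <- if_params(8, 5, 0.4, -0.6, 0.4, 0.37)
  w <- reconstruct(p)
  expect_equal(w[1], p$c_hat + p$Rs_hat * sin(p$phi1_hat))

  # off-grid continuity at the notch and periodicity at the cycle ends
  eps <- 1e-9
  at <- if_eval(p, c(p$T0_hat - eps, p$T0_hat + eps, 0, 1))
  expect_lt(abs(at[1] - at[2]), 1e-7)
  expect_lt(abs(at[3] - at[4]), 1e-8)

  # phase shifts by 2*pi change nothing
  shifted <- p
  shifted$phi1_hat <- shifted$phi1_hat + 2 * pi
  expect_equal(reconstruct(shifted), w, tolerance = 1e-12)
})

test_that("parameter scaling matches the standard-form relations exactly", {
  u <- tibble::tibble(omega1 = 10, omega2 = 6, Rs = 20, Rd = 10,
                      phi1 = -0.5, phi2 = 0.2, c = 90, T0 = 0.3)
  s <- normalize_parameters(u, Pmin = 50, Pmax = 130, T = 0.8)
  expect_equal(s$omega1_hat, 8)
  expect_equal(s$c_hat, 0.5)
  expect_equal(s$Rs_hat, 0.25)
  expect_equal(s$T0_hat, 0.375)
  expect_equal(s$phi1_hat, u$phi1)
  expect_equal(s$ER_hat, 2)

  ident <- normalize_parameters(u, Pmin = 0, Pmax = 1, T = 1)
  expect_equal(ident$omega1_hat, u$omega1)
  expect_equal(ident$c_hat, u$c)

  expect_error(normalize_parameters(u, 1, 1, 1), class = "ifpulse_invalid_input")
  expect_error(denormalize_parameters(s, 0, 1, -1), class = "ifpulse_invalid_input")
})

test_that("normalize/denormalize form an exact bijection on random draws", {
  withr::with_seed(31, {
    u <- tibble::tibble(
      omega1 = stats::runif(1000, 1, 300), omega2 = stats::runif(1000, 1, 300),
      Rs = stats::runif(1000, 0, 50), Rd = stats::runif(1000, 0, 50),
      phi1 = stats::runif(1000, -pi, pi), phi2 = stats::runif(1000, -pi, pi),
      c = stats::runif(1000, 40, 150), T0 = stats::runif(1000, 0.1, 0.6)
    )
  })
  back <- denormalize_parameters(
    normalize_parameters(u, Pmin = 48.5, Pmax = 131.2, T = 0.84),
    Pmin = 48.5, Pmax = 131.2, T = 0.84
  )
  for (col in names(u)) {
    expect_equal(back[[col]], u[[col]], tolerance = 1e-12)
  }
})
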