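test_that("rmse matches its definition and a brute-force recomputation", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 0), c(1, 1)), 1)
  withr::with_seed(101, {
    p <- stats::rnorm(500)
    t <- stats::rnorm(500)
  })
  brute <- sqrt(sum((p - t)^2) / 500)
  expect_equal(rmse(p, t), brute, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), class = "ifpulse_invalid_input")
})

test_that("ensemble relative error is RMSE over mean magnitude, in percent", {
  expect_equal(ensemble_relative_error(c(1, 2), c(1, 2)), 0)
  withr::with_seed(102, {
    t <- stats::runif(200, 60, 143)
    p <- t + stats::rnorm(200, 0, 0.63)
  })
  expect_equal(ensemble_relative_error(p, t),
               100 * rmse(p, t) / mean(abs(t)), tolerance = 1e-12)
  # invariant under common positive rescaling
  expect_equal(ensemble_relative_error(3.7 * p, 3.7 * t),
               ensemble_relative_error(p, t), tolerance = 1e-12)
  # consistency back-check of the definition: an ensemble with RMSE 0.63
  # and mean magnitude ~88.7 pairs with ~0.71%
  expect_equal(100 * 0.63 / 88.7, 0.71, tolerance = 0.01)
  expect_error(ensemble_relative_error(c(1, -1), c(0, 0)),
               class = "ifpulse_invalid_input")
})

test_that("pointwise relative error averages per-sample errors", {
  t <- c(2, 4, 8)
  expect_equal(as.numeric(pointwise_relative_error(1.1 * t, t)), 10,
               tolerance = 1e-12)
  withr::with_seed(103, {
    t2 <- stats::runif(300, 1, 5)
    p2 <- t2 + stats::rnorm(300, 0, 0.2)
  })
  brute <- 100 * sum(abs(p2 - t2) / abs(t2)) / 300
  expect_equal(as.numeric(pointwise_relative_error(p2, t2)), brute,
               tolerance = 1e-12)
  expect_equal(as.numeric(pointwise_relative_error(2 * p2, 2 * t2)),
               as.numeric(pointwise_relative_error(p2, t2)),
               tolerance = 1e-12)
  # zero-truth samples are excluded, with the count reported
  expect_warning(out <- pointwise_relative_error(c(1, 1.1), c(0, 1)),
                 "zero truth")
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(as.numeric(out), 10, tolerance = 1e-9)
})

test_that("pearson matches the reference implementation and its null", {
  withr::with_seed(104, {
    t <- stats::rnorm(100)
    p <- 0.8 * t + stats::rnorm(100, 0, 0.5)
  })
  ours <- pearson(p, t)
  ref <- stats::cor.test(p, t)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  expect_equal(pearson(1:10, 2 * (1:10) + 3)$r, 1)

  withr::with_seed(105, {
    a <- stats::rnorm(1e4)
    b <- stats::rnorm(1e4)
  })
  expect_lt(abs(pearson(a, b)$r), 0.05)
  expect_error(pearson(rep(1, 5), 1:5), class = "ifpulse_invalid_input")
})

test_that("Bland-Altman bias and limits match the closed form", {
  expect_equal(unlist(bland_altman(c(1, 2, 3), c(1, 2, 3))),
               c(bias = 0, loa_lower = 0, loa_upper = 0))
  ba <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(unlist(ba), c(bias = 1, loa_lower = 1, loa_upper = 1))

  # Monte-Carlo check against the normal closed form
  withr::with_seed(106, d <- stats::rnorm(1e5, 0.5, 1))
  ba2 <- bland_altman(d, rep(0, 1e5))
  expect_equal(ba2$bias, 0.5, tolerance = 0.02)
  expect_equal(ba2$loa_lower, 0.5 - 1.96, tolerance = 0.02)
  expect_equal(ba2$loa_upper, 0.5 + 1.96, tolerance = 0.02)

  # brute-force recomputation on arbitrary draws
  withr::with_seed(107, {
    p <- stats::rnorm(50)
    t <- stats::rnorm(50)
  })
  ba3 <- bland_altman(p, t)
  m <- mean(p - t)
  s <- sqrt(sum((p - t - m)^2) / 49)
  expect_equal(ba3$bias, m, tolerance = 1e-12)
  expect_equal(ba3$loa_upper, m + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba3$loa_upper - ba3$bias, ba3$bias - ba3$loa_lower,
               tolerance = 1e-12)
})

test_that("error histograms cover [0, max error] and count every sample", {
  withr::with_seed(108, {
    p <- stats::rnorm(400)
    t <- stats::rnorm(400)
  })
  h <- error_histogram(p, t, bins = 30)
  expect_equal(nrow(h), 30)
  expect_equal(sum(h$count), 400)
  expect_equal(h$lower[1], 0)
  expect_equal(h$upper[30], max(abs(p - t)))
})

test_that("agreement reports aggregate all statistics per parameter", {
  truth <- sample_parameters(parameter_ranges("table3"), 150, seed = 109)
  withr::with_seed(110, {
    pred <- truth
    for (col in c("omega1_hat", "omega2_hat", "Rs_hat", "phi1_hat", "c_hat")) {
      pred[[col]] <- pred[[col]] +
        stats::rnorm(150, 0, 0.02 * stats::sd(pred[[col]]))
    }
  })
  rep <- agreement_report(pred, truth)
  expect_equal(rep$parameter,
               c("omega1_hat", "omega2_hat", "Rs_hat", "phi1_hat", "c_hat"))
  expect_true(all(rep$rmse >= 0))
  expect_true(all(rep$pearson_r > 0.99))
  expect_equal(rep$rmse[1], rmse(pred$omega1_hat, truth$omega1_hat))
  expect_equal(rep$loa_upper - rep$bias, rep$bias - rep$loa_lower,
               tolerance = 1e-12)
  hist <- attr(rep, "histograms")
  expect_equal(sum(hist$omega1_hat$count), 150)

  for (type in c("regression", "bland_altman", "histogram")) {
    expect_s3_class(autoplot(rep, type = type), "ggplot")
  }
})

test_that("the sensitivity curve uses nested subsets and a fixed validation set", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 300, seed = 111)
  va <- generate_dataset(rg, 80, seed = 112)
  cfg <- fnn_config(hidden_layers = 2, first_width = 32, epochs = 40,
                    restarts = 1, patience = 40, seed = 13)
  tab <- sensitivity_curve(tr, va, cfg, fractions = c(0.2, 0.6, 1), seed = 3)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$fraction, c(0.2, 0.6, 1))
  expect_equal(tab$n_train, c(60, 180, 300))
  expect_true(all(is.finite(tab$val_mse)))

  # fraction 1.0 reproduces the baseline training run
  base <- fnn_train(cfg, tr, va)
  expect_equal(tab$val_mse[3], base$val_mse, tolerance = 1e-12)

  # expected trend: more data does not hurt, on average over seeds
  vals <- sapply(1:3, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- s
    t <- sensitivity_curve(tr, va, cfg_s, fractions = c(0.2, 1), seed = s)
    diff(t$val_mse) # val_mse(1.0) - val_mse(0.2)
  })
  expect_lt(mean(vals), 0)
  expect_s3_class(autoplot(tab), "ggplot")
  expect_error(sensitivity_curve(tr, va, cfg, fractions = c(0, 1)),
               class = "ifpulse_invalid_input")
})
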