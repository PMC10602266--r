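test_that("configuration enforces the halved-width architecture", {
  cfg <- fnn_config(hidden_layers = 4, first_width = 256)
  expect_equal(cfg$widths, c(256L, 128L, 64L, 32L))
  expect_error(fnn_config(hidden_layers = 4, first_width = 100),
               class = "ifpulse_invalid_input")
  expect_equal(fnn_config(hidden_layers = 3, first_width = 128)$widths,
               c(128L, 64L, 32L))
})

test_that("feature scaling standardizes and inverts exactly", {
  withr::with_seed(3, y <- matrix(stats::rnorm(500, c(5, -2), c(2, 0.3)),
                                  250, 2, byrow = TRUE))
  sc <- fit_feature_scaler(y)
  z <- scale_targets(sc, y)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, stats::sd), c(1, 1), tolerance = 1e-12)
  expect_equal(unscale_targets(sc, z), y, tolerance = 1e-12)
  expect_error(fit_feature_scaler(cbind(y[, 1], 3)),
               class = "ifpulse_invalid_input")
})

test_that("the forward pass matches a hand-computed toy network", {
  cfg <- fnn_config(hidden_layers = 1, first_width = 2, restarts = 1,
                    input_width = 3, output_width = 1)
  model <- structure(
    list(weights = list(rbind(c(1, -1), c(2, 0.5), c(-0.5, 0.3)),
                        matrix(c(2, -1), 2, 1)),
         biases = list(c(0.1, -0.2), 0.5),
         scaler = NULL, config = cfg),
    class = "if_surrogate"
  )
  x <- c(0.5, -1, 2)
  # explicit scalar arithmetic, independent of the package's matrix code
  z1 <- 0.5 * 1 + (-1) * 2 + 2 * (-0.5) + 0.1
  z2 <- 0.5 * (-1) + (-1) * 0.5 + 2 * 0.3 - 0.2
  a1 <- z1 / (1 + exp(-z1))
  a2 <- z2 / (1 + exp(-z2))
  expected <- 2 * a1 - 1 * a2 + 0.5
  expect_equal(drop(fnn_forward(model, x)), expected, tolerance = 1e-12)

  # zero weights and biases propagate to a zero output (Swish(0) = 0)
  zero <- model
  zero$weights <- lapply(model$weights, function(w) w * 0)
  zero$biases <- lapply(model$biases, function(b) b * 0)
  expect_equal(drop(fnn_forward(zero, x)), 0)

  expect_error(fnn_forward(model, c(1, 2)), class = "ifpulse_invalid_input")
})

test_that("training learns a constant target to high accuracy", {
  tr <- constant_target_set(300, 8, seed = 51)
  va <- constant_target_set(80, 8, seed = 52)
  cfg <- fnn_config(hidden_layers = 2, first_width = 16, lambda = 0,
                    epochs = 150, batch_size = 32, restarts = 1,
                    patience = 150, seed = 4, input_width = 8,
                    output_width = 2)
  fit <- fnn_train(cfg, tr, va)
  pred <- unscale_targets(fit$scaler, fnn_forward(fit, va$x))
  expect_lt(mean((pred - va$y)^2), 1e-4)

  # descent sanity on the recorded history
  h <- tidy(fit)
  expect_lte(min(h$val_mse), h$val_mse[1])
})

test_that("a small network learns the IF map on a small synthetic set", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 500, seed = 61)
  va <- generate_dataset(rg, 120, seed = 62)
  cfg <- fnn_config(hidden_layers = 3, first_width = 64, reg = "L2",
                    lambda = 1e-6, epochs = 200, restarts = 1,
                    patience = 200, seed = 7)
  fit <- fnn_train(cfg, tr, va)
  expect_lt(fit$val_mse, 0.1)

  # restart determinism: the same master seed reproduces the model exactly
  fit2 <- fnn_train(cfg, tr, va)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$val_mse, fit2$val_mse)

  # predictions are full parameter sets satisfying both constraints
  pred <- predict(fit, va)
  expect_equal(nrow(pred), 120)
  ok <- !is.na(pred$Rd_hat)
  res <- constraint_residuals(pred[ok, ])
  expect_lt(max(abs(unlist(res))), 1e-9)
  expect_identical(pred, predict_full(fit, va))
})

test_that("L1 regularization trains and penalizes weights", {
  tr <- constant_target_set(200, 6, seed = 53)
  va <- constant_target_set(50, 6, seed = 54)
  cfg <- fnn_config(hidden_layers = 1, first_width = 8, reg = "L1",
                    lambda = 1e-3, epochs = 60, restarts = 1, patience = 60,
                    seed = 5, input_width = 6, output_width = 2)
  fit <- fnn_train(cfg, tr, va)
  expect_true(is.finite(fit$val_mse))
})

test_that("grid search selects the validation argmin and keeps the table", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 200, seed = 71)
  va <- generate_dataset(rg, 60, seed = 72)
  base <- fnn_config(epochs = 25, restarts = 1, patience = 25, seed = 9)

  single <- fnn_grid_search(
    tr, va, grid = data.frame(hidden_layers = 3, first_width = 128,
                              reg = "L2", lambda = 1e-6),
    base_config = base)
  expect_equal(nrow(single$table), 1)
  direct <- fnn_train(fnn_config(hidden_layers = 3, first_width = 128,
                                 reg = "L2", lambda = 1e-6, epochs = 25,
                                 restarts = 1, patience = 25, seed = 9),
                      tr, va)
  expect_equal(single$model$val_mse, direct$val_mse)

  grid <- expand.grid(hidden_layers = c(2, 3), first_width = c(16, 32),
                      reg = "L2", lambda = c(1e-5, 1e-6),
                      stringsAsFactors = FALSE)
  res <- fnn_grid_search(tr, va, grid = grid, base_config = base)
  expect_equal(nrow(res$table), nrow(grid))
  expect_true(all(is.finite(res$table$val_mse)))
  expect_equal(res$model$val_mse, min(res$table$val_mse))
})

test_that("surrogates persist to text files and reload identically", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 150, seed = 81)
  va <- generate_dataset(rg, 40, seed = 82)
  cfg <- fnn_config(hidden_layers = 2, first_width = 32, epochs = 20,
                    restarts = 1, patience = 20, seed = 10)
  fit <- fnn_train(cfg, tr, va)
  dir <- withr::local_tempdir()
  write_surrogate(fit, dir)
  back <- read_surrogate(dir)
  x <- surrogate_inputs_for_test(va)
  expect_equal(fnn_forward(back, x), fnn_forward(fit, x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$scaler$mean, fit$scaler$mean,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("batch prediction over thousands of waveforms is fast", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 200, seed = 91)
  va <- generate_dataset(rg, 50, seed = 92)
  cfg <- fnn_config(hidden_layers = 4, first_width = 256, epochs = 3,
                    restarts = 1, patience = 3, seed = 11)
  fit <- fnn_train(cfg, tr, va)
  big <- generate_dataset(rg, 3009, seed = 93)
  elapsed <- system.time(pred <- predict(fit, big))["elapsed"]
  expect_equal(nrow(pred), 3009)
  expect_lt(elapsed, 10)
})

test_that("empty sets and mismatched dimensions fail loudly", {
  rg <- parameter_ranges("table3")
  tr <- generate_dataset(rg, 30, seed = 95)
  cfg <- fnn_config(hidden_layers = 2, first_width = 16, epochs = 5,
                    restarts = 1, seed = 12)
  empty <- list(x = tr$waveforms[0, ], y = as.matrix(tr$params[0, 1:5]))
  expect_error(fnn_train(cfg, empty, empty), class = "ifpulse_training_failure")
  bad <- list(x = tr$waveforms, y = as.matrix(tr$params[, 1:5]))
  expect_error(fnn_train(cfg, bad, bad), class = "ifpulse_invalid_input")
})
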