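#' Configuration of the sequentially-reduced feedforward surrogate
#'
#' The surrogate is a feedforward network whose hidden-layer widths halve
#' layer by layer (`W_l = W1 / 2^(l-1)`), mapping the 501-dimensional input
#' `[notch fraction, 500 waveform samples]` to the five scaled IF outputs
#' `(omega1_hat, omega2_hat, Rs_hat, phi1_hat, c_hat)`. Hidden layers use
#' the Swish activation `x * sigmoid(x)`; the output layer is affine. The
#' loss is the mean squared error on feature-scaled targets plus an L1 or
#' L2 penalty on the weights (biases are not penalized), minimized with the
#' Adam optimizer on shuffled mini-batches. Training restarts several times
#' from fresh random initializations (re-initializing weights and
#' re-shuffling data) and keeps the restart with the lowest validation MSE.
#'
#' @param hidden_layers Number of hidden layers `L`.
#' @param first_width Width `W1` of the first hidden layer; must be
#'   divisible by `2^(L-1)` so every halved width is an integer.
#' @param reg Weight-regularization type, `"L2"` or `"L1"`.
#' @param lambda Regularization coefficient.
#' @param learning_rate Adam learning rate.
#' @param epochs Maximum training epochs per restart.
#' @param batch_size Mini-batch size.
#' @param restarts Number of random restarts.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); the best-epoch weights are restored.
#' @param seed Master seed; each restart derives its own seed from it.
#' @param input_width,output_width Layer sizes at the two ends (501 and 5
#'   for the standard waveform contract; overridable for toy networks).
#'
#' @return A list of class `fnn_config` with a `widths` element.
#' @export
fnn_config <- function(hidden_layers = 4, first_width = 256,
                       reg = c("L2", "L1"), lambda = 1e-6,
                       learning_rate = 1e-3, epochs = 500, batch_size = 64,
                       restarts = 10, patience = 50, seed = 1,
                       input_width = 501, output_width = 5) {
  reg <- match.arg(reg)
  L <- as.integer(hidden_layers)
  if (L < 1) stop_invalid("`hidden_layers` must be at least 1.")
  if (first_width %% 2^(L - 1) != 0) {
    stop_invalid("`first_width` must be divisible by 2^(hidden_layers - 1).")
  }
  widths <- as.integer(first_width / 2^(seq_len(L) - 1))
  structure(
    list(hidden_layers = L, first_width = as.integer(first_width),
         widths = widths, reg = reg, lambda = lambda,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), restarts = as.integer(restarts),
         patience = as.integer(patience), seed = seed,
         input_width = as.integer(input_width),
         output_width = as.integer(output_width)),
    class = "fnn_config"
  )
}

#' Per-output feature scaling
#'
#' Network targets are standardized per output, `(y - mean)/sd`, with the
#' statistics computed on the training targets only, and inverted at
#' prediction time. `fit_feature_scaler()` errors when any output is
#' constant (`sd = 0`).
#'
#' @param y Numeric target matrix (rows = records).
#' @param scaler A scaler from `fit_feature_scaler()`.
#' @return `fit_feature_scaler()`: a list with `mean` and `sd` vectors;
#'   `scale_targets()`/`unscale_targets()`: a matrix like `y`.
#' @export
fit_feature_scaler <- function(y) {
  y <- as.matrix(y)
  mu <- colMeans(y)
  sd <- apply(y, 2, stats::sd)
  if (any(sd <= 0)) stop_invalid("Feature scaling needs sd > 0 for every output.")
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @export
scale_targets <- function(scaler, y) {
  y <- as.matrix(y)
  sweep(sweep(y, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' @rdname fit_feature_scaler
#' @export
unscale_targets <- function(scaler, y) {
  y <- as.matrix(y)
  sweep(sweep(y, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

swish_ <- function(z) z * stats::plogis(z)
dswish_ <- function(z) {
  s <- stats::plogis(z)
  s * (1 + z * (1 - s))
}

add_bias_ <- function(z, b) z + rep(b, each = nrow(z))

# Glorot-uniform initialization for one restart.
init_layers_ <- function(dims) {
  L1 <- length(dims) - 1
  weights <- vector("list", L1)
  biases <- vector("list", L1)
  for (l in seq_len(L1)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))
    weights[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                           dims[l], dims[l + 1])
    biases[[l]] <- numeric(dims[l + 1])
  }
  list(weights = weights, biases = biases)
}

forward_pass_ <- function(weights, biases, x) {
  n_layer <- length(weights)
  a <- x
  for (l in seq_len(n_layer - 1)) {
    a <- swish_(add_bias_(a %*% weights[[l]], biases[[l]]))
  }
  add_bias_(a %*% weights[[n_layer]], biases[[n_layer]])
}

#' Forward pass of a trained surrogate
#'
#' Propagates one input vector (or a matrix of rows) through the network:
#' affine-then-Swish through the hidden layers, affine at the output. The
#' result is in feature-scaled output space; use [predict()] for unscaled,
#' constraint-completed IF parameters.
#'
#' @param model A trained surrogate from [fnn_train()].
#' @param input A numeric vector of length `input_width` (501 under the
#'   standard contract: notch fraction then the 500 waveform samples) or a
#'   matrix with that many columns.
#' @return A numeric matrix of feature-scaled outputs, one row per input.
#' @export
fnn_forward <- function(model, input) {
  if (is.vector(input)) input <- matrix(input, nrow = 1)
  input <- as.matrix(input)
  if (ncol(input) != model$config$input_width) {
    stop_invalid(sprintf("Input must have %d columns, got %d.",
                         model$config$input_width, ncol(input)))
  }
  forward_pass_(model$weights, model$biases, input)
}

# One restart: Adam on shuffled mini-batches with early stopping.
# Returns weights/biases at the best validation epoch plus the history.
train_restart_ <- function(config, xtr, ytr, xval, yval, restart_seed) {
  dims <- c(config$input_width, config$widths, config$output_width)
  n <- nrow(xtr)
  n_layer <- length(dims) - 1
  lam <- config$lambda
  l2 <- config$reg == "L2"
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7

  set.seed(restart_seed)
  st <- init_layers_(dims)
  W <- st$weights; bb <- st$biases
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(bb, function(b) b * 0); vB <- mB
  step <- 0

  best_val <- Inf; best_W <- W; best_b <- bb; wait <- 0
  hist_train <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      xb <- xtr[idx, , drop = FALSE]
      yb <- ytr[idx, , drop = FALSE]
      bsz <- length(idx)

      # forward, caching pre-activations
      zs <- vector("list", n_layer); as <- vector("list", n_layer + 1)
      as[[1]] <- xb
      for (l in seq_len(n_layer - 1)) {
        zs[[l]] <- add_bias_(as[[l]] %*% W[[l]], bb[[l]])
        as[[l + 1]] <- swish_(zs[[l]])
      }
      yhat <- add_bias_(as[[n_layer]] %*% W[[n_layer]], bb[[n_layer]])

      err <- yhat - yb
      epoch_loss <- epoch_loss + sum(err^2)
      delta <- 2 * err / (bsz * ncol(yb))

      # backward
      gW <- vector("list", n_layer); gB <- vector("list", n_layer)
      for (l in n_layer:1) {
        gW[[l]] <- crossprod(as[[l]], delta)
        gB[[l]] <- colSums(delta)
        if (lam > 0) {
          gW[[l]] <- gW[[l]] +
            if (l2) 2 * lam * W[[l]] else lam * sign(W[[l]])
        }
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * dswish_(zs[[l - 1]])
        }
      }

      # Adam update
      step <- step + 1
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (l in seq_len(n_layer)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB[[l]]
        vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB[[l]]^2
        bb[[l]] <- bb[[l]] - lr * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + eps)
      }
    }

    train_mse <- epoch_loss / (n * ncol(ytr))
    val_mse <- mean((forward_pass_(W, bb, xval) - yval)^2)
    if (!is.finite(train_mse) || !is.finite(val_mse)) {
      abort(sprintf("Non-finite loss at epoch %d (restart seed %s).",
                    epoch, format(restart_seed)),
            class = "ifpulse_training_failure")
    }
    hist_train <- c(hist_train, train_mse)
    hist_val <- c(hist_val, val_mse)

    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse; best_W <- W; best_b <- bb; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }

  list(weights = best_W, biases = best_b, val_mse = best_val,
       history = tibble(epoch = seq_along(hist_train),
                        train_loss = hist_train, val_mse = hist_val))
}

#' Train the feedforward IF surrogate
#'
#' Trains the network described by `config` on feature-scaled targets (the
#' scaler is fitted on the training targets only), restarting
#' `config$restarts` times from fresh seeded initializations and returning
#' the restart with the lowest validation MSE. Training minimizes
#' `MSE + lambda * penalty(weights)` by Adam on shuffled mini-batches, with
#' early stopping on the validation MSE (best-epoch weights restored).
#'
#' @param config An [fnn_config()].
#' @param train,validation Training and validation data: [generate_dataset()]
#'   objects, or lists with elements `x` (inputs, rows = records) and `y`
#'   (targets).
#'
#' @return An object of class `if_surrogate`: weights, biases, the feature
#'   scaler, the config, per-restart summaries, and per-epoch loss
#'   histories. Supports [predict()], [generics::tidy()],
#'   [generics::glance()].
#' @export
fnn_train <- function(config, train, validation) {
  if (!inherits(config, "fnn_config")) {
    stop_invalid("`config` must be created by fnn_config().")
  }
  tr <- surrogate_inputs(train)
  va <- surrogate_inputs(validation)
  if (nrow(tr$x) == 0 || nrow(va$x) == 0) {
    abort("Training and validation sets must be nonempty.",
          class = "ifpulse_training_failure")
  }
  if (ncol(tr$x) != config$input_width || ncol(tr$y) != config$output_width) {
    stop_invalid("Data dimensions do not match the network configuration.")
  }
  scaler <- fit_feature_scaler(tr$y)
  ytr <- scale_targets(scaler, tr$y)
  yva <- scale_targets(scaler, va$y)

  runs <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    runs[[r]] <- train_restart_(config, tr$x, ytr, va$x, yva,
                                restart_seed = derive_seed(config$seed, r))
  }
  vals <- vapply(runs, `[[`, numeric(1), "val_mse")
  best <- which.min(vals)
  history <- dplyr::bind_rows(
    lapply(seq_along(runs), function(r) {
      h <- runs[[r]]$history
      h$restart <- r
      h
    })
  )
  structure(
    list(weights = runs[[best]]$weights, biases = runs[[best]]$biases,
         scaler = scaler, config = config, history = history,
         restart_summary = tibble(restart = seq_along(vals), val_mse = vals),
         best_restart = best, val_mse = vals[best]),
    class = "if_surrogate"
  )
}

#' Hyperparameter grid search for the surrogate
#'
#' Enumerates a grid of (hidden layers, first width, regularization type,
#' regularization coefficient) combinations, trains each with [fnn_train()],
#' and returns the configuration with the smallest validation MSE together
#' with the full search table. The default grid is the full 54-combination
#' design space `L in {3,4,5} x W1 in {128,256,512} x {L1,L2} x
#' lambda in {1e-5,1e-6,1e-7}`; pass a subset data frame to restrict it.
#'
#' @inheritParams fnn_train
#' @param grid A data frame with columns `hidden_layers`, `first_width`,
#'   `reg`, `lambda`; defaults to the full design grid.
#' @param base_config An [fnn_config()] supplying all remaining settings.
#'
#' @return A list of class `if_grid_search` with `model` (best
#'   `if_surrogate`) and `table` (one row per combination, with validation
#'   MSE).
#' @export
fnn_grid_search <- function(train, validation, grid = NULL,
                            base_config = fnn_config()) {
  if (is.null(grid)) {
    grid <- expand.grid(hidden_layers = c(3, 4, 5),
                        first_width = c(128, 256, 512),
                        reg = c("L1", "L2"),
                        lambda = c(1e-5, 1e-6, 1e-7),
                        stringsAsFactors = FALSE)
  }
  grid <- as_tibble(grid)
  models <- vector("list", nrow(grid))
  val <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- fnn_config(
      hidden_layers = grid$hidden_layers[i], first_width = grid$first_width[i],
      reg = as.character(grid$reg[i]), lambda = grid$lambda[i],
      learning_rate = base_config$learning_rate, epochs = base_config$epochs,
      batch_size = base_config$batch_size, restarts = base_config$restarts,
      patience = base_config$patience, seed = base_config$seed,
      input_width = base_config$input_width,
      output_width = base_config$output_width
    )
    models[[i]] <- fnn_train(cfg, train, validation)
    val[i] <- models[[i]]$val_mse
  }
  grid$val_mse <- val
  best <- which.min(val)
  structure(list(model = models[[best]], table = grid, best = best),
            class = "if_grid_search")
}

#' Predict full IF parameter sets with the surrogate
#'
#' Runs the forward pass, inverts the feature scaling to obtain the five
#' scaled outputs `(omega1_hat, omega2_hat, Rs_hat, phi1_hat, c_hat)`, and
#' completes each record analytically with [recover_diastolic()] using the
#' notch fraction carried by the input, so every prediction satisfies the
#' continuity and periodicity constraints exactly. Records whose predicted
#' parameters hit degenerate diastolic geometry are returned with
#' `phi2_hat`/`Rd_hat` set to `NA` and a warning.
#'
#' @param object A trained `if_surrogate`.
#' @param newdata A [scaled_waveform()], an `if_dataset`, or an input matrix
#'   with `input_width` columns (first column = notch fraction).
#' @param ... Unused.
#' @return A full scaled parameter tibble (see [if_params()]).
#' @export
predict.if_surrogate <- function(object, newdata, ...) {
  if (inherits(newdata, "scaled_waveform")) {
    x <- matrix(c(notch_fraction_of(newdata), newdata$value), nrow = 1)
  } else if (inherits(newdata, "if_dataset")) {
    x <- surrogate_inputs(newdata)$x
  } else {
    x <- as.matrix(newdata)
  }
  out <- unscale_targets(object$scaler, fnn_forward(object, x))
  colnames(out) <- c("omega1_hat", "omega2_hat", "Rs_hat", "phi1_hat", "c_hat")
  p <- as_tibble(out)
  p$T0_hat <- x[, 1]
  rec <- recover_diastolic(p$omega1_hat, p$omega2_hat, p$Rs_hat,
                           p$phi1_hat, p$T0_hat, strict = FALSE)
  if (any(rec$degenerate)) {
    warn(sprintf("%d prediction(s) hit degenerate diastolic geometry; %s",
                 sum(rec$degenerate),
                 "their phi2_hat/Rd_hat are NA."))
  }
  p$phi2_hat <- rec$phi2_hat
  p$Rd_hat <- rec$Rd_hat
  p$ER_hat <- ifelse(!is.na(p$Rd_hat) & p$Rd_hat > 0,
                     p$Rs_hat / p$Rd_hat, NA_real_)
  p[, c("omega1_hat", "omega2_hat", "Rs_hat", "Rd_hat", "phi1_hat",
        "phi2_hat", "c_hat", "T0_hat", "ER_hat")]
}

#' @rdname predict.if_surrogate
#' @param model A trained `if_surrogate` (alias of `object`).
#' @param w Waveform input (alias of `newdata`).
#' @export
predict_full <- function(model, w) {
  predict(model, w)
}

#' @export
print.if_surrogate <- function(x, ...) {
  cat(sprintf(
    "<if_surrogate: %s -> %s -> %d; %s reg lambda = %g; best of %d restarts, val MSE %.4g>\n",
    x$config$input_width, paste(x$config$widths, collapse = "-"),
    x$config$output_width, x$config$reg, x$config$lambda,
    x$config$restarts, x$val_mse))
  invisible(x)
}

#' Tidy methods for trained surrogates
#'
#' `tidy()` returns the per-epoch loss history across restarts; `glance()`
#' a one-row summary of the selected model.
#'
#' @param x An `if_surrogate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.if_surrogate <- function(x, ...) {
  x$history[, c("restart", "epoch", "train_loss", "val_mse")]
}

#' @rdname tidy.if_surrogate
#' @export
glance.if_surrogate <- function(x, ...) {
  tibble(
    hidden_layers = x$config$hidden_layers,
    first_width = x$config$first_width,
    reg = x$config$reg,
    lambda = x$config$lambda,
    restarts = x$config$restarts,
    best_restart = x$best_restart,
    val_mse = x$val_mse,
    n_parameters = sum(vapply(x$weights, length, numeric(1))) +
      sum(vapply(x$biases, length, numeric(1)))
  )
}

#' Save and reload a trained surrogate as plain text
#'
#' The model is written as a JSON manifest (configuration, feature scaler,
#' layer shapes, validation MSE) plus one delimited text file of weights per
#' layer. `read_surrogate()` re-verifies the layer-shape invariants while
#' loading.
#'
#' @param model A trained `if_surrogate`.
#' @param dir Directory to write to / read from.
#' @return `write_surrogate()` returns `dir` invisibly; `read_surrogate()`
#'   an `if_surrogate` (without training history).
#' @export
write_surrogate <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = unclass(model$config),
    scaler = list(mean = model$scaler$mean, sd = model$scaler$sd),
    val_mse = model$val_mse,
    n_layers = length(model$weights),
    shapes = lapply(model$weights, dim)
  )
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_along(model$weights)) {
    utils::write.table(model$weights[[l]],
                       file.path(dir, sprintf("weights_%02d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(matrix(model$biases[[l]], nrow = 1),
                       file.path(dir, sprintf("biases_%02d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "model.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- fnn_config(
    hidden_layers = cfg$hidden_layers, first_width = cfg$first_width,
    reg = cfg$reg, lambda = cfg$lambda, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size, restarts = cfg$restarts,
    patience = cfg$patience, seed = cfg$seed,
    input_width = cfg$input_width, output_width = cfg$output_width
  )
  dims <- c(config$input_width, config$widths, config$output_width)
  weights <- vector("list", manifest$n_layers)
  biases <- vector("list", manifest$n_layers)
  for (l in seq_len(manifest$n_layers)) {
    w <- as.matrix(utils::read.table(
      file.path(dir, sprintf("weights_%02d.tsv", l)), sep = "\t"))
    dimnames(w) <- NULL
    b <- as.numeric(utils::read.table(
      file.path(dir, sprintf("biases_%02d.tsv", l)), sep = "\t"))
    if (!identical(dim(w), c(dims[l], dims[l + 1])) ||
        length(b) != dims[l + 1]) {
      stop_invalid(sprintf("Layer %d has inconsistent shapes on disk.", l))
    }
    weights[[l]] <- w
    biases[[l]] <- b
  }
  structure(
    list(weights = weights, biases = biases,
         scaler = structure(list(mean = manifest$scaler$mean,
                                 sd = manifest$scaler$sd),
                            class = "feature_scaler"),
         config = config, history = NULL, restart_summary = NULL,
         best_restart = NA_integer_, val_mse = manifest$val_mse),
    class = "if_surrogate"
  )
}
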