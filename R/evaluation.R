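#' Agreement statistics between two parameter estimates
#'
#' Scalar metrics comparing a vector of predictions against a reference
#' ("truth") vector of equal length:
#'
#' * `rmse()`: root mean squared error `sqrt(mean((pred - truth)^2))`.
#' * `ensemble_relative_error()`: the RMSE expressed as a percentage of the
#'   ensemble mean magnitude, `100 * rmse / mean(|truth|)`. The published
#'   blind-test tables pair an RMSE with a percentage in exactly this
#'   ratio, but the formula is this package's inference -- it is isolated
#'   here so it can be swapped if a different convention is wanted.
#' * `pointwise_relative_error()`: the mean of per-sample relative absolute
#'   errors, `100 * mean(|pred - truth| / |truth|)`; zero-truth samples are
#'   excluded with a warning and the excluded count is attached as the
#'   `n_excluded` attribute.
#' * `pearson()`: the sample Pearson correlation with a two-sided p-value
#'   from the t transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees
#'   of freedom.
#' * `bland_altman()`: mean difference (bias) and 95% limits of agreement
#'   `bias +/- 1.96 * sd(differences)` (sample standard deviation).
#' * `error_histogram()`: counts of absolute errors in `bins` equal-width
#'   bins over `[0, max |error|]`.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @param bins Number of histogram bins.
#' @return `rmse()` and the relative errors: a single number (percent for
#'   the relative errors). `pearson()`: a list with `r` and `p_value`.
#'   `bland_altman()`: a list with `bias`, `loa_lower`, `loa_upper`.
#'   `error_histogram()`: a tibble of bin edges and counts.
#' @examples
#' rmse(c(1, 2, 3), c(1, 1, 3))
#' bland_altman(c(1.1, 2.2, 2.9), c(1, 2, 3))
#' @export
rmse <- function(pred, truth) {
  check_paired(pred, truth, min_n = 1)
  sqrt(mean((pred - truth)^2))
}

#' @rdname rmse
#' @export
ensemble_relative_error <- function(pred, truth) {
  check_paired(pred, truth, min_n = 1)
  denom <- mean(abs(truth))
  if (denom == 0) stop_invalid("mean(|truth|) is zero; relative error undefined.")
  100 * rmse(pred, truth) / denom
}

#' @rdname rmse
#' @export
pointwise_relative_error <- function(pred, truth) {
  check_paired(pred, truth, min_n = 1)
  nz <- truth != 0
  n_excluded <- sum(!nz)
  if (n_excluded > 0) {
    warn(sprintf("Excluding %d sample(s) with zero truth value.", n_excluded))
  }
  if (!any(nz)) stop_invalid("All truth values are zero.")
  out <- 100 * mean(abs(pred[nz] - truth[nz]) / abs(truth[nz]))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' @rdname rmse
#' @export
pearson <- function(pred, truth) {
  check_paired(pred, truth, min_n = 3)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    stop_invalid("Pearson correlation needs nonzero variance in both vectors.")
  }
  n <- length(pred)
  r <- sum((pred - mean(pred)) * (truth - mean(truth))) /
    ((n - 1) * stats::sd(pred) * stats::sd(truth))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p_value = p)
}

#' @rdname rmse
#' @export
bland_altman <- function(pred, truth) {
  check_paired(pred, truth, min_n = 2)
  d <- pred - truth
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}

#' @rdname rmse
#' @export
error_histogram <- function(pred, truth, bins = 30) {
  check_paired(pred, truth, min_n = 1)
  err <- abs(pred - truth)
  edges <- seq(0, max(err), length.out = bins + 1)
  if (max(err) == 0) edges <- seq(0, 1e-12, length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(err, edges, rightmost.closed = TRUE),
                          bins), nbins = bins)
  tibble(lower = edges[-length(edges)], upper = edges[-1], count = counts)
}

check_paired <- function(pred, truth, min_n = 1) {
  if (length(pred) != length(truth)) {
    stop_invalid("`pred` and `truth` must have the same length.")
  }
  if (length(pred) < min_n) {
    stop_invalid(sprintf("At least %d paired values are required.", min_n))
  }
  invisible(NULL)
}

#' Per-parameter agreement report
#'
#' Compares two parameter tables column by column (over their shared
#' numeric columns) and assembles, per parameter: RMSE, ensemble and
#' point-wise relative errors, Pearson correlation with p-value, and
#' Bland--Altman bias with limits of agreement. Per-parameter
#' absolute-error histograms are attached as an attribute, and the paired
#' long-form data are retained for [ggplot2::autoplot()].
#'
#' @param pred,truth Data frames of parameter estimates with matching
#'   columns (e.g. surrogate predictions vs. ground truth or solver
#'   output).
#' @param parameters Columns to compare; defaults to the five network
#'   outputs present in both tables, falling back to all shared numeric
#'   columns.
#' @param bins Histogram bins per parameter.
#' @return A tibble of class `if_agreement`, one row per parameter.
#' @export
agreement_report <- function(pred, truth, parameters = NULL, bins = 30) {
  pred <- as_tibble(pred)
  truth <- as_tibble(truth)
  if (is.null(parameters)) {
    preferred <- c("omega1_hat", "omega2_hat", "Rs_hat", "phi1_hat", "c_hat")
    shared <- intersect(names(pred), names(truth))
    parameters <- intersect(preferred, shared)
    if (length(parameters) == 0) {
      parameters <- shared[vapply(pred[shared], is.numeric, logical(1))]
    }
  }
  if (nrow(pred) != nrow(truth)) {
    stop_invalid("`pred` and `truth` must have the same number of records.")
  }
  rows <- lapply(parameters, function(par) {
    p <- pred[[par]]; t <- truth[[par]]
    pe <- pearson(p, t)
    ba <- bland_altman(p, t)
    tibble(
      parameter = par,
      n = length(p),
      rmse = rmse(p, t),
      ensemble_relative_error = ensemble_relative_error(p, t),
      pointwise_relative_error = suppressWarnings(
        as.numeric(pointwise_relative_error(p, t))),
      pearson_r = pe$r,
      p_value = pe$p_value,
      bias = ba$bias,
      loa_lower = ba$loa_lower,
      loa_upper = ba$loa_upper
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "histograms") <- stats::setNames(
    lapply(parameters, function(par) error_histogram(pred[[par]], truth[[par]], bins)),
    parameters)
  attr(out, "pairs") <- dplyr::bind_rows(lapply(parameters, function(par) {
    tibble(parameter = par, pred = pred[[par]], truth = truth[[par]])
  }))
  class(out) <- c("if_agreement", class(out))
  out
}

#' Training-size sensitivity of the surrogate
#'
#' Re-trains a fixed configuration on nested, seeded subsamples of the
#' training pool (a larger fraction always contains every record of a
#' smaller one) while evaluating against the same validation population,
#' and tabulates final training and validation MSE per fraction.
#'
#' @param train Training pool ([generate_dataset()] object or `x`/`y` list).
#' @param validation Fixed validation set, same formats.
#' @param config An [fnn_config()] used for every fraction.
#' @param fractions Fractions of the training pool to use, in `(0, 1]`.
#' @param seed Seed for the single subsampling permutation.
#' @return A tibble of class `if_sensitivity` with one row per fraction:
#'   `fraction`, `n_train`, `train_mse`, `val_mse`.
#' @export
sensitivity_curve <- function(train, validation, config,
                              fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                              seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop_invalid("`fractions` must lie in (0, 1].")
  }
  tr <- surrogate_inputs(train)
  n <- nrow(tr$x)
  perm <- with_seed_(seed, sample.int(n))
  rows <- lapply(sort(fractions), function(f) {
    # sorted so the full fraction reproduces the baseline run exactly
    take <- sort(perm[seq_len(max(1, floor(f * n)))])
    sub <- list(x = tr$x[take, , drop = FALSE], y = tr$y[take, , drop = FALSE])
    fit <- fnn_train(config, sub, validation)
    final <- fit$history[fit$history$restart == fit$best_restart, ]
    tibble(fraction = f, n_train = length(take),
           train_mse = final$train_loss[which.min(final$val_mse)],
           val_mse = fit$val_mse)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("if_sensitivity", class(out))
  out
}
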