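#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: for an [solve_if()]
#' fit, the waveform with its IF reconstruction and the notch position; for
#' an [agreement_report()], regression, Bland--Altman, or absolute-error
#' histogram panels faceted by parameter; for a [sensitivity_curve()]
#' table, training/validation MSE versus training-set fraction; for a
#' dataset, a spaghetti plot of sampled waveforms.
#'
#' @param object The object to plot.
#' @param type Panel type for agreement reports.
#' @param n_show Number of waveforms to show for a dataset.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ifpulse-autoplot
NULL

#' @rdname ifpulse-autoplot
#' @export
autoplot.if_fit <- function(object, ...) {
  w <- object$waveform
  rec <- tibble(tau = w$tau, value = reconstruct(object$params, n = nrow(w)))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_line(data = rec, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$params$T0_hat,
                        linetype = "dotted", colour = "darkgreen") +
    ggplot2::labs(x = "normalized time", y = "normalized pressure",
                  title = sprintf("IF fit: omega1_hat = %.2f, omega2_hat = %.2f",
                                  object$params$omega1_hat,
                                  object$params$omega2_hat))
}

#' @rdname ifpulse-autoplot
#' @export
autoplot.if_agreement <- function(object,
                                  type = c("regression", "bland_altman",
                                           "histogram"), ...) {
  type <- match.arg(type)
  pairs <- attr(object, "pairs")
  if (type == "regression") {
    ggplot2::ggplot(pairs, ggplot2::aes(x = .data$truth, y = .data$pred)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_abline(linetype = "dotted") +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "reference", y = "prediction")
  } else if (type == "bland_altman") {
    pairs <- dplyr::mutate(pairs,
                           avg = (.data$pred + .data$truth) / 2,
                           diff = .data$pred - .data$truth)
    lines <- tidyr::pivot_longer(
      as_tibble(object)[, c("parameter", "bias", "loa_lower", "loa_upper")],
      cols = -"parameter", values_to = "y")
    ggplot2::ggplot(pairs, ggplot2::aes(x = .data$avg, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$y),
                          colour = "purple") +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "mean of methods", y = "difference")
  } else {
    hist_df <- dplyr::bind_rows(attr(object, "histograms"), .id = "parameter")
    ggplot2::ggplot(hist_df,
                    ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                 y = .data$count)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "absolute error", y = "count")
  }
}

#' @rdname ifpulse-autoplot
#' @export
autoplot.if_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("train_mse", "val_mse"),
                              names_to = "loss", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$mse,
                                     colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "relative training size", y = "MSE")
}

#' @rdname ifpulse-autoplot
#' @export
autoplot.if_dataset <- function(object, n_show = 12, ...) {
  idx <- seq_len(min(n_show, nrow(object$waveforms)))
  df <- dplyr::bind_rows(lapply(idx, function(i) {
    tibble(record = i, tau = seq(0, 1, length.out = ncol(object$waveforms)),
           value = object$waveforms[i, ])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value,
                                   group = .data$record)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "normalized time", y = "normalized pressure")
}
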