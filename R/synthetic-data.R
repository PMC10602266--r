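#' Physiological parameter ranges for the synthetic generator
#'
#' Rectangular sampling intervals for the six free scaled IF parameters
#' `(omega1_hat, omega2_hat, Rs_hat, phi1_hat, c_hat, T0_hat)`, plus
#' validity filters applied to each completed tuple. Two presets carry the
#' published physiological ranges of scaled carotid IF parameters:
#'
#' | preset | omega1_hat | omega2_hat | Rs_hat | phi1_hat | c_hat |
#' |---|---|---|---|---|---|
#' | `"table3"` | 75.0--155.2 | 19.2--71.3 | 0.43--0.89 | -1.269 -- -0.008 | 0.18--0.58 |
#' | `"table2"` | 60.4--143.5 | 26.9--152.3 | 0.49--0.94 | -1.06 -- 0.16 | 0.14--0.51 |
#'
#' No published range exists for the notch fraction; the default
#' `T0_hat` interval `[0.30, 0.45]` is this package's choice of a typical
#' systolic fraction of the cardiac cycle. The `"smooth"` preset uses low
#' radian frequencies (`omega1_hat` 2--20, `omega2_hat` 1--12) for slowly
#' oscillating waveforms.
#'
#' Validity filters: the completed diastolic envelope must satisfy
#' `Rd_hat <= rd_ratio_max * Rs_hat` (the periodicity constraint can
#' otherwise blow the envelope up), all reconstructed values must lie inside
#' `value_band`, and tuples with degenerate diastolic geometry are rejected.
#' Optional linear pairwise constraints (e.g.
#' `list(c(omega1_hat = 1, omega2_hat = -1, rhs = 0))`, read as
#' `1*omega1_hat - 1*omega2_hat >= 0`) can restrict the rectangle further;
#' the default is none.
#'
#' @param preset `"table3"`, `"table2"`, or `"smooth"`.
#' @param T0_hat_range Sampling interval for the notch fraction.
#' @param rd_ratio_max Maximum allowed `Rd_hat / Rs_hat`.
#' @param value_band Allowed band for reconstructed waveform values.
#' @param pairwise Optional list of named coefficient vectors with an `rhs`
#'   entry; each is enforced as `sum(coef * param) >= rhs`.
#' @param ... Named interval overrides (`omega1_hat`, `omega2_hat`,
#'   `Rs_hat`, `phi1_hat`, `c_hat`), each a numeric length-2 vector.
#'
#' @return A list of class `if_ranges` with elements `intervals` (a tibble
#'   of `parameter`, `lower`, `upper`) and the filters.
#' @export
parameter_ranges <- function(preset = c("table3", "table2", "smooth"),
                             T0_hat_range = c(0.30, 0.45),
                             rd_ratio_max = 4,
                             value_band = c(-0.25, 1.25),
                             pairwise = NULL, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    table3 = list(omega1_hat = c(75.0, 155.2), omega2_hat = c(19.2, 71.3),
                  Rs_hat = c(0.43, 0.89), phi1_hat = c(-1.269, -0.008),
                  c_hat = c(0.18, 0.58)),
    table2 = list(omega1_hat = c(60.4, 143.5), omega2_hat = c(26.9, 152.3),
                  Rs_hat = c(0.49, 0.94), phi1_hat = c(-1.06, 0.16),
                  c_hat = c(0.14, 0.51)),
    smooth = list(omega1_hat = c(2, 20), omega2_hat = c(1, 12),
                  Rs_hat = c(0.2, 0.6), phi1_hat = c(-1.2, -0.01),
                  c_hat = c(0.2, 0.6))
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(base)) stop_invalid(sprintf("Unknown parameter `%s`.", nm))
    base[[nm]] <- as.double(overrides[[nm]])
  }
  base$T0_hat <- as.double(T0_hat_range)
  iv <- tibble(
    parameter = names(base),
    lower = vapply(base, `[`, numeric(1), 1),
    upper = vapply(base, `[`, numeric(1), 2)
  )
  if (any(!is.finite(iv$lower)) || any(!is.finite(iv$upper)) ||
      any(iv$upper < iv$lower)) {
    stop_invalid("Every sampling interval must be finite and non-empty.")
  }
  structure(
    list(intervals = iv, rd_ratio_max = rd_ratio_max,
         value_band = as.double(value_band), pairwise = pairwise,
         preset = preset),
    class = "if_ranges"
  )
}

#' Sample valid scaled IF parameter tuples
#'
#' Draws the six free parameters either uniformly at random inside the
#' rectangle (`mode = "random"`) or on a uniform mesh with near-equal points
#' per axis sized so the full mesh has at least `n` nodes
#' (`mode = "mesh"`). Each tuple is completed with [recover_diastolic()]
#' and then passed through the validity filters (non-degenerate geometry,
#' diastolic-envelope ratio, reconstructed-value band, optional pairwise
#' constraints). Random draws are redrawn until `n` valid tuples exist;
#' mesh nodes that fail are dropped. Sampling is fully reproducible for a
#' fixed `seed`.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param n Number of tuples requested.
#' @param mode `"random"` or `"mesh"`.
#' @param seed Integer seed (optional; the caller's RNG stream is never
#'   disturbed).
#' @param max_attempts Maximum number of redraw rounds before an
#'   infeasible-filter error.
#'
#' @return A full scaled parameter tibble (see [if_params()]) with `n` rows
#'   (possibly fewer, with a warning, when a mesh is exhausted).
#' @export
sample_parameters <- function(ranges, n, mode = c("random", "mesh"),
                              seed = NULL, max_attempts = 20) {
  if (!inherits(ranges, "if_ranges")) {
    stop_invalid("`ranges` must be created by parameter_ranges().")
  }
  mode <- match.arg(mode)
  if (n < 1) stop_invalid("`n` must be at least 1.")
  iv <- ranges$intervals
  lo <- stats::setNames(iv$lower, iv$parameter)
  hi <- stats::setNames(iv$upper, iv$parameter)

  complete_and_filter <- function(draw) {
    rec <- recover_diastolic(draw$omega1_hat, draw$omega2_hat, draw$Rs_hat,
                             draw$phi1_hat, draw$T0_hat, strict = FALSE)
    p <- if_params(draw$omega1_hat, draw$omega2_hat, draw$Rs_hat,
                   draw$phi1_hat, draw$c_hat, draw$T0_hat,
                   phi2_hat = ifelse(rec$degenerate, 0, rec$phi2_hat),
                   Rd_hat = ifelse(rec$degenerate, 0, rec$Rd_hat))
    keep <- !rec$degenerate &
      p$Rd_hat <= ranges$rd_ratio_max * p$Rs_hat
    if (!is.null(ranges$pairwise)) {
      for (pc in ranges$pairwise) {
        rhs <- pc[["rhs"]]
        coefs <- pc[setdiff(names(pc), "rhs")]
        lhs <- rep(0, nrow(p))
        for (nm in names(coefs)) lhs <- lhs + coefs[[nm]] * p[[nm]]
        keep <- keep & (lhs >= rhs)
      }
    }
    if (any(keep)) {
      vals <- if_eval(p[keep, , drop = FALSE], seq(0, 1, length.out = 500))
      vals <- matrix(vals, nrow = sum(keep))
      in_band <- apply(vals, 1, function(v) {
        min(v) >= ranges$value_band[1] && max(v) <= ranges$value_band[2]
      })
      keep[keep] <- in_band
    }
    p[keep, , drop = FALSE]
  }

  with_seed_(seed, {
    if (mode == "random") {
      out <- NULL
      acc <- 0.5 # running acceptance-rate estimate, drives oversampling
      for (attempt in seq_len(max_attempts)) {
        m <- max(n - sum(NROW(out)), 1)
        n_draw <- min(ceiling(m / acc * 1.2) + 8, 200000)
        draw <- as_tibble(lapply(stats::setNames(nm = iv$parameter), function(par) {
          stats::runif(n_draw, lo[[par]], hi[[par]])
        }))
        good <- complete_and_filter(draw)
        acc <- max((nrow(good) + 1) / (n_draw + 2), 1e-3)
        out <- if (is.null(out)) good else dplyr::bind_rows(out, good)
        if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
      }
      abort(sprintf(
        "Could not generate %d valid tuples in %d rounds; filters look infeasible.",
        n, max_attempts), class = "ifpulse_generation_failure")
    } else {
      m_axis <- max(2L, ceiling(n^(1 / nrow(iv))))
      for (grow in 0:2) {
        axes <- lapply(stats::setNames(nm = iv$parameter), function(par) {
          if (lo[[par]] == hi[[par]]) lo[[par]]
          else seq(lo[[par]], hi[[par]], length.out = m_axis + grow)
        })
        mesh <- as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
        good <- complete_and_filter(mesh)
        if (nrow(good) >= n) return(good[seq_len(n), , drop = FALSE])
      }
      if (nrow(good) == 0) {
        abort("Mesh exhausted with no valid tuples; filters look infeasible.",
              class = "ifpulse_generation_failure")
      }
      warn(sprintf("Mesh exhausted: returning %d of %d requested tuples.",
                   nrow(good), n))
      good
    }
  })
}

#' Generate a synthetic waveform dataset with exact ground truth
#'
#' For each sampled parameter tuple the waveform is the exact analytic
#' reconstruction on the 500-point standard grid ([reconstruct()]), so the
#' stored parameters are exact ground truth. Generated waveforms keep their
#' analytic values and are deliberately **not** re-min-max-normalized:
#' renormalizing would silently change `Rs_hat` and `c_hat` away from the
#' stored truth. The value-band filter in [parameter_ranges()] keeps shapes
#' near the standard `[0, 1]` band instead. Optional additive Gaussian
#' noise (default none) supports robustness experiments; ground-truth
#' parameters always describe the noise-free waveform.
#'
#' @inheritParams sample_parameters
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = none).
#' @param n_samples Samples per waveform (500).
#'
#' @return An object of class `if_dataset`: a list with `waveforms` (an
#'   `n x 500` matrix), `params` (ground-truth tibble), and the generator
#'   metadata (`seed`, `mode`, `ranges`, `noise_sd`). `as_tibble()` gives a
#'   per-record view with a waveform list-column.
#' @examples
#' ds <- generate_dataset(parameter_ranges("table3"), n = 5, seed = 1)
#' ds
#' @export
generate_dataset <- function(ranges, n = 8208, mode = c("random", "mesh"),
                             seed = NULL, noise_sd = 0, n_samples = 500) {
  mode <- match.arg(mode)
  params <- sample_parameters(ranges, n, mode = mode, seed = seed)
  waves <- reconstruct(params, n = n_samples)
  waves <- matrix(waves, nrow = nrow(params))
  if (noise_sd > 0) {
    waves <- waves + with_seed_(
      if (is.null(seed)) NULL else derive_seed(seed, 17),
      matrix(stats::rnorm(length(waves), 0, noise_sd), nrow = nrow(waves))
    )
  }
  structure(
    list(waveforms = waves, params = params, seed = seed, mode = mode,
         ranges = ranges, noise_sd = noise_sd),
    class = "if_dataset"
  )
}

#' @export
print.if_dataset <- function(x, ...) {
  cat(sprintf(
    "<if_dataset: %d waveforms x %d samples (preset %s, mode %s, seed %s, noise_sd %g)>\n",
    nrow(x$waveforms), ncol(x$waveforms), x$ranges$preset, x$mode,
    if (is.null(x$seed)) "none" else format(x$seed), x$noise_sd))
  invisible(x)
}

#' @export
as_tibble.if_dataset <- function(x, ...) {
  out <- x$params
  out$waveform <- lapply(seq_len(nrow(x$waveforms)),
                         function(i) x$waveforms[i, ])
  out
}

# Model-input view of a dataset: x is [notch fraction, 500 samples] per row,
# y the five network targets in fixed order.
surrogate_inputs <- function(data) {
  if (inherits(data, "if_dataset")) {
    x <- cbind(data$params$T0_hat, data$waveforms)
    y <- as.matrix(data$params[, c("omega1_hat", "omega2_hat", "Rs_hat",
                                   "phi1_hat", "c_hat")])
    return(list(x = x, y = y))
  }
  if (is.list(data) && all(c("x", "y") %in% names(data))) {
    return(list(x = as.matrix(data$x), y = as.matrix(data$y)))
  }
  stop_invalid("`data` must be an if_dataset or a list with `x` and `y`.")
}

# One record of a dataset as a scaled_waveform view (no renormalization).
dataset_waveform <- function(data, i) {
  new_scaled_waveform(data$waveforms[i, ], data$params$T0_hat[i])
}
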