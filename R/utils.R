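# Internal helpers shared across modules.

#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats predict
NULL

# Reduce an angle to the interval (-pi, pi].
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Deterministic derivation of per-stage seeds from one master seed; keeps the
# result a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.double(seed) * 7919 + 104729 * stage) %% 2147483647
}

stop_invalid <- function(msg) {
  abort(msg, class = "ifpulse_invalid_input")
}

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
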