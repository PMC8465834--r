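# Internal helpers: typed errors, seed hygiene, moving averages.

ht_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ht_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L &&
    (is.finite(x) || (allow_inf && !is.na(x)))
  if (!ok) {
    ht_error("ht_invalid_parameter",
             sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    ht_error("ht_invalid_parameter", sprintf("`%s` must be > 0", name))
  }
  if (nonnegative && x < 0) {
    ht_error("ht_invalid_parameter", sprintf("`%s` must be >= 0", name))
  }
  invisible(x)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. All generators route their randomness through this.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Centered moving average; returns NA where the full window does not fit.
moving_average <- function(x, half_width) {
  if (half_width < 1L) return(x)
  k <- 2L * as.integer(half_width) + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}
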