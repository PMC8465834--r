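#' Normalized autocorrelation of a gap (or signal) trace
#'
#' Computes the autocorrelation function of the fluctuation
#' `dE(t) - <dE>` about the record mean,
#' `ACF(l) = <dE(0) dE(l)> / <(dE)^2>`, with the N-normalized (biased)
#' estimator: both the lagged covariance and the variance carry a `1/N`
#' factor, so `ACF(0) = 1` exactly and the estimate is stable at long lags.
#' The lag grid starts at one sampling interval (sub-interval behavior is
#' not resolvable) and extends to `max_lag_ps`, by default half the record.
#'
#' @param trace A single-channel [site_energy_trace()] (use [gap_trace()]
#'   for a two-channel trace first).
#' @param max_lag_ps Maximum lag, ps; must be below the record span.
#' @return An `acf_result`: list with `lag_ps`, `acf`, the record `mean`
#'   used as the equilibrium value, and the N-normalized `variance`
#'   (units of the channel squared).
#' @examples
#' tr <- site_energy_trace(seq(0, 99.5, 0.5),
#'                         value = sin(seq(0, 99.5, 0.5) / 5))
#' a <- autocorrelation(tr)
#' a$acf[1]   # lag 0: exactly 1
#' @export
autocorrelation <- function(trace, max_lag_ps = NULL) {
  x <- single_channel(trace)
  n <- length(x)
  span <- trace$time_ps[n] - trace$time_ps[1]
  if (is.null(max_lag_ps)) max_lag_ps <- span / 2
  stopifnot_scalar_number(max_lag_ps, "max_lag_ps", positive = TRUE)
  if (max_lag_ps >= span) {
    ht_error("ht_invalid_parameter", "max_lag_ps must be below the record span")
  }
  v <- sum((x - mean(x))^2) / n
  if (v == 0) {
    ht_error("ht_degenerate_input",
             "zero-variance series: autocorrelation undefined")
  }
  lag_max <- floor(max_lag_ps / trace$dt_ps)
  est <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE,
                    type = "correlation")
  structure(
    list(lag_ps = est$lag[, 1, 1] * trace$dt_ps,
         acf = est$acf[, 1, 1],
         mean = mean(x),
         variance = v),
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("acf_result: %d lags up to %g ps, <x> = %.4g, var = %.4g\n",
              length(x$lag_ps) - 1L, max(x$lag_ps), x$mean, x$variance))
  invisible(x)
}

#' Half-period of the slow mode from an ACF reversal
#'
#' Locates the first reversal of the (optionally smoothed) autocorrelation
#' function and returns twice its lag as the half-period of the underlying
#' slow solvent mode. This is the estimator that reads an activation time
#' off a non-exponential, oscillatory gap ACF: a reversal at ~450 ps implies
#' a half-period of ~900 ps.
#'
#' Two reversal definitions are offered. The default, `"sign"`, takes the
#' lag where the correlation first turns negative (for a cosine-shaped ACF
#' this is the quarter period, so doubling it recovers the half period
#' exactly). `"extremum"` instead takes the first local extremum after the
#' initial decay (for a cosine this is the half period itself, and doubling
#' yields the full period); it is provided because a heavily damped ACF may
#' reverse slope without ever changing sign.
#'
#' An ACF that decays monotonically toward zero has no reversal; this is
#' reported with `found = FALSE` rather than as an error.
#'
#' @param acf_result An [autocorrelation()] result.
#' @param window_ps Centered moving-average smoothing window applied to the
#'   ACF before the scan (default 50 ps; 0 disables smoothing).
#' @param method `"sign"` (first sign change, default) or `"extremum"`
#'   (first slope reversal).
#' @return List with `half_period_ps`, `reversal_lag_ps`, `found`,
#'   `method`, and `window_ps`.
#' @examples
#' lags <- seq(0, 1400, 0.5)
#' tr <- site_energy_trace(seq(0, 5999.5, 0.5),
#'                         value = cos(pi * seq(0, 5999.5, 0.5) / 900))
#' a <- autocorrelation(tr, max_lag_ps = 1500)
#' acf_half_period(a, window_ps = 0)$half_period_ps   # ~900 ps
#' @export
acf_half_period <- function(acf_result, window_ps = 50,
                            method = c("sign", "extremum")) {
  if (!inherits(acf_result, "acf_result")) {
    ht_error("ht_invalid_parameter", "`acf_result` must come from autocorrelation()")
  }
  method <- match.arg(method)
  stopifnot_scalar_number(window_ps, "window_ps", nonnegative = TRUE)
  lag <- acf_result$lag_ps
  dt <- lag[2] - lag[1]
  s <- acf_result$acf
  if (window_ps > 0) {
    hw <- max(0L, round(window_ps / (2 * dt)))
    s <- moving_average(s, hw)
  }
  ok <- which(!is.na(s))
  s <- s[ok]; lag <- lag[ok]
  out <- list(half_period_ps = NA_real_, reversal_lag_ps = NA_real_,
              found = FALSE, method = method, window_ps = window_ps)
  rev_lag <- NA_real_
  if (method == "sign") {
    neg <- which(s < 0)
    if (length(neg)) {
      i <- neg[1]
      # interpolate the crossing between the bracketing lags
      rev_lag <- if (i > 1) {
        lag[i - 1] + (0 - s[i - 1]) / (s[i] - s[i - 1]) * (lag[i] - lag[i - 1])
      } else lag[i]
    }
  } else {
    dirs <- sign(diff(s))
    nz <- which(dirs != 0)
    if (length(nz)) {
      d0 <- dirs[nz[1]]
      flip <- nz[dirs[nz] != d0]
      if (length(flip)) rev_lag <- lag[flip[1]]
    }
  }
  if (is.na(rev_lag)) return(out)
  list(half_period_ps = 2 * rev_lag, reversal_lag_ps = rev_lag,
       found = TRUE, method = method, window_ps = window_ps)
}
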