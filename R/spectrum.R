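#' Single-sided power spectrum on a wavenumber axis
#'
#' Fourier-analyzes a uniformly sampled signal (e.g. the electrostatic
#' potential at a nucleobase site) and reports single-sided spectral power
#' against vacuum wavenumbers. The signal is first detrended (mean removal,
#' or mean plus linear trend), then tapered (Hann window by default), then
#' transformed with the FFT. Frequencies are converted via
#' `1 THz = 33.35641 cm^-1` (fixed `c = 2.99792458e10 cm/s`).
#'
#' Note the Nyquist limit: 0.5 ps sampling caps the axis at ~33 cm^-1, so
#' resolving the 100-3000 cm^-1 vibrational band requires fs-scale
#' sampling.
#'
#' @param trace A single-channel [site_energy_trace()] with >= 16 samples.
#' @param detrend `"mean"` (default) or `"linear"`.
#' @param window Taper: `"hann"` (default) or `"none"`.
#' @return A `spectrum_result`: list with `wavenumber_cm1` (0..Nyquist),
#'   `power` (single-sided, arbitrary units), `detrend`, `window`, and a
#'   `parseval` pair (`time_domain` = sum of squares of the windowed,
#'   detrended signal; `freq_domain` = the same energy summed over the
#'   transform) whose relative difference certifies the transform.
#' @examples
#' t_fs <- seq(0, 9999, 1)                      # 10 ps at 1 fs
#' nu <- 1000 * ht_constants$c_cm_s * 1e-15     # 1000 cm^-1 in fs^-1
#' tr <- site_energy_trace(t_fs / 1000, value = cos(2 * pi * nu * t_fs))
#' sp <- fourier_spectrum(tr)
#' sp$wavenumber_cm1[which.max(sp$power)]       # ~1000
#' @export
fourier_spectrum <- function(trace, detrend = c("mean", "linear"),
                             window = c("hann", "none")) {
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  x <- single_channel(trace)
  n <- length(x)
  if (n < 16L) {
    ht_error("ht_invalid_parameter", "spectrum needs >= 16 samples")
  }
  if (detrend == "mean") {
    x <- x - mean(x)
  } else {
    tt <- trace$time_ps
    x <- stats::lm(x ~ tt)$residuals
  }
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  } else rep(1, n)
  y <- x * w

  X <- stats::fft(y)
  dt_s <- trace$dt_ps * 1e-12
  half <- seq_len(floor(n / 2) + 1L)          # DC .. Nyquist
  freq_hz <- (half - 1L) / (n * dt_s)
  power <- Mod(X[half])^2 / n
  dbl <- half > 1L & (half - 1L) < n / 2      # interior bins appear twice
  power[dbl] <- 2 * power[dbl]

  structure(
    list(wavenumber_cm1 = freq_hz / ht_constants$c_cm_s,
         power = power,
         detrend = detrend, window = window,
         parseval = c(time_domain = sum(y^2),
                      freq_domain = sum(Mod(X)^2) / n)),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  pk <- which.max(x$power)
  cat(sprintf("spectrum_result: %d bins to %.4g cm^-1 (%s detrend, %s window)\n",
              length(x$wavenumber_cm1), max(x$wavenumber_cm1),
              x$detrend, x$window))
  cat(sprintf("  dominant bin: %.4g cm^-1\n", x$wavenumber_cm1[pk]))
  invisible(x)
}
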