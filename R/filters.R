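## Internal zero-phase filtering utilities.
##
## signal::filtfilt applies no edge padding, so transients at the series ends
## would leak into the data. filtfilt_pad() mirrors scipy-style odd reflection
## padding before the forward-backward pass and strips it afterwards.

filtfilt_pad <- function(flt, x) {
  n <- length(x)
  if (n >= 4096) return(filtfilt_fft(list(flt), x))
  npad <- min(n - 1, max(3 * max(length(flt$a), length(flt$b)), 200L))
  if (n <= 3 * max(length(flt$a), length(flt$b)) + 1) {
    ## too short to pad meaningfully; filter directly
    return(signal::filtfilt(flt, x))
  }
  ## remove the start level before filtering (filtfilt starts from zero
  ## state, so a DC offset would ring at the edges) and restore it through
  ## the filter's DC gain afterwards
  x1 <- x[1]
  g0 <- sum(flt$b) / sum(flt$a)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(flt, c(pre, x, post) - x1) + g0 * x1
  y[(npad + 1):(npad + n)]
}

## Zero-phase filtering in the frequency domain: multiplies the spectrum by
## the squared magnitude response |H|^2 of the designed filter(s), which is
## the exact transfer function of a forward-backward pass (a cascade when
## several filters are given). Odd-reflection padding suppresses wrap-around
## at the series ends. Much faster than time-domain filtfilt for the long
## records this package handles.
filtfilt_fft <- function(filters, x) {
  n <- length(x)
  npad <- min(n - 1, 5000L)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(pre, x, post)
  N <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, rep(0, N - length(xp)))
  H2 <- 1
  for (flt in filters) {
    Hb <- stats::fft(c(flt$b, rep(0, N - length(flt$b))))
    Ha <- stats::fft(c(flt$a, rep(0, N - length(flt$a))))
    H2 <- H2 * (Mod(Hb) / Mod(Ha))^2
  }
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / N
  y[(npad + 1):(npad + n)]
}

## cascade of zero-phase filters in a single spectral pass when long enough
filtfilt_cascade <- function(filters, x) {
  if (length(x) >= 4096) return(filtfilt_fft(filters, x))
  for (flt in filters) x <- filtfilt_pad(flt, x)
  x
}

## squared magnitude response of a filter cascade on the length-N DFT grid
cascade_H2 <- function(filters, N) {
  H2 <- 1
  for (flt in filters) {
    Hb <- stats::fft(c(flt$b, rep(0, N - length(flt$b))))
    Ha <- stats::fft(c(flt$a, rep(0, N - length(flt$a))))
    H2 <- H2 * (Mod(Hb) / Mod(Ha))^2
  }
  H2
}

## Zero-phase filter a matrix of real channels (columns), two channels per
## complex FFT: because |H|^2 is real and conjugate-symmetric, filtering the
## complex series x1 + i x2 and splitting real/imaginary parts filters both
## channels at once.
filtfilt_fft_mat <- function(filters, X) {
  n <- nrow(X)
  k <- ncol(X)
  if (n < 4096) {
    for (j in seq_len(k)) {
      for (flt in filters) X[, j] <- filtfilt_pad(flt, X[, j])
    }
    return(X)
  }
  npad <- min(n - 1, 5000L)
  N <- stats::nextn(n + 2 * npad, c(2, 3, 5))
  H2 <- cascade_H2(filters, N)
  out <- X
  j <- 1L
  while (j <= k) {
    x1 <- X[, j]
    two <- j + 1L <= k
    x2 <- if (two) X[, j + 1L] else NULL
    pre1 <- 2 * x1[1] - x1[(npad + 1):2]
    post1 <- 2 * x1[n] - x1[(n - 1):(n - npad)]
    z <- c(pre1, x1, post1)
    if (two) {
      pre2 <- 2 * x2[1] - x2[(npad + 1):2]
      post2 <- 2 * x2[n] - x2[(n - 1):(n - npad)]
      z <- complex(real = z, imaginary = c(pre2, x2, post2))
    }
    z <- c(z, rep(if (two) 0i else 0, N - length(z)))
    y <- stats::fft(stats::fft(z) * H2, inverse = TRUE) / N
    out[, j] <- Re(y)[(npad + 1):(npad + n)]
    if (two) out[, j + 1L] <- Im(y)[(npad + 1):(npad + n)]
    j <- j + 2L
  }
  out
}

## Band-limited Gaussian carriers by spectral synthesis: iid complex
## Gaussian spectra shaped by the cascade's |H|^2 amplitude (the spectrum a
## zero-phase-filtered white noise would have), two independent real
## carriers per inverse FFT. Columns are normalized to unit SD.
synth_carriers <- function(filters, n, k) {
  N <- stats::nextn(n, c(2, 3, 5))
  H2 <- cascade_H2(filters, N)
  out <- matrix(0, n, k)
  j <- 1L
  while (j <= k) {
    z <- complex(real = rnorm(N), imaginary = rnorm(N)) * H2
    y <- stats::fft(z, inverse = TRUE) / sqrt(N)
    out[, j] <- Re(y)[seq_len(n)]
    if (j + 1L <= k) out[, j + 1L] <- Im(y)[seq_len(n)]
    j <- j + 2L
  }
  scale(out, center = FALSE, scale = apply(out, 2, sd))[, , drop = FALSE]
}

butter_lowpass <- function(cutoff_hz, rate_hz, order) {
  if (cutoff_hz >= rate_hz / 2) {
    abort(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                  cutoff_hz, rate_hz / 2))
  }
  signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
}

butter_highpass <- function(cutoff_hz, rate_hz, order) {
  if (cutoff_hz >= rate_hz / 2) {
    abort(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                  cutoff_hz, rate_hz / 2))
  }
  signal::butter(order, cutoff_hz / (rate_hz / 2), type = "high")
}

#' Magnitude response of a designed Butterworth section
#'
#' Returns the magnitude of the frequency response at `freq_hz` for the
#' package's filter designs, computed from the filter coefficients. Because
#' the pipeline filters are applied zero-phase (forward and backward), the
#' effective magnitude is the square of the single-pass magnitude; set
#' `zero_phase = TRUE` (the default) to obtain it.
#'
#' @param type `"marker_lowpass"`, `"emg_bandpass"` or `"envelope_lowpass"`.
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param rate_hz Sampling rate of the signal the filter is designed for.
#' @param cfg A [gait_config()] providing cutoffs and orders.
#' @param zero_phase Square the single-pass magnitude (zero-phase
#'   application).
#' @return Numeric vector of gains in `[0, 1]`.
#' @export
filter_response <- function(type = c("marker_lowpass", "emg_bandpass", "envelope_lowpass"),
                            freq_hz, rate_hz, cfg = gait_config(),
                            zero_phase = TRUE) {
  type <- match.arg(type)
  w <- pi * freq_hz / (rate_hz / 2)
  ## evaluate H(e^{-iw}) directly from the coefficients
  mag_of <- function(flt) {
    vapply(w, function(wi) {
      zb <- exp(-1i * wi * (seq_along(flt$b) - 1))
      za <- exp(-1i * wi * (seq_along(flt$a) - 1))
      Mod(sum(flt$b * zb) / sum(flt$a * za))
    }, numeric(1))
  }
  mag <- switch(type,
    marker_lowpass = mag_of(butter_lowpass(cfg$marker_lowpass_hz, rate_hz,
                                           cfg$marker_filter_order)),
    envelope_lowpass = mag_of(butter_lowpass(cfg$envelope_lowpass_hz, rate_hz,
                                             cfg$envelope_filter_order)),
    emg_bandpass = {
      hp <- butter_highpass(cfg$emg_band_hz[1], rate_hz, cfg$emg_filter_order)
      lp <- butter_lowpass(cfg$emg_band_hz[2], rate_hz, cfg$emg_filter_order)
      mag_of(hp) * mag_of(lp)
    }
  )
  if (zero_phase) mag^2 else mag
}
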