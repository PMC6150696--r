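#' Band-pass filter raw EMG
#'
#' Conditions a raw EMG series by zero-phase Butterworth band-pass filtering
#' (default 5--500 Hz, 4th order), removing motion artifact below the low
#' corner and out-of-band noise above the high corner. The band-pass is
#' realized as a cascade of a 4th-order high-pass at the low corner and a
#' 4th-order low-pass at the high corner, each applied forward-backward so
#' the output is delay-free and the same length as the input.
#'
#' @param x Numeric EMG series (mV).
#' @param rate_hz Sampling rate (Hz); must exceed twice the high corner.
#' @param cfg A [gait_config()]; uses `emg_band_hz`, `emg_filter_order` and
#'   `emg_notch_60`.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_filter_emg <- function(x, rate_hz, cfg = gait_config()) {
  low <- cfg$emg_band_hz[1]
  high <- cfg$emg_band_hz[2]
  if (high >= rate_hz / 2) {
    abort(sprintf("EMG band upper corner %g Hz must be below Nyquist (%g Hz)",
                  high, rate_hz / 2))
  }
  if (isTRUE(cfg$emg_notch_60)) {
    ## narrow 2nd-order band-stop centred on the mains frequency
    bs <- signal::butter(2, c(58, 62) / (rate_hz / 2), type = "stop")
    x <- filtfilt_pad(bs, x)
  }
  hp <- butter_highpass(low, rate_hz, cfg$emg_filter_order)
  lp <- butter_lowpass(high, rate_hz, cfg$emg_filter_order)
  filtfilt_cascade(list(hp, lp), x)
}

#' Rectify EMG and compute its envelope
#'
#' Full-wave rectifies a band-passed EMG series and low-pass filters the
#' result (default 20 Hz, 4th order, zero-phase) to obtain the linear
#' envelope. Filter undershoot below zero is clipped so the envelope is
#' non-negative everywhere.
#'
#' @param x Band-pass filtered EMG series (mV).
#' @param rate_hz Sampling rate (Hz).
#' @param cfg A [gait_config()]; uses `envelope_lowpass_hz` and
#'   `envelope_filter_order`.
#' @return Non-negative envelope series, same length as `x`.
#' @export
rectify_and_envelope <- function(x, rate_hz, cfg = gait_config()) {
  lp <- butter_lowpass(cfg$envelope_lowpass_hz, rate_hz, cfg$envelope_filter_order)
  pmax(filtfilt_pad(lp, abs(x)), 0)
}

#' Compute envelopes for every EMG channel of a trial
#'
#' Applies [bandpass_filter_emg()] then [rectify_and_envelope()] to each
#' muscle channel.
#'
#' @param trial A [trial_recording()].
#' @param cfg A [gait_config()].
#' @return A tibble with `time_s` and one envelope column per muscle (mV).
#' @export
trial_envelopes <- function(trial, cfg = gait_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  rate <- trial$emg_rate
  if (cfg$emg_band_hz[2] >= rate / 2) {
    abort(sprintf("EMG band upper corner %g Hz must be below Nyquist (%g Hz)",
                  cfg$emg_band_hz[2], rate / 2))
  }
  X <- as.matrix(trial$emg[GAIT_MUSCLES])
  if (isTRUE(cfg$emg_notch_60)) {
    bs <- signal::butter(2, c(58, 62) / (rate / 2), type = "stop")
    X <- filtfilt_fft_mat(list(bs), X)
  }
  hp <- butter_highpass(cfg$emg_band_hz[1], rate, cfg$emg_filter_order)
  lp <- butter_lowpass(cfg$emg_band_hz[2], rate, cfg$emg_filter_order)
  X <- filtfilt_fft_mat(list(hp, lp), X)
  elp <- butter_lowpass(cfg$envelope_lowpass_hz, rate, cfg$envelope_filter_order)
  E <- pmax(filtfilt_fft_mat(list(elp), abs(X)), 0)
  colnames(E) <- GAIT_MUSCLES
  as_tibble(cbind(tibble(time_s = trial$emg$time_s), as_tibble(E)))
}

#' Detect burst onsets in an EMG envelope
#'
#' Data-driven onset detection: the quiet floor is the set of envelope
#' samples at or below the `quiet_quantile` quantile of the envelope; the
#' threshold is the floor mean plus `k_sd` floor standard deviations. An
#' onset is an upward threshold crossing that stays supra-threshold for at
#' least `min_burst_s`; successive onsets closer than `min_gap_s` are merged
#' (the earlier one wins). To keep slow fluctuations of the quiet floor from
#' triggering, the threshold is floored at `onset_min_level_frac` of the
#' envelope's 95th percentile. Because every ingredient is a quantile or
#' moment of the data, onset times are invariant to rescaling the raw
#' signal.
#'
#' @param env Envelope series (non-negative, mV).
#' @param rate_hz Sampling rate (Hz).
#' @param cfg A [gait_config()]; uses the `onset_*` keys.
#' @return A tibble with columns `onset_s` (strictly increasing) and
#'   `threshold_mv`. A flat envelope yields zero rows.
#' @export
detect_onsets <- function(env, rate_hz, cfg = gait_config()) {
  n <- length(env)
  min_run <- max(1L, as.integer(round(cfg$onset_min_burst_s * rate_hz)))
  if (n <= min_run) abort("envelope shorter than the minimum burst duration")
  thr <- envelope_threshold(env, cfg)
  above <- env > thr
  if (!any(above)) {
    return(tibble(onset_s = numeric(0), threshold_mv = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  onset_idx <- starts[keep]
  if (length(onset_idx) == 0) {
    return(tibble(onset_s = numeric(0), threshold_mv = numeric(0)))
  }
  onset_t <- (onset_idx - 1L) / rate_hz
  ## enforce the refractory gap
  kept <- onset_t[1]
  for (t in onset_t[-1]) {
    if (t - kept[length(kept)] >= cfg$onset_min_gap_s) kept <- c(kept, t)
  }
  tibble(onset_s = kept, threshold_mv = thr)
}
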