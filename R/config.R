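#' Pipeline configuration
#'
#' `gait_config()` collects every tunable constant of the analysis chain in a
#' single validated list. Defaults are the values used throughout the
#' package's reference analysis: a 10 Hz / 5th-order Butterworth low-pass for
#' marker trajectories, a 5--500 Hz / 4th-order band-pass for EMG, a 20 Hz
#' envelope low-pass, stride screening at 1.5 sample standard deviations
#' (duration), Tukey fences at 1.5 interquartile ranges (EMG artifacts), a
#' strict 20% missing-kinematics limit, and time normalization to 100
#' samples per cycle.
#'
#' @param ... Named overrides for any configuration key. Unknown keys are an
#'   error; the message lists the valid keys.
#'
#' @return An object of class `gait_config` (a named list).
#'
#' @details Keys and units:
#' \describe{
#'   \item{marker_lowpass_hz, marker_filter_order}{Marker low-pass cutoff
#'     (Hz) and Butterworth order.}
#'   \item{emg_band_hz, emg_filter_order}{EMG band-pass corner frequencies
#'     (Hz, length 2) and the order of each (high/low-pass) section.}
#'   \item{emg_notch_60}{Apply a software 60 Hz notch before band-passing;
#'     off by default because hardware chains typically notch at acquisition.}
#'   \item{envelope_lowpass_hz, envelope_filter_order}{Low-pass applied to the
#'     rectified EMG to form the envelope.}
#'   \item{onset_quiet_quantile, onset_k_sd, onset_min_burst_s,
#'     onset_min_gap_s}{Burst-onset detector: the quiet floor is the set of
#'     envelope samples below the `onset_quiet_quantile` quantile, the
#'     threshold is floor mean + `onset_k_sd` floor SDs, a crossing must stay
#'     supra-threshold for `onset_min_burst_s`, and successive onsets must be
#'     `onset_min_gap_s` apart. The threshold is additionally floored at
#'     `onset_min_level_frac` times the envelope's 95th percentile so that
#'     slow fluctuations of the noise floor cannot trigger onsets.}
#'   \item{duration_sd}{Stride-duration screen half-width in sample SDs.}
#'   \item{tukey_k}{Tukey fence multiplier for per-muscle envelope maxima.}
#'   \item{missing_frac}{Strides with strictly more than this fraction of
#'     missing frames in any kinematic channel are excluded.}
#'   \item{normalized_length}{Samples per time-normalized cycle (>= 2).}
#'   \item{stance_frac_threshold, stance_min_s}{Stance detector: stance is
#'     declared while the toe's forward velocity is below
#'     `-stance_frac_threshold * belt speed`; intervals shorter than
#'     `stance_min_s` are discarded.}
#'   \item{gap_interp_frames}{Longest masked marker run (frames) bridged
#'     linearly before filtering. Bridged frames still count as missing for
#'     the `missing_frac` rule.}
#'   \item{burst_muscle}{Quadriceps channel whose detected extension burst
#'     anchors the mid-burst kinematic event.}
#'   \item{burst_fallback}{If no supra-threshold burst is found, integrate
#'     over `[foot_strike - 0.1 * duration, foot_off]` instead of dropping
#'     the stride's EMG feature.}
#'   \item{min_bout_strides}{Minimum run of consecutive duration-passing
#'     strides that counts as stable walking (1 disables the screen).}
#'   \item{seed}{Optional integer seed recorded with run manifests.}
#' }
#'
#' @examples
#' cfg <- gait_config(normalized_length = 50)
#' cfg$normalized_length
#' @export
gait_config <- function(...) {
  cfg <- list(
    marker_lowpass_hz = 10,
    marker_filter_order = 5,
    emg_band_hz = c(5, 500),
    emg_filter_order = 4,
    emg_notch_60 = FALSE,
    envelope_lowpass_hz = 20,
    envelope_filter_order = 4,
    onset_quiet_quantile = 0.1,
    onset_k_sd = 3,
    onset_min_burst_s = 0.05,
    onset_min_gap_s = 0.15,
    onset_min_level_frac = 0.05,
    duration_sd = 1.5,
    tukey_k = 1.5,
    missing_frac = 0.2,
    normalized_length = 100,
    stance_frac_threshold = 0.5,
    stance_min_s = 0.05,
    gap_interp_frames = 5,
    burst_muscle = "RF",
    burst_fallback = TRUE,
    min_bout_strides = 1,
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("all configuration overrides must be named")
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown configuration key(s): %s\nvalid keys: %s",
      paste(unknown, collapse = ", "), paste(names(cfg), collapse = ", ")
    ))
  }
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  structure(cfg, class = "gait_config")
}

validate_config <- function(cfg) {
  num_keys <- c(
    "marker_lowpass_hz", "marker_filter_order", "emg_filter_order",
    "envelope_lowpass_hz", "envelope_filter_order", "onset_quiet_quantile",
    "onset_k_sd", "onset_min_burst_s", "onset_min_gap_s", "onset_min_level_frac",
    "duration_sd", "tukey_k", "missing_frac", "normalized_length", "stance_frac_threshold",
    "stance_min_s", "gap_interp_frames", "min_bout_strides"
  )
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(sprintf("configuration key '%s' must be a single finite number", k))
    }
  }
  if (!is.numeric(cfg$emg_band_hz) || length(cfg$emg_band_hz) != 2 ||
      any(!is.finite(cfg$emg_band_hz)) || cfg$emg_band_hz[1] <= 0 ||
      diff(cfg$emg_band_hz) <= 0) {
    abort("'emg_band_hz' must be two increasing positive frequencies")
  }
  positive <- c(
    "marker_lowpass_hz", "marker_filter_order", "emg_filter_order",
    "envelope_lowpass_hz", "envelope_filter_order", "onset_k_sd",
    "onset_min_burst_s", "onset_min_gap_s", "duration_sd", "tukey_k",
    "stance_frac_threshold", "stance_min_s"
  )
  for (k in positive) {
    if (cfg[[k]] <= 0) abort(sprintf("configuration key '%s' must be positive", k))
  }
  if (cfg$missing_frac <= 0 || cfg$missing_frac >= 1) {
    abort("'missing_frac' must lie in (0, 1)")
  }
  if (cfg$onset_quiet_quantile <= 0 || cfg$onset_quiet_quantile >= 1) {
    abort("'onset_quiet_quantile' must lie in (0, 1)")
  }
  if (cfg$normalized_length < 2) abort("'normalized_length' must be >= 2")
  if (cfg$gap_interp_frames < 0) abort("'gap_interp_frames' must be >= 0")
  if (cfg$min_bout_strides < 1) abort("'min_bout_strides' must be >= 1")
  if (!is.character(cfg$burst_muscle) || length(cfg$burst_muscle) != 1) {
    abort("'burst_muscle' must be a single muscle name")
  }
  if (!is.logical(cfg$burst_fallback) || length(cfg$burst_fallback) != 1) {
    abort("'burst_fallback' must be TRUE or FALSE")
  }
  invisible(cfg)
}

#' Read and write pipeline configuration files
#'
#' Configurations are stored as YAML. Keys absent from the file take the
#' package defaults (see [gait_config()]); unknown keys are an error. A
#' write-then-read round trip returns an identical configuration.
#'
#' @param path File path.
#' @param cfg A `gait_config` object.
#' @return `load_config()` returns a `gait_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$emg_band_hz)) raw$emg_band_hz <- as.numeric(raw$emg_band_hz)
  do.call(gait_config, raw)
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gait_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k, if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
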