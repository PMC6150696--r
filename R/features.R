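#' Stance percentage of a stride
#'
#' Duration of the stance phase divided by the stride duration, as a
#' percentage. Absent stance yields `NA` (the feature is absent, not zero).
#'
#' @param duration Stride duration (s).
#' @param foot_strike,foot_off Stance bounds (s); may be `NA`.
#' @return Percentage in `(0, 100)` (values are not clamped; a stance
#'   nominally longer than the stride would exceed 100 and should be treated
#'   as suspect upstream).
#' @export
stance_percentage <- function(duration, foot_strike, foot_off) {
  ifelse(
    is.na(foot_strike) | is.na(foot_off) | is.na(duration) | duration <= 0,
    NA_real_,
    100 * (foot_off - foot_strike) / duration
  )
}

#' Range of motion of an angle series
#'
#' Maximum minus minimum over the valid frames of a stride's joint-angle
#' series, in degrees. Fewer than two valid frames yield `NA`.
#'
#' @param angle Numeric angle series (deg) for one stride.
#' @return Range of motion (deg, >= 0) or `NA`.
#' @export
range_of_motion <- function(angle) {
  v <- angle[!is.na(angle)]
  if (length(v) < 2) return(NA_real_)
  max(v) - min(v)
}

#' Joint angles and limb features at a cycle event
#'
#' Reads the kinematic state of a time-normalized stride at a named event:
#' `end_stance` is the normalized sample at foot-off; `mid_burst` is the
#' midpoint of the detected quadriceps extension-burst window (an earlier
#' point within the stance-related burst). Masked event samples yield `NA`.
#'
#' @param norm Normalized stride tibble from [normalize_stride()] containing
#'   `hip`, `knee`, `ankle`, `limb_length`, `limb_angle` columns.
#' @param event_frac Event position as a fraction of the cycle in `[0, 1]`
#'   (e.g. `(foot_off - start) / duration` for end of stance).
#' @return A one-row tibble with the five kinematic features at the event.
#' @export
angles_at_event <- function(norm, event_frac) {
  L <- nrow(norm)
  if (is.na(event_frac)) {
    return(tibble(hip = NA_real_, knee = NA_real_, ankle = NA_real_,
                  limb_length = NA_real_, limb_angle = NA_real_))
  }
  idx <- min(L, max(1L, 1L + as.integer(round(event_frac * L))))
  tibble(
    hip = norm$hip[idx], knee = norm$knee[idx], ankle = norm$ankle[idx],
    limb_length = norm$limb_length[idx], limb_angle = norm$limb_angle[idx]
  )
}

#' Locate a muscle's extension-burst window within a stride
#'
#' Finds the supra-threshold burst of an envelope between the stride start
#' and foot-off, using the same data-driven threshold as the onset detector
#' (quiet-floor mean + k SDs, computed over the whole trial's envelope and
#' passed in as `threshold`). The window is the span from the first to the
#' last supra-threshold sample in `[start, foot_off]`. If no sample is
#' supra-threshold and the fallback is enabled, the stance-anchored window
#' `[foot_strike - 0.1 * duration, foot_off]` is returned; otherwise the
#' window is absent (`NA`s).
#'
#' @param env_time,env Envelope time base (s) and values (mV) for the trial.
#' @param start,foot_strike,foot_off Stride bounds and stance events (s).
#' @param threshold Envelope threshold (mV).
#' @param fallback Use the stance-anchored fallback window.
#' @return A list with `window_start`, `window_end` (s; `NA` if absent) and
#'   `used_fallback`.
#' @export
burst_window <- function(env_time, env, start, foot_strike, foot_off,
                         threshold, fallback = TRUE) {
  absent <- list(window_start = NA_real_, window_end = NA_real_,
                 used_fallback = FALSE)
  if (is.na(foot_off)) return(absent)
  sel <- which(env_time >= start & env_time <= foot_off & env > threshold)
  if (length(sel) >= 2) {
    return(list(window_start = env_time[sel[1]],
                window_end = env_time[sel[length(sel)]],
                used_fallback = FALSE))
  }
  if (fallback && !is.na(foot_strike)) {
    dur <- foot_off - start
    return(list(window_start = max(start, foot_strike - 0.1 * dur),
                window_end = foot_off, used_fallback = TRUE))
  }
  absent
}

#' Integrate an EMG envelope over a window
#'
#' Trapezoidal integral of the envelope at its native sampling rate between
#' `from` and `to` (s). Integrals are computed on the raw time base, not the
#' normalized cycle, so the result is in physical units (mV s) independent
#' of time normalization.
#'
#' @param env_time,env Envelope time base (s) and values (mV).
#' @param from,to Window bounds (s).
#' @return Integral in mV s (`NA` for an absent window).
#' @export
integrate_envelope <- function(env_time, env, from, to) {
  if (is.na(from) || is.na(to) || to <= from) return(NA_real_)
  sel <- which(env_time >= from & env_time <= to)
  if (length(sel) < 2) return(NA_real_)
  tt <- env_time[sel]
  vv <- env[sel]
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Normalize integrated EMG to each subject's baseline mean
#'
#' Divides every stride's raw integrated extension-burst activity by the
#' mean raw integral over that subject's included baseline strides for the
#' same muscle, yielding the relative change of activation with respect to
#' baseline (baseline strides average to 1 by construction). Subjects with
#' no baseline strides for a muscle contribute no normalized rows for it
#' (logged as a message), mirroring designs where not every animal
#' contributes to every cell.
#'
#' @param features Long feature tibble containing `raw_int_emg_<muscle>`
#'   rows (columns `subject`, `week`, `session`, `stride_id`, `feature`,
#'   `value`).
#' @param baseline_week Label of the pre-perturbation condition
#'   (default `"base"`).
#' @return The input with `int_emg_<muscle>` rows appended (dimensionless).
#' @export
normalize_to_baseline <- function(features, baseline_week = "base") {
  raw <- features |>
    filter(stringr::str_starts(.data$feature, "raw_int_emg_"), !is.na(.data$value))
  if (nrow(raw) == 0) return(features)
  base_means <- raw |>
    filter(.data$week == baseline_week) |>
    group_by(.data$subject, .data$feature) |>
    summarise(base_mean = mean(.data$value), .groups = "drop")
  norm <- raw |>
    left_join(base_means, by = c("subject", "feature"))
  dropped <- norm |>
    filter(is.na(.data$base_mean) | .data$base_mean <= 0) |>
    distinct(.data$subject, .data$feature)
  if (nrow(dropped) > 0) {
    inform(sprintf(
      "no baseline strides for %d subject-muscle pair(s); their normalized EMG is absent",
      nrow(dropped)
    ))
  }
  norm <- norm |>
    filter(!is.na(.data$base_mean), .data$base_mean > 0) |>
    mutate(
      feature = sub("^raw_", "", .data$feature),
      value = .data$value / .data$base_mean
    ) |>
    select(-"base_mean")
  bind_rows(features, norm)
}
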