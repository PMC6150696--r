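#' Segment a trial into strides at TA onsets
#'
#' Each stride spans one tibialis anterior burst onset to the next; the last
#' onset opens no stride. Detected stance intervals are assigned to the
#' stride containing their foot-strike (at most one per stride; the first
#' wins).
#'
#' @param onsets Tibble of TA onsets from [detect_onsets()] (column
#'   `onset_s`), or a numeric vector of onset times (s).
#' @param stance Optional tibble of stance intervals from [detect_stance()]
#'   (columns `foot_strike`, `foot_off`).
#' @return A stride ledger tibble with columns `stride_id`, `start`, `end`,
#'   `duration`, `foot_strike`, `foot_off` (NA when no stance interval fell
#'   inside the stride). Fewer than two onsets yield an empty ledger with a
#'   warning.
#' @export
segment_strides <- function(onsets, stance = NULL) {
  t_on <- if (is.data.frame(onsets)) onsets$onset_s else as.numeric(onsets)
  empty <- tibble(
    stride_id = integer(0), start = numeric(0), end = numeric(0),
    duration = numeric(0), foot_strike = numeric(0), foot_off = numeric(0)
  )
  if (length(t_on) < 2) {
    warn("fewer than two TA onsets: no strides segmented")
    return(empty)
  }
  t_on <- sort(t_on)
  strides <- tibble(
    stride_id = seq_len(length(t_on) - 1L),
    start = t_on[-length(t_on)],
    end = t_on[-1]
  )
  strides$duration <- strides$end - strides$start
  strides$foot_strike <- NA_real_
  strides$foot_off <- NA_real_
  if (!is.null(stance) && nrow(stance) > 0) {
    idx <- findInterval(stance$foot_strike, t_on)
    ok <- idx >= 1 & idx <= nrow(strides)
    ## first stance interval striking inside each stride wins
    for (j in which(ok)) {
      i <- idx[j]
      if (is.na(strides$foot_strike[i])) {
        strides$foot_strike[i] <- stance$foot_strike[j]
        strides$foot_off[i] <- stance$foot_off[j]
      }
    }
  }
  strides
}

#' Apply the stride inclusion criteria
#'
#' Screens segmented strides with three single-pass rules, flagging but
#' never deleting:
#' \enumerate{
#'   \item \strong{duration_outlier}: stride duration differs from the
#'     session mean by more than `duration_sd` (default 1.5) sample standard
#'     deviations (n - 1 denominator), both statistics computed once over
#'     all segmented strides of the session;
#'   \item \strong{emg_artifact}: for any muscle, the stride's envelope
#'     maximum exceeds the Tukey fence Q3 + `tukey_k` * IQR (default 1.5) of
#'     that muscle's per-stride maxima (quartiles by linear interpolation of
#'     order statistics, R type 7);
#'   \item \strong{kinematic_missing}: any kinematic channel is missing in
#'     strictly more than `missing_frac` (default 20%) of the stride's
#'     frames.
#' }
#' With fewer than three strides the two statistical rules are skipped with
#' a warning. When `min_bout_strides > 1`, strides outside runs of at least
#' that many consecutive duration-passing strides are additionally marked
#' `duration_outlier` (an operationalization of "stable walking"; disabled
#' by default).
#'
#' @param strides Stride ledger from [segment_strides()] (needs `stride_id`
#'   and `duration`).
#' @param emg_maxima Optional tibble with columns `stride_id`, `muscle`,
#'   `max_mv`: per-stride envelope maxima. `NULL` skips rule 2.
#' @param kin_missing Optional tibble with columns `stride_id`, `channel`,
#'   `missing_frac`: per-stride fraction of missing frames per kinematic
#'   channel. `NULL` skips rule 3.
#' @param cfg A [gait_config()].
#' @return The ledger with logical `included` and character
#'   `exclusion_reasons` (comma-separated, `""` when included) appended.
#' @export
include_strides <- function(strides, emg_maxima = NULL, kin_missing = NULL,
                            cfg = gait_config()) {
  n <- nrow(strides)
  reasons <- vector("list", n)
  if (n == 0) {
    strides$included <- logical(0)
    strides$exclusion_reasons <- character(0)
    return(strides)
  }
  dur_ok <- rep(TRUE, n)
  if (n >= 3) {
    m <- mean(strides$duration)
    s <- sd(strides$duration)
    if (is.finite(s) && s > 0) {
      dur_ok <- abs(strides$duration - m) <= cfg$duration_sd * s
    }
    if (cfg$min_bout_strides > 1) {
      r <- rle(dur_ok)
      short <- rep(r$values & r$lengths < cfg$min_bout_strides, r$lengths)
      dur_ok[short] <- FALSE
    }
  } else {
    warn("fewer than 3 strides: duration and EMG-artifact screens skipped")
  }
  for (i in which(!dur_ok)) reasons[[i]] <- c(reasons[[i]], "duration_outlier")

  if (!is.null(emg_maxima) && n >= 3 && nrow(emg_maxima) > 0) {
    fences <- emg_maxima |>
      group_by(.data$muscle) |>
      summarise(
        fence = quantile(.data$max_mv, 0.75, names = FALSE, type = 7) +
          cfg$tukey_k * (quantile(.data$max_mv, 0.75, names = FALSE, type = 7) -
                           quantile(.data$max_mv, 0.25, names = FALSE, type = 7)),
        .groups = "drop"
      )
    bad <- emg_maxima |>
      left_join(fences, by = "muscle") |>
      filter(.data$max_mv > .data$fence) |>
      pull("stride_id") |>
      unique()
    for (i in which(strides$stride_id %in% bad)) {
      reasons[[i]] <- c(reasons[[i]], "emg_artifact")
    }
  }

  if (!is.null(kin_missing) && nrow(kin_missing) > 0) {
    bad <- kin_missing |>
      filter(.data$missing_frac > cfg$missing_frac) |>
      pull("stride_id") |>
      unique()
    for (i in which(strides$stride_id %in% bad)) {
      reasons[[i]] <- c(reasons[[i]], "kinematic_missing")
    }
  }

  strides$exclusion_reasons <- vapply(
    reasons, function(r) paste(unique(r), collapse = ","), character(1)
  )
  strides$included <- strides$exclusion_reasons == ""
  strides
}

#' Time-normalize stride signals to a fixed cycle length
#'
#' Resamples every signal column onto `L` equispaced points across the
#' stride `[start, end)` by linear interpolation in time (point `k` sits at
#' `start + (k - 1) / L * duration`, so the first sample is the stride's
#' start value). Masked samples are interpolated only when flanked by valid
#' samples on both sides at the target time; otherwise the normalized sample
#' is missing.
#'
#' @param signals Tibble with a `time_s` column and numeric signal columns
#'   covering `[start, end]` (EMG envelopes and joint angles are treated
#'   identically).
#' @param start,end Stride bounds (s), `end > start`.
#' @param L Normalized cycle length (>= 2), default 100.
#' @return A tibble with `cycle_frac` (in `[0, 1)`) and the resampled signal
#'   columns, exactly `L` rows.
#' @export
normalize_stride <- function(signals, start, end, L = 100) {
  if (L < 2) abort("normalized length L must be >= 2")
  if (end <= start) abort("stride end must exceed start")
  t_out <- start + (seq_len(L) - 1) / L * (end - start)
  out <- list(cycle_frac = (seq_len(L) - 1) / L)
  tt <- signals$time_s
  for (col in setdiff(names(signals), "time_s")) {
    x <- signals[[col]]
    ok <- !is.na(x)
    if (sum(ok) < 2) {
      out[[col]] <- rep(NA_real_, L)
      next
    }
    y <- approx(tt[ok], x[ok], xout = t_out, rule = 2)$y
    ## masked runs of >= 2 raw samples (and runs touching the series ends)
    ## are not "flanked": normalized samples falling inside them stay missing
    r <- rle(!ok)
    r_end <- cumsum(r$lengths)
    r_start <- r_end - r$lengths + 1L
    for (k in which(r$values)) {
      edge <- r_start[k] == 1L || r_end[k] == length(tt)
      if (r$lengths[k] >= 2L || edge) {
        lo <- if (r_start[k] == 1L) -Inf else tt[r_start[k]]
        hi <- if (r_end[k] == length(tt)) Inf else tt[r_end[k]]
        y[t_out >= lo & t_out <= hi] <- NA_real_
      }
    }
    out[[col]] <- y
  }
  as_tibble(out)
}
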