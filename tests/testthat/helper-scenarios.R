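# Shared scenario builders and comparison helpers for the suite. Scenarios
# are kept small so signal synthesis stays cheap in unit tests.

# A noise profile with every stochastic corruption switched off.
noise_off <- function(...) {
  utils::modifyList(
    list(carrier_band = c(30, 450), line_amp = 0, artifact_rate = 0,
         artifact_amp = 8, artifact_dur = 0.03, marker_sd = 0,
         knee_artifact = 0, occlusion_rate = 0, occlusion_mean_run = 6),
    list(...)
  )
}

# Default noise but without cable artifacts / occlusions, for oracle tests
# that need every stride or stance boundary detectable.
noise_clean <- function(...) {
  utils::modifyList(
    list(carrier_band = c(30, 450), line_amp = 0.002, artifact_rate = 0,
         artifact_amp = 8, artifact_dur = 0.03, marker_sd = 0.5,
         knee_artifact = 3, occlusion_rate = 0, occlusion_mean_run = 6),
    list(...)
  )
}

tiny_scenario <- function(n_subjects = 1, weeks = "base",
                          strides_per_session = 8, seed = 5, ...) {
  gait_scenario(n_subjects = n_subjects, weeks = weeks,
                strides_per_session = strides_per_session, seed = seed, ...)
}

# Uniform-gain table over muscles x weeks with named overrides like
# RF_week1 = 2.
flat_gains <- function(weeks, ...) {
  g <- tidyr::expand_grid(muscle = stridelab:::GAIT_MUSCLES, week = weeks)
  g$gain <- 1
  over <- list(...)
  for (nm in names(over)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    g$gain[g$muscle == parts[1] & g$week == paste(parts[-1], collapse = "_")] <-
      over[[nm]]
  }
  g
}

# Match each detected event time to the nearest true event; returns the
# signed errors (s) for pairs closer than `max_s`.
nearest_errors <- function(detected, truth, max_s = 0.25) {
  if (length(detected) == 0 || length(truth) == 0) return(numeric(0))
  err <- vapply(detected, function(t) {
    d <- t - truth
    d[which.min(abs(d))]
  }, numeric(1))
  err[abs(err) <= max_s]
}

# Minimal well-formed marker/EMG tables for io tests (n marker frames at
# 200 Hz and the matching EMG length at 5000 Hz).
tiny_marker_tbl <- function(n = 2) {
  cols <- list(time_s = (seq_len(n) - 1) / 200)
  for (mk in stridelab:::GAIT_MARKERS) {
    cols[[paste0(mk, "_x")]] <- seq_len(n) * 1.0
    cols[[paste0(mk, "_y")]] <- seq_len(n) + 10
    cols[[paste0(mk, "_z")]] <- rep(15, n)
  }
  tibble::as_tibble(cols)
}

tiny_emg_tbl <- function(n = 50) {
  cols <- list(time_s = (seq_len(n) - 1) / 5000)
  for (m in stridelab:::GAIT_MUSCLES) cols[[m]] <- sin(seq_len(n) / 3) / 10
  tibble::as_tibble(cols)
}

tiny_meta <- function() {
  list(subject = "S01", week = "base", session = "S01_base",
       marker_rate = 200, emg_rate = 5000, belt_speed = 12,
       femur_length = 38, tibia_length = 42, foot_length = 20,
       knee_side = "anterior")
}
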