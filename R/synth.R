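#' Specify a synthetic locomotion experiment
#'
#' Builds the scenario description consumed by [generate_experiment()]. The
#' defaults describe the package's reference adaptation scenario: six
#' subjects recorded at baseline and one, two and seven weeks after
#' paralysis of vastus lateralis, walking on a treadmill at 12 m/min.
#' Post-lesion weeks abolish VL (residual cross-talk gain 0.05), elevate RF
#' strongly at week 1 with partial decay by week 7, leave VM near baseline,
#' and perturb kinematics transiently (shorter stance, reduced limb
#' excursion, larger ankle swing amplitude) with full recovery by week 7.
#'
#' @param n_subjects Number of subjects.
#' @param weeks Conditions recorded per subject, in chronological order.
#' @param strides_per_session True strides generated per recording.
#' @param stride_duration_mean,stride_duration_sd Stride duration mean and
#'   stride-to-stride SD (s). Durations are drawn from a normal truncated to
#'   plus/minus three SDs; the mean must exceed three SDs or generation
#'   fails.
#' @param stance_fraction_mean,stance_fraction_sd Stance fraction of the
#'   cycle, mean in (0,1) and stride-to-stride SD.
#' @param belt_speed Belt speed (m/min).
#' @param geometry A [limb_geometry()] shared by all subjects.
#' @param hip_clearance Vertical hip-to-ankle distance during stance (mm).
#' @param swing_lift Peak ankle lift during swing (mm).
#' @param foot_angle_deg Foot (ankle-to-toe) direction relative to
#'   horizontal during stance (deg; negative points the toe down-forward).
#' @param ankle_swing_amp Baseline amplitude of the swing-phase foot
#'   rotation (deg); per-week deltas add to it.
#' @param pelvis_bob Amplitude of the stride-locked vertical hip
#'   oscillation (mm).
#' @param lateral_offset Constant z offset of all markers (mm).
#' @param week_kinematics Tibble with columns `week`, `stance_delta`
#'   (additive change of stance fraction), `excursion_scale`
#'   (multiplicative change of limb excursion) and `ankle_amp_delta` (deg).
#' @param burst_spec Tibble with columns `muscle`, `on_frac`, `off_frac`
#'   (burst window as cycle fractions), `amp_mv` (envelope amplitude, mV),
#'   `baseline_mv` (tonic floor, mV) and `attack_frac` (fraction of the
#'   burst occupied by the cosine attack; 0.5 gives the symmetric raised
#'   cosine, and the burst integral is `amp * gain * width / 2` for any
#'   value). TA defaults to a fast attack because its onset is the stride
#'   fiducial.
#' @param gains Tibble with columns `muscle`, `week`, `gain` (>= 0): the
#'   ground-truth multiplicative change of each muscle's burst amplitude per
#'   week. This is the quantity the EMG analysis recovers.
#' @param subject_sd Named list of between-subject SDs: `duration` (s),
#'   `stance` (fraction), `log_excursion`, `log_gain_int` (log-scale gain
#'   intercept), `log_gain_slope` (log-scale gain drift per week unit).
#' @param session_sd Named list of between-session SDs: `log_gain`
#'   (day-level gain factor shared by all muscles), `stance`,
#'   `log_excursion`.
#' @param stride_sd Named list of stride-level SDs: `log_gain`,
#'   `log_excursion`.
#' @param noise Named list: `carrier_band` (Hz, band of the EMG noise
#'   carrier), `line_amp` (mV, residual 60 Hz interference),
#'   `artifact_rate` (per-stride probability of a cable-strike transient),
#'   `artifact_amp` (amplitude factor relative to the muscle's burst),
#'   `artifact_dur` (s), `marker_sd` (mm), `knee_artifact` (mm,
#'   stride-locked skin-movement displacement of the knee marker only),
#'   `occlusion_rate` (per-frame probability that an occlusion run starts),
#'   `occlusion_mean_run` (frames).
#' @param marker_rate,emg_rate Sampling rates (Hz).
#' @param lead_s,tail_s Quiet standing recorded before and after walking
#'   (s).
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return An object of class `gait_scenario`.
#' @export
gait_scenario <- function(
    n_subjects = 6,
    weeks = GAIT_WEEKS,
    strides_per_session = 78,
    stride_duration_mean = 0.7,
    stride_duration_sd = 0.05,
    stance_fraction_mean = 0.62,
    stance_fraction_sd = 0.015,
    belt_speed = 12,
    geometry = limb_geometry(38, 42, 20),
    hip_clearance = 55,
    swing_lift = 12,
    foot_angle_deg = -50,
    ankle_swing_amp = 25,
    pelvis_bob = 2,
    lateral_offset = 15,
    week_kinematics = NULL,
    burst_spec = NULL,
    gains = NULL,
    subject_sd = list(duration = 0.04, stance = 0.015, log_excursion = 0.04,
                      log_gain_int = 0.10, log_gain_slope = 0.015),
    session_sd = list(log_gain = 0.04, stance = 0.003, log_excursion = 0.01),
    stride_sd = list(log_gain = 0.05, log_excursion = 0.02),
    noise = list(carrier_band = c(30, 450), line_amp = 0.002,
                 artifact_rate = 0.03, artifact_amp = 8, artifact_dur = 0.03,
                 marker_sd = 0.5, knee_artifact = 3,
                 occlusion_rate = 0.004, occlusion_mean_run = 6),
    marker_rate = 200,
    emg_rate = 5000,
    lead_s = 0.5,
    tail_s = 0.5,
    seed = 42) {
  if (is.null(week_kinematics)) {
    week_kinematics <- tibble(
      week = GAIT_WEEKS,
      stance_delta = c(0, -0.08, -0.035, 0),
      excursion_scale = c(1, 0.75, 0.90, 1),
      ankle_amp_delta = c(0, 8, 4, 0)
    )
  }
  if (is.null(burst_spec)) {
    burst_spec <- tibble(
      muscle = c("TA", "VL", "VM", "RF", "SM", "BFp", "GRc"),
      on_frac = c(0.00, 0.32, 0.32, 0.30, 0.35, 0.35, 0.35),
      off_frac = c(0.30, 0.92, 0.92, 0.92, 0.90, 0.90, 0.90),
      amp_mv = c(0.8, 0.5, 0.5, 0.5, 0.4, 0.4, 0.4),
      baseline_mv = rep(0.003, 7),
      ## TA rises abruptly (it is the stride-segmentation fiducial); the
      ## extensors keep the symmetric raised cosine
      attack_frac = c(0.12, rep(0.5, 6))
    )
  }
  if (is.null(gains)) {
    gains <- tidyr::expand_grid(muscle = GAIT_MUSCLES, week = weeks) |>
      mutate(gain = 1)
    adapt <- tibble(
      muscle = rep(c("VL", "RF", "VM"), each = 3),
      week = rep(c("week1", "week2", "week7"), 3),
      gain = c(0.05, 0.05, 0.05,  2.6, 2.2, 1.9,  1.04, 1.02, 1.00)
    )
    gains <- gains |>
      left_join(adapt, by = c("muscle", "week"), suffix = c("", ".adapt")) |>
      mutate(gain = dplyr::coalesce(.data$gain.adapt, .data$gain)) |>
      select(-"gain.adapt")
    gains <- gains[gains$week %in% weeks, ]
  }
  spec <- structure(
    list(
      n_subjects = n_subjects, weeks = weeks,
      strides_per_session = strides_per_session,
      stride_duration_mean = stride_duration_mean,
      stride_duration_sd = stride_duration_sd,
      stance_fraction_mean = stance_fraction_mean,
      stance_fraction_sd = stance_fraction_sd,
      belt_speed = belt_speed, geometry = geometry,
      hip_clearance = hip_clearance, swing_lift = swing_lift,
      foot_angle_deg = foot_angle_deg, ankle_swing_amp = ankle_swing_amp,
      pelvis_bob = pelvis_bob, lateral_offset = lateral_offset,
      week_kinematics = week_kinematics, burst_spec = burst_spec,
      gains = gains, subject_sd = subject_sd, session_sd = session_sd,
      stride_sd = stride_sd, noise = noise,
      marker_rate = marker_rate, emg_rate = emg_rate,
      lead_s = lead_s, tail_s = tail_s, seed = seed
    ),
    class = "gait_scenario"
  )
  validate_scenario(spec)
  spec
}

validate_scenario <- function(spec) {
  if (spec$n_subjects < 1) abort("'n_subjects' must be >= 1")
  if (spec$strides_per_session < 2) abort("'strides_per_session' must be >= 2")
  if (spec$stance_fraction_mean <= 0 || spec$stance_fraction_mean >= 1) {
    abort("'stance_fraction_mean' must lie in (0, 1)")
  }
  if (spec$stride_duration_mean <= 3 * spec$stride_duration_sd) {
    abort(paste0(
      "'stride_duration_sd' too large: truncated-normal durations could ",
      "reach zero (need mean > 3 * SD)"
    ))
  }
  if (any(spec$gains$gain < 0)) abort("ground-truth gains must be >= 0")
  miss <- setdiff(spec$weeks, spec$week_kinematics$week)
  if (length(miss) > 0) {
    abort(sprintf("week_kinematics is missing week(s): %s", paste(miss, collapse = ", ")))
  }
  occ <- spec$noise$occlusion_rate
  if (occ < 0 || occ >= 1) abort("'occlusion_rate' must lie in [0, 1)")
  if (spec$noise$marker_sd < 0 || spec$noise$knee_artifact < 0) {
    abort("marker noise amplitudes must be >= 0")
  }
  invisible(spec)
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf(
    "<gait_scenario> %d subject(s) x %d week(s), %d strides/session, seed %s\n",
    x$n_subjects, length(x$weeks), x$strides_per_session, format(x$seed)
  ))
  invisible(x)
}

## Unimodal burst envelope on [0, 1]: cosine attack over the first
## `attack_frac` of the burst, cosine decay over the remainder. At
## attack_frac = 0.5 this is the standard raised cosine. The integral over
## the burst is 1/2 for every attack_frac, so closed-form burst integrals
## are shape-independent.
burst_shape <- function(w, attack_frac = 0.5) {
  a <- min(max(attack_frac, 1e-3), 1 - 1e-3)
  out <- numeric(length(w))
  up <- w < a
  out[up] <- 0.5 * (1 - cos(pi * w[up] / a))
  out[!up] <- 0.5 * (1 + cos(pi * (w[!up] - a) / (1 - a)))
  out
}

rot2 <- function(theta_deg, vx, vy) {
  th <- theta_deg * pi / 180
  list(x = vx * cos(th) - vy * sin(th), y = vx * sin(th) + vy * cos(th))
}

#' Forward kinematics: joint angles to sagittal markers
#'
#' Reconstructs hip, knee, ankle and toe marker positions from joint-angle
#' series, segment lengths and a pelvis pose, using the package's angle
#' conventions (0 deg = full flexion, 180 deg = full extension; the knee on
#' the anterior side of the hip-to-ankle line). The emitted chain satisfies
#' the segment-length constraints exactly, and re-measuring angles from the
#' emitted markers with [joint_angles()] returns the inputs to numerical
#' precision.
#'
#' @param angles Tibble with columns `hip`, `knee`, `ankle` (deg, all in
#'   `[0, 180]`) and optionally `time_s`.
#' @param geometry A [limb_geometry()].
#' @param pelvis Tibble with columns `rostral_pelvis_x/_y`,
#'   `caudal_pelvis_x/_y`, `hip_x/_y` (mm), one row per frame (or one row
#'   recycled).
#' @return A sagittal pose tibble (`time_s`, six `<marker>_x/_y` columns).
#' @export
forward_kinematics <- function(angles, geometry, pelvis) {
  stopifnot(inherits(geometry, "limb_geometry"))
  n <- nrow(angles)
  if (nrow(pelvis) == 1 && n > 1) {
    pelvis <- pelvis[rep(1, n), ]
  }
  stopifnot(nrow(pelvis) == n)
  for (col in c("hip", "knee", "ankle")) {
    a <- angles[[col]]
    if (any(!is.na(a) & (a < 0 | a > 180))) {
      abort(sprintf("'%s' angles must lie in [0, 180] degrees", col))
    }
  }
  ux <- pelvis$rostral_pelvis_x - pelvis$hip_x
  uy <- pelvis$rostral_pelvis_y - pelvis$hip_y
  nu <- sqrt(ux^2 + uy^2)
  ux <- ux / nu; uy <- uy / nu
  ## thigh: clockwise from the hip->rostral-pelvis direction by the hip angle
  th <- rot2(-angles$hip, ux, uy)
  knee_x <- pelvis$hip_x + geometry$femur_length * th$x
  knee_y <- pelvis$hip_y + geometry$femur_length * th$y
  ## shank: counter-clockwise from knee->hip by the knee angle puts the knee
  ## on the anterior side of the hip--ankle line
  sh <- rot2(angles$knee, -th$x, -th$y)
  ankle_x <- knee_x + geometry$tibia_length * sh$x
  ankle_y <- knee_y + geometry$tibia_length * sh$y
  ## foot: clockwise from ankle->knee by the ankle angle
  ft <- rot2(-angles$ankle, -sh$x, -sh$y)
  toe_x <- ankle_x + geometry$foot_length * ft$x
  toe_y <- ankle_y + geometry$foot_length * ft$y
  tibble(
    time_s = if ("time_s" %in% names(angles)) angles$time_s else (seq_len(n) - 1),
    rostral_pelvis_x = pelvis$rostral_pelvis_x,
    rostral_pelvis_y = pelvis$rostral_pelvis_y,
    caudal_pelvis_x = pelvis$caudal_pelvis_x,
    caudal_pelvis_y = pelvis$caudal_pelvis_y,
    hip_x = pelvis$hip_x, hip_y = pelvis$hip_y,
    knee_x = knee_x, knee_y = knee_y,
    ankle_x = ankle_x, ankle_y = ankle_y,
    toe_x = toe_x, toe_y = toe_y
  )
}

## Phase bookkeeping: stride index (0 = before, n+1 = after) and within-
## stride phase in [0, 1) for each time stamp.
stride_phase <- function(t, boundaries) {
  n <- length(boundaries) - 1L
  i <- findInterval(t, boundaries)
  p <- rep(0, length(t))
  inside <- i >= 1L & i <= n
  p[inside] <- (t[inside] - boundaries[i[inside]]) /
    (boundaries[i[inside] + 1L] - boundaries[i[inside]])
  list(stride = i, phase = p, inside = inside)
}

#' Synthesize multi-channel EMG for one trial
#'
#' Generates the seven-muscle EMG of one recording: each channel is a
#' zero-mean band-limited Gaussian carrier (unit RMS) multiplied by a
#' deterministic amplitude envelope (tonic baseline plus one raised-cosine
#' burst per stride, scaled by the muscle's gain), plus residual 60 Hz line
#' interference and sparse large cable-strike artifacts. The expected
#' rectified envelope equals `sqrt(2 / pi)` times the amplitude envelope, so
#' the expected integrated burst scales linearly with the gain.
#'
#' @param boundaries Stride boundaries (s), length n_strides + 1, strictly
#'   increasing.
#' @param total_s Total record duration (s).
#' @param burst_spec Burst table as in [gait_scenario()].
#' @param gains Named numeric vector: effective per-muscle burst gain for
#'   this trial (>= 0).
#' @param stride_gain_jitter Matrix (n_strides x muscles, dimnames muscle)
#'   of multiplicative stride-level gain factors, or `NULL` for none.
#' @param noise Noise list as in [gait_scenario()].
#' @param emg_rate Sampling rate (Hz).
#' @return A tibble with `time_s` and one column per muscle (mV). Uses the
#'   current RNG state; seed upstream for reproducibility.
#' @export
synth_emg <- function(boundaries, total_s, burst_spec, gains,
                      stride_gain_jitter = NULL, noise = gait_scenario()$noise,
                      emg_rate = 5000) {
  if (any(diff(boundaries) <= 0)) abort("stride boundaries must be strictly increasing")
  n_str <- length(boundaries) - 1L
  ne <- round(total_s * emg_rate)
  t <- (seq_len(ne) - 1) / emg_rate
  ph <- stride_phase(t, boundaries)
  band <- noise$carrier_band
  carrier_flt <- signal::butter(4, band / (emg_rate / 2), type = "pass")
  carriers <- synth_carriers(list(carrier_flt), ne, length(burst_spec$muscle))
  colnames(carriers) <- burst_spec$muscle
  out <- list(time_s = t)
  for (m in burst_spec$muscle) {
    bs <- burst_spec[burst_spec$muscle == m, ]
    g <- unname(gains[[m]])
    jit <- if (is.null(stride_gain_jitter)) rep(1, n_str) else stride_gain_jitter[, m]
    env <- rep(bs$baseline_mv, ne)
    sel <- ph$inside & ph$phase >= bs$on_frac & ph$phase <= bs$off_frac
    if (any(sel) && g > 0) {
      w <- (ph$phase[sel] - bs$on_frac) / (bs$off_frac - bs$on_frac)
      env[sel] <- env[sel] +
        bs$amp_mv * g * jit[ph$stride[sel]] * burst_shape(w, bs$attack_frac %||% 0.5)
    }
    ## sparse cable-strike artifacts
    if (noise$artifact_rate > 0 && n_str > 0) {
      hit <- runif(n_str) < noise$artifact_rate / length(burst_spec$muscle)
      for (i in which(hit)) {
        t0 <- boundaries[i] +
          runif(1) * max(0, diff(boundaries)[i] - noise$artifact_dur)
        asel <- t >= t0 & t <= t0 + noise$artifact_dur
        aw <- (t[asel] - t0) / noise$artifact_dur
        env[asel] <- env[asel] +
          noise$artifact_amp * bs$amp_mv * 0.5 * (1 - cos(2 * pi * aw))
      }
    }
    carrier <- carriers[, m]
    line <- if (noise$line_amp > 0) {
      noise$line_amp * sin(2 * pi * 60 * t + runif(1) * 2 * pi)
    } else 0
    out[[m]] <- carrier * env + line
  }
  as_tibble(out)
}

#' Generate a synthetic locomotion experiment with ground truth
#'
#' Simulates one [trial_recording()] per subject and week according to a
#' [gait_scenario()], together with the ground truth every downstream stage
#' can be checked against: true stride boundaries and stance intervals, true
#' joint-angle series, the true (artifact-free) knee path, and the effective
#' per-muscle burst gains.
#'
#' The limb is built from an endpoint path: during stance the ankle travels
#' rearward with the belt at constant height; during swing it returns along
#' a smooth profile with a lift. The knee follows exactly from the segment
#' lengths (anterior two-circle branch), so artifact-free markers lie on the
#' true kinematic chain. Noise is then injected: Gaussian marker noise, a
#' stride-locked low-frequency skin-movement displacement added to the knee
#' marker only, and random occlusion runs (masked samples).
#'
#' @param spec A [gait_scenario()].
#' @return A list with elements `trials` (named list of
#'   [trial_recording()]s, names `<subject>_<week>`) and `truth` (named list
#'   with, per trial, `strides` (tibble: `stride_id`, `start`, `end`,
#'   `foot_strike`, `foot_off`, `stance_frac`, `duration`), `gains` (tibble:
#'   `muscle`, `gain` nominal, `gain_effective`), `angles` (tibble of true
#'   joint angles and limb features per frame) and `knee_true` (tibble of
#'   the artifact-free knee path)).
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "gait_scenario"))
  set.seed(spec$seed)
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  ssd <- spec$subject_sd
  subj <- tibble(
    subject = subjects,
    dur_off = rnorm(spec$n_subjects, 0, ssd$duration),
    stance_off = rnorm(spec$n_subjects, 0, ssd$stance),
    log_exc_off = rnorm(spec$n_subjects, 0, ssd$log_excursion),
    log_gain_int = rnorm(spec$n_subjects, 0, ssd$log_gain_int),
    log_gain_slope = rnorm(spec$n_subjects, 0, ssd$log_gain_slope)
  )
  trials <- list()
  truth <- list()
  for (si in seq_len(spec$n_subjects)) {
    for (w in spec$weeks) {
      id <- paste0(subjects[si], "_", w)
      gen <- generate_trial(spec, subj[si, ], w, si)
      trials[[id]] <- gen$trial
      truth[[id]] <- gen$truth
    }
  }
  list(trials = trials, truth = truth)
}

generate_trial <- function(spec, subj, week, session_idx) {
  g <- spec$geometry
  wk <- spec$week_kinematics[spec$week_kinematics$week == week, ]
  n_str <- spec$strides_per_session
  belt_mm_s <- spec$belt_speed * 1000 / 60
  sesd <- spec$session_sd
  strsd <- spec$stride_sd

  ## session-level factors (day effects)
  sess_stance <- rnorm(1, 0, sesd$stance)
  sess_exc <- rnorm(1, 0, sesd$log_excursion)
  sess_gain <- rnorm(1, 0, sesd$log_gain)

  ## stride durations: truncated normal (+- 3 SD)
  m_dur <- spec$stride_duration_mean + subj$dur_off
  if (m_dur <= 3 * spec$stride_duration_sd) {
    abort("subject stride-duration mean too close to zero for the requested SD")
  }
  dur <- rnorm(n_str, m_dur, spec$stride_duration_sd)
  bad <- abs(dur - m_dur) > 3 * spec$stride_duration_sd
  while (any(bad)) {
    dur[bad] <- rnorm(sum(bad), m_dur, spec$stride_duration_sd)
    bad <- abs(dur - m_dur) > 3 * spec$stride_duration_sd
  }
  b <- spec$lead_s + cumsum(c(0, dur))
  total_s <- spec$lead_s + sum(dur) + spec$tail_s

  ## stance fractions and excursions
  cfrac <- pmin(0.8, pmax(0.35, rnorm(
    n_str, spec$stance_fraction_mean + subj$stance_off + wk$stance_delta + sess_stance,
    spec$stance_fraction_sd
  )))
  exc_scale <- wk$excursion_scale *
    exp(subj$log_exc_off + sess_exc + rnorm(n_str, 0, strsd$log_excursion))
  E_raw <- belt_mm_s * cfrac * dur * exc_scale
  ## cap the excursion so the chain stays inside triangulation feasibility
  reach <- g$femur_length + g$tibia_length
  E_cap <- 1.98 * sqrt(max(0, (reach - 5)^2 -
                             (spec$hip_clearance + spec$pelvis_bob)^2))
  E <- pmin(E_raw, E_cap)

  ## marker-frame kinematics
  nm <- round(total_s * spec$marker_rate)
  tm <- (seq_len(nm) - 1) / spec$marker_rate
  ph <- stride_phase(tm, b)
  idx <- ph$stride
  p <- ph$phase
  ## per-frame stride parameters (edge frames borrow the nearest stride)
  i_near <- pmin(pmax(idx, 1L), n_str)
  Ei <- E[i_near]; ci <- cfrac[i_near]
  x_strike <- Ei / 2
  x0_swing <- -c(E[1], E[seq_len(n_str - 1)])[i_near] / 2 # previous stance end
  A_sw <- spec$ankle_swing_amp + wk$ankle_amp_delta
  phi0 <- spec$foot_angle_deg
  y_ankle0 <- -g$foot_length * sin(phi0 * pi / 180) # toe on ground at y = 0

  swing <- ph$inside & p < (1 - ci)
  stance <- ph$inside & !swing
  s <- rep(0, nm)
  s[swing] <- p[swing] / (1 - ci[swing])
  u <- rep(0, nm)
  u[stance] <- (p[stance] - (1 - ci[stance])) / ci[stance]

  ankle_x <- rep(NA_real_, nm)
  ankle_y <- rep(y_ankle0, nm)
  phi <- rep(phi0, nm)
  prof <- s[swing] - sin(2 * pi * s[swing]) / (2 * pi)
  ankle_x[swing] <- x0_swing[swing] + (x_strike[swing] - x0_swing[swing]) * prof
  ankle_y[swing] <- y_ankle0 + spec$swing_lift * sin(pi * s[swing])^2
  phi[swing] <- phi0 - A_sw * sin(pi * s[swing])
  ankle_x[stance] <- x_strike[stance] - Ei[stance] * u[stance]
  outside <- !ph$inside
  ankle_x[outside & tm < b[1]] <- -E[1] / 2
  ankle_x[outside & tm >= b[1]] <- -E[n_str] / 2

  hip_x <- rep(0, nm)
  hip_y <- y_ankle0 + spec$hip_clearance + spec$pelvis_bob * sin(2 * pi * p)
  rp_x <- hip_x + 25; rp_y <- hip_y + 15
  cp_x <- hip_x - 12; cp_y <- hip_y + 17
  toe_x <- ankle_x + g$foot_length * cos(phi * pi / 180)
  toe_y <- ankle_y + g$foot_length * sin(phi * pi / 180)

  tri <- triangulate_knee(cbind(hip_x, hip_y), cbind(ankle_x, ankle_y), g)
  if (!all(tri$feasible)) {
    abort("internal error: synthetic limb configuration left the feasible region")
  }
  knee_x <- tri$knee[, 1]; knee_y <- tri$knee[, 2]

  pose_true <- tibble(
    time_s = tm,
    rostral_pelvis_x = rp_x, rostral_pelvis_y = rp_y,
    caudal_pelvis_x = cp_x, caudal_pelvis_y = cp_y,
    hip_x = hip_x, hip_y = hip_y, knee_x = knee_x, knee_y = knee_y,
    ankle_x = ankle_x, ankle_y = ankle_y, toe_x = toe_x, toe_y = toe_y
  )
  angles_true <- joint_angles(pose_true)

  ## ---- noise injection -------------------------------------------------
  noise <- spec$noise
  markers <- pose_true
  ## skin-movement artifact: stride-locked low-frequency displacement of the
  ## knee marker only (the channel triangulation is meant to replace)
  markers$knee_x <- markers$knee_x + noise$knee_artifact * sin(2 * pi * p + 0.8)
  markers$knee_y <- markers$knee_y + 0.4 * noise$knee_artifact * sin(2 * pi * p + 2.0)
  wide <- tibble(time_s = tm)
  for (mk in GAIT_MARKERS) {
    wide[[paste0(mk, "_x")]] <- markers[[paste0(mk, "_x")]] +
      rnorm(nm, 0, noise$marker_sd)
    wide[[paste0(mk, "_y")]] <- markers[[paste0(mk, "_y")]] +
      rnorm(nm, 0, noise$marker_sd)
    wide[[paste0(mk, "_z")]] <- spec$lateral_offset + rnorm(nm, 0, noise$marker_sd)
  }
  ## occlusion runs per marker mask all three coordinates
  if (noise$occlusion_rate > 0) {
    for (mk in GAIT_MARKERS) {
      starts <- which(runif(nm) < noise$occlusion_rate)
      if (length(starts) > 0) {
        lens <- 1 + stats::rgeom(length(starts), 1 / noise$occlusion_mean_run)
        mask <- rep(FALSE, nm)
        for (k in seq_along(starts)) {
          mask[starts[k]:min(nm, starts[k] + lens[k] - 1L)] <- TRUE
        }
        for (ax in c("_x", "_y", "_z")) {
          wide[[paste0(mk, ax)]][mask] <- NA_real_
        }
      }
    }
  }

  ## ---- EMG -------------------------------------------------------------
  wknum <- week_num(week)
  gain_eff <- vapply(GAIT_MUSCLES, function(m) {
    nominal <- spec$gains$gain[spec$gains$muscle == m & spec$gains$week == week]
    if (length(nominal) == 0) nominal <- 1
    nominal * exp(subj$log_gain_int + subj$log_gain_slope * wknum + sess_gain)
  }, numeric(1))
  jit <- matrix(
    exp(rnorm(n_str * length(GAIT_MUSCLES), 0, strsd$log_gain)),
    n_str, length(GAIT_MUSCLES), dimnames = list(NULL, GAIT_MUSCLES)
  )
  emg <- synth_emg(b, total_s, spec$burst_spec, as.list(gain_eff),
                   stride_gain_jitter = jit, noise = noise,
                   emg_rate = spec$emg_rate)
  trial <- trial_recording(
    subject = subj$subject, week = week,
    session = sprintf("%s_%s", subj$subject, week),
    markers = wide, emg = emg,
    marker_rate = spec$marker_rate, emg_rate = spec$emg_rate,
    belt_speed = spec$belt_speed, geometry = g
  )
  nominal <- vapply(GAIT_MUSCLES, function(m) {
    v <- spec$gains$gain[spec$gains$muscle == m & spec$gains$week == week]
    if (length(v) == 0) 1 else v
  }, numeric(1))
  truth <- list(
    strides = tibble(
      stride_id = seq_len(n_str),
      start = b[-length(b)], end = b[-1],
      foot_strike = b[-length(b)] + (1 - cfrac) * dur,
      foot_off = b[-1],
      stance_frac = cfrac, duration = dur
    ),
    gains = tibble(muscle = GAIT_MUSCLES, gain = unname(nominal),
                   gain_effective = unname(gain_eff)),
    angles = angles_true,
    knee_true = tibble(time_s = tm, knee_x = knee_x, knee_y = knee_y)
  )
  list(trial = trial, truth = truth)
}

#' Simulate stride-level EMG features directly
#'
#' A fast feature-level counterpart of the full signal generator: draws
#' normalized integrated-EMG values straight from the mixed-effects
#' generative model (log-normal stride noise, subject random intercept and
#' slope, session effects shared across muscles), skipping signal synthesis.
#' Intended for Monte-Carlo calibration and power studies of the
#' statistical layer, where hundreds of replicate experiments are needed.
#'
#' @param gains Tibble with columns `muscle`, `week`, `gain` (> 0): the true
#'   mean normalized activity per muscle and week.
#' @param n_subjects Number of subjects.
#' @param strides_per_cell Strides per subject, week and muscle.
#' @param sd_subject_int,sd_subject_slope,sd_session,sd_resid Log-scale SDs
#'   of the subject intercept, subject slope (per week unit), session
#'   effect and stride residual.
#' @param seed Optional integer seed.
#' @return A long feature tibble (`subject`, `week`, `session`, `stride_id`,
#'   `feature` = `int_emg_<muscle>`, `value`).
#' @export
simulate_emg_features <- function(gains, n_subjects = 6, strides_per_cell = 50,
                                  sd_subject_int = 0.10, sd_subject_slope = 0.03,
                                  sd_session = 0.08, sd_resid = 0.35,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weeks <- unique(gains$week)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  b0 <- rnorm(n_subjects, 0, sd_subject_int)
  b1 <- rnorm(n_subjects, 0, sd_subject_slope)
  rows <- tidyr::expand_grid(
    subject = subjects, week = weeks,
    muscle = unique(gains$muscle), stride_id = seq_len(strides_per_cell)
  ) |>
    left_join(gains, by = c("muscle", "week"))
  sess <- rows |>
    distinct(.data$subject, .data$week) |>
    mutate(u_sess = rnorm(n(), 0, sd_session))
  rows |>
    left_join(sess, by = c("subject", "week")) |>
    mutate(
      si = match(.data$subject, subjects),
      value = exp(log(.data$gain) + b0[.data$si] +
                    b1[.data$si] * week_num(.data$week) + .data$u_sess +
                    rnorm(n(), 0, sd_resid)),
      session = paste0(.data$subject, "_", .data$week),
      feature = paste0("int_emg_", .data$muscle)
    ) |>
    select("subject", "week", "session", "stride_id", "feature", "value")
}

#' Simulate a paired muscle-mass table
#'
#' Draws wet masses (g) of the quadriceps muscles in the instrumented
#' (`ipsi`) and contralateral (`contra`) limb for `n_subjects` animals. The
#' default effects mirror the adaptation scenario: marked atrophy of the
#' denervated VL, modest use-dependent growth of RF, and no change in VM or
#' VI. Clearly synthetic: means and effects are package defaults, not
#' measurements.
#'
#' @param n_subjects Number of animals.
#' @param base_mass_g Named vector of contralateral mean masses (g).
#' @param ipsi_factor Named vector of ipsilateral/contralateral mass ratios.
#' @param size_sd,meas_sd Log-scale SDs of animal size and per-measurement
#'   error.
#' @param seed Optional integer seed.
#' @return A tibble with columns `subject`, `muscle`, `side`, `mass_g`.
#' @export
simulate_mass_table <- function(n_subjects = 6,
                                base_mass_g = c(VL = 2.2, RF = 1.5, VM = 1.3, VI = 0.35),
                                ipsi_factor = c(VL = 0.65, RF = 1.10, VM = 1.0, VI = 1.0),
                                size_sd = 0.08, meas_sd = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  size <- exp(rnorm(n_subjects, 0, size_sd))
  rows <- tidyr::expand_grid(
    subject = subjects, muscle = names(base_mass_g), side = c("ipsi", "contra")
  )
  rows |>
    mutate(
      si = match(.data$subject, subjects),
      mass_g = unname(base_mass_g[.data$muscle]) * size[.data$si] *
        ifelse(.data$side == "ipsi", unname(ipsi_factor[.data$muscle]), 1) *
        exp(rnorm(n(), 0, meas_sd))
    ) |>
    select("subject", "muscle", "side", "mass_g")
}
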