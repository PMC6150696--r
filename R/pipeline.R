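## Envelope threshold shared by onset detection and burst-window location:
## quiet-floor mean + k SDs, floored at a fraction of the 95th percentile.
envelope_threshold <- function(env, cfg) {
  qs <- quantile(env, c(cfg$onset_quiet_quantile, 0.95), names = FALSE, type = 7)
  fl <- env[env <= qs[1]]
  thr <- mean(fl) + cfg$onset_k_sd * sd(fl)
  if (!is.finite(thr)) thr <- 0
  max(thr, cfg$onset_min_level_frac * qs[2])
}

#' Process one trial into stride-level features
#'
#' Runs the full single-recording chain: EMG conditioning and envelopes, TA
#' onset detection, marker filtering, sagittal projection, knee
#' triangulation, joint angles, stance detection, stride segmentation,
#' inclusion screening, time normalization and feature extraction.
#'
#' @param trial A [trial_recording()].
#' @param cfg A [gait_config()].
#' @return A list: `features` (long tibble of raw per-stride features),
#'   `strides` (the stride ledger with inclusion flags), `angles` (the
#'   per-frame joint-angle series), `stance` (detected stance intervals)
#'   and `onsets` (TA onsets).
#' @export
process_trial <- function(trial, cfg = gait_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  env <- trial_envelopes(trial, cfg)
  onsets <- detect_onsets(env$TA, trial$emg_rate, cfg)
  filt <- lowpass_markers(trial$markers, trial$marker_rate, cfg)
  pose <- reconstruct_knee(project_sagittal(filt), trial$geometry)
  ang <- joint_angles(pose)
  stance <- detect_stance(pose$toe_x, trial$marker_rate, trial$belt_speed, cfg)
  strides <- segment_strides(onsets, stance)
  empty <- list(
    features = tibble(subject = character(0), week = character(0),
                      session = character(0), stride_id = integer(0),
                      feature = character(0), value = numeric(0)),
    strides = strides, angles = ang, stance = stance, onsets = onsets
  )
  if (nrow(strides) == 0) return(empty)

  mrate <- trial$marker_rate
  erate <- trial$emg_rate
  n_env <- nrow(env)
  n_ang <- nrow(ang)
  ## per-stride envelope maxima (all muscles) for the artifact screen
  seg_env <- function(t0, t1) {
    i0 <- max(1L, 1L + as.integer(ceiling(t0 * erate - 1e-9)))
    i1 <- min(n_env, 1L + as.integer(floor(t1 * erate + 1e-9)))
    if (i1 < i0) integer(0) else i0:i1
  }
  seg_ang <- function(t0, t1) {
    i0 <- max(1L, 1L + as.integer(ceiling(t0 * mrate - 1e-9)))
    i1 <- min(n_ang, 1L + as.integer(floor(t1 * mrate + 1e-9)))
    if (i1 < i0) integer(0) else i0:i1
  }
  ns <- nrow(strides)
  env_mat <- as.matrix(env[GAIT_MUSCLES])
  max_mat <- matrix(NA_real_, ns, length(GAIT_MUSCLES),
                    dimnames = list(NULL, GAIT_MUSCLES))
  pose_channels <- GAIT_MARKERS
  miss_mat <- matrix(1, ns, length(pose_channels),
                     dimnames = list(NULL, pose_channels))
  pose_na <- vapply(pose_channels, function(ch) {
    is.na(pose[[paste0(ch, "_x")]]) | is.na(pose[[paste0(ch, "_y")]])
  }, logical(nrow(pose)))
  for (i in seq_len(ns)) {
    idx <- seg_env(strides$start[i], strides$end[i])
    if (length(idx) > 0) {
      max_mat[i, ] <- suppressWarnings(apply(env_mat[idx, , drop = FALSE], 2, max))
    }
    aidx <- seg_ang(strides$start[i], strides$end[i])
    if (length(aidx) > 0) {
      miss_mat[i, ] <- colMeans(pose_na[aidx, , drop = FALSE])
    }
  }
  emg_maxima <- tibble(
    stride_id = rep(strides$stride_id, each = length(GAIT_MUSCLES)),
    muscle = rep(GAIT_MUSCLES, ns),
    max_mv = as.vector(t(max_mat))
  )
  kin_missing <- tibble(
    stride_id = rep(strides$stride_id, each = length(pose_channels)),
    channel = rep(pose_channels, ns),
    missing_frac = as.vector(t(miss_mat))
  )
  strides <- include_strides(strides, emg_maxima, kin_missing, cfg)

  thresholds <- vapply(GAIT_MUSCLES, function(m) envelope_threshold(env[[m]], cfg),
                       numeric(1))
  ang_signals <- ang # time_s + hip/knee/ankle/limb_length/limb_angle
  L <- cfg$normalized_length

  feat_list <- lapply(which(strides$included), function(i) {
    st <- strides[i, ]
    vals <- list()
    vals$stance_pct <- stance_percentage(st$duration, st$foot_strike, st$foot_off)
    aidx <- seg_ang(st$start, st$end)
    for (j in c("hip", "knee", "ankle")) {
      vals[[paste0("rom_", j)]] <- range_of_motion(ang[[j]][aidx])
    }
    norm <- normalize_stride(ang_signals[aidx, ], st$start, st$end, L)
    if (!is.na(st$foot_off)) {
      es <- angles_at_event(norm, min(1, (st$foot_off - st$start) / st$duration))
      vals$hip_at_end_stance <- es$hip
      vals$knee_at_end_stance <- es$knee
      vals$ankle_at_end_stance <- es$ankle
      vals$limb_length_end_stance <- es$limb_length
      vals$limb_angle_end_stance <- es$limb_angle
      ## mid-burst event: midpoint of the quadriceps extension-burst window
      qm <- cfg$burst_muscle
      eidx <- seg_env(st$start, st$end)
      bw <- burst_window(env$time_s[eidx], env[[qm]][eidx], st$start,
                         st$foot_strike, st$foot_off, thresholds[[qm]],
                         fallback = cfg$burst_fallback)
      if (!is.na(bw$window_start)) {
        mid_frac <- ((bw$window_start + bw$window_end) / 2 - st$start) / st$duration
        mb <- angles_at_event(norm, min(1, max(0, mid_frac)))
        vals$hip_at_mid_burst <- mb$hip
        vals$knee_at_mid_burst <- mb$knee
        vals$ankle_at_mid_burst <- mb$ankle
        vals$limb_length_mid_burst <- mb$limb_length
        vals$limb_angle_mid_burst <- mb$limb_angle
      }
      eidx_off <- seg_env(st$start, min(st$end, st$foot_off))
      for (m in GAIT_MUSCLES) {
        bwm <- burst_window(env$time_s[eidx_off], env[[m]][eidx_off], st$start,
                            st$foot_strike, st$foot_off, thresholds[[m]],
                            fallback = cfg$burst_fallback)
        vals[[paste0("raw_int_emg_", m)]] <- integrate_envelope(
          env$time_s[eidx], env[[m]][eidx], bwm$window_start, bwm$window_end
        )
      }
    }
    list(stride_id = st$stride_id, feature = names(vals),
         value = unlist(vals, use.names = FALSE))
  })
  nf <- vapply(feat_list, function(v) length(v$feature), integer(1))
  feat_rows <- tibble(
    subject = trial$subject, week = trial$week, session = trial$session,
    stride_id = rep(vapply(feat_list, `[[`, integer(1), "stride_id"), nf),
    feature = unlist(lapply(feat_list, `[[`, "feature")),
    value = unlist(lapply(feat_list, `[[`, "value"))
  )

  list(features = feat_rows, strides = strides, angles = ang,
       stance = stance, onsets = onsets)
}

#' Analyze a set of trials end to end
#'
#' Processes every trial with [process_trial()], pools the per-stride
#' features, normalizes integrated EMG to each subject's baseline and
#' assembles a run manifest with per-stage counts.
#'
#' @param trials List of [trial_recording()]s.
#' @param cfg A [gait_config()].
#' @param baseline_week Pre-perturbation condition label.
#' @return A list: `features` (long tibble, raw and normalized),
#'   `strides` (pooled ledger with subject/week/session columns) and
#'   `manifest` (named list of counts; segmented = included + excluded).
#' @export
analyze_experiment <- function(trials, cfg = gait_config(), baseline_week = "base") {
  results <- lapply(trials, process_trial, cfg = cfg)
  features <- bind_rows(lapply(results, `[[`, "features"))
  ledgers <- purrr::imap(results, function(r, id) {
    tr <- trials[[id]]
    mutate(r$strides, subject = tr$subject, week = tr$week,
           session = tr$session, .before = 1)
  })
  strides <- bind_rows(ledgers)
  features <- normalize_to_baseline(features, baseline_week = baseline_week)
  reasons <- unlist(strsplit(strides$exclusion_reasons[strides$exclusion_reasons != ""], ","))
  manifest <- list(
    trials_read = length(trials),
    strides_segmented = nrow(strides),
    strides_included = sum(strides$included),
    strides_excluded = sum(!strides$included),
    excluded_duration_outlier = sum(reasons == "duration_outlier"),
    excluded_emg_artifact = sum(reasons == "emg_artifact"),
    excluded_kinematic_missing = sum(reasons == "kinematic_missing"),
    features_emitted = nrow(features)
  )
  list(features = features, strides = strides, manifest = manifest)
}

#' Write a synthetic experiment to disk
#'
#' Generates an experiment from a [gait_scenario()] and writes one trial
#' directory per subject and week (`markers.tsv`, `emg.tsv`, `meta.yaml`),
#' plus `ground_truth_strides.tsv`, `ground_truth_gains.tsv` and a
#' `manifest.yaml`. Identical scenarios (same seed) produce byte-identical
#' trees.
#'
#' @param spec A [gait_scenario()].
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
write_synthetic_experiment <- function(spec, out_dir) {
  gen <- generate_experiment(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(gen$trials)) {
    write_trial(gen$trials[[id]], file.path(out_dir, id))
  }
  truth_strides <- purrr::imap(gen$truth, function(tr, id) {
    t0 <- gen$trials[[id]]
    mutate(tr$strides, subject = t0$subject, week = t0$week, .before = 1)
  }) |> bind_rows()
  truth_gains <- purrr::imap(gen$truth, function(tr, id) {
    t0 <- gen$trials[[id]]
    mutate(tr$gains, subject = t0$subject, week = t0$week, .before = 1)
  }) |> bind_rows()
  write_num_tsv(truth_strides, file.path(out_dir, "ground_truth_strides.tsv"))
  write_num_tsv(truth_gains, file.path(out_dir, "ground_truth_gains.tsv"))
  manifest <- list(
    generator = "stridelab", seed = spec$seed,
    n_subjects = spec$n_subjects, weeks = spec$weeks,
    strides_per_session = spec$strides_per_session,
    trials_written = length(gen$trials)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the full analysis pipeline over a data directory
#'
#' Reads every trial directory under `data_dir` (any directory containing
#' `markers.tsv`, `emg.tsv` and `meta.yaml`), runs [analyze_experiment()],
#' fits the standard models (one kinematic mixed model per feature in
#' `kinematic_features`, and the two-muscle EMG model), and writes
#' `features.tsv`, `strides.tsv`, `contrasts_kinematic.tsv`,
#' `contrasts_emg.tsv` and `manifest.yaml` under `out_dir`.
#'
#' @param data_dir Directory of trial subdirectories.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [gait_config()].
#' @param kinematic_features Features to model individually.
#' @param emg_muscles Two muscles for the EMG model.
#' @param baseline_week Pre-perturbation condition label.
#' @return A list with `features`, `strides`, `manifest`, `fits` and
#'   `contrasts`, invisibly.
#' @export
run_pipeline <- function(data_dir, out_dir, cfg = gait_config(),
                         kinematic_features = c("stance_pct", "rom_hip",
                                                "rom_knee", "rom_ankle"),
                         emg_muscles = c("VM", "RF"),
                         baseline_week = "base") {
  dirs <- list.dirs(data_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "markers.tsv")) &
                 file.exists(file.path(dirs, "emg.tsv")) &
                 file.exists(file.path(dirs, "meta.yaml"))]
  if (length(dirs) == 0) abort(sprintf("no trial directories found under %s", data_dir))
  trials <- lapply(dirs, function(d) {
    read_trial(file.path(d, "markers.tsv"), file.path(d, "emg.tsv"),
               file.path(d, "meta.yaml"))
  })
  names(trials) <- basename(dirs)
  res <- analyze_experiment(trials, cfg, baseline_week = baseline_week)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(res$features, file.path(out_dir, "features.tsv"))
  write_num_tsv(res$strides, file.path(out_dir, "strides.tsv"))
  if (res$manifest$strides_included == 0) {
    yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
    abort("no strides survived the inclusion criteria (ledger written)")
  }
  fits <- list()
  contrasts <- list()
  for (f in kinematic_features) {
    fit <- tryCatch(fit_kinematic_lmem(res$features, f, baseline_week = baseline_week),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("kinematic model for '%s' failed: %s", f, conditionMessage(fit)))
      next
    }
    fits[[f]] <- fit
    contrasts[[f]] <- mutate(week_contrasts(fit), feature = f, .before = 1)
  }
  emg_fit <- tryCatch(
    fit_emg_lmem(res$features, muscles = emg_muscles, baseline_week = baseline_week),
    error = function(e) e
  )
  if (inherits(emg_fit, "error")) {
    warn(sprintf("EMG model failed: %s", conditionMessage(emg_fit)))
    emg_ct <- NULL
  } else {
    fits$emg <- emg_fit
    emg_ct <- emg_contrasts(emg_fit)
  }
  if (length(contrasts) > 0) {
    write_num_tsv(bind_rows(contrasts), file.path(out_dir, "contrasts_kinematic.tsv"))
  }
  if (!is.null(emg_ct)) {
    write_num_tsv(emg_ct, file.path(out_dir, "contrasts_emg.tsv"))
  }
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(features = res$features, strides = res$strides,
                 manifest = res$manifest, fits = fits,
                 contrasts = c(contrasts, list(emg = emg_ct))))
}
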