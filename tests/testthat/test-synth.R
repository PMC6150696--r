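test_that("identical seeds give identical experiments", {
  s1 <- tiny_scenario(n_subjects = 2, weeks = c("base", "week1"), seed = 7)
  s2 <- tiny_scenario(n_subjects = 2, weeks = c("base", "week1"), seed = 7)
  g1 <- generate_experiment(s1)
  g2 <- generate_experiment(s2)
  expect_identical(g1$trials[[3]]$markers, g2$trials[[3]]$markers)
  expect_identical(g1$trials[[3]]$emg, g2$trials[[3]]$emg)
  expect_identical(g1$truth[[2]]$strides, g2$truth[[2]]$strides)
  g3 <- generate_experiment(tiny_scenario(n_subjects = 2,
                                          weeks = c("base", "week1"), seed = 8))
  expect_false(identical(g1$trials[[1]]$emg, g3$trials[[1]]$emg))
})

test_that("noise-off markers lie exactly on the true kinematic chain", {
  spec <- tiny_scenario(seed = 3, noise = noise_off())
  gen <- generate_experiment(spec)
  mk <- gen$trials[[1]]$markers
  expect_false(anyNA(mk))
  femur <- sqrt((mk$knee_x - mk$hip_x)^2 + (mk$knee_y - mk$hip_y)^2)
  tibia <- sqrt((mk$knee_x - mk$ankle_x)^2 + (mk$knee_y - mk$ankle_y)^2)
  foot <- sqrt((mk$toe_x - mk$ankle_x)^2 + (mk$toe_y - mk$ankle_y)^2)
  expect_lt(max(abs(femur - 38)), 1e-9)
  expect_lt(max(abs(tibia - 42)), 1e-9)
  expect_lt(max(abs(foot - 20)), 1e-9)
})

test_that("experiment bookkeeping matches the scenario", {
  spec <- gait_scenario(n_subjects = 2, weeks = c("base", "week1"),
                        strides_per_session = 30, seed = 5)
  gen <- generate_experiment(spec)
  expect_length(gen$trials, 4)
  for (th in gen$truth) {
    expect_equal(nrow(th$strides), 30)
    expect_true(all(diff(th$strides$start) > 0))
    expect_true(all(th$strides$foot_strike > th$strides$start &
                      th$strides$foot_off <= th$strides$end + 1e-9))
  }
  expect_setequal(names(gen$trials),
                  c("S01_base", "S01_week1", "S02_base", "S02_week1"))
})

test_that("scenario validation rejects impossible parameters", {
  expect_error(gait_scenario(stride_duration_sd = 0.4), "zero")
  expect_error(gait_scenario(stance_fraction_mean = 1.2), "0, 1")
  expect_error(
    gait_scenario(gains = flat_gains(c("base", "week1", "week2", "week7"),
                                     RF_week1 = -2)),
    ">= 0"
  )
  expect_error(
    gait_scenario(noise = noise_clean(occlusion_rate = 1.5)),
    "occlusion_rate"
  )
})

test_that("forward kinematics respects the angle conventions", {
  g <- limb_geometry(38, 42, 20)
  pel <- tibble::tibble(rostral_pelvis_x = 25, rostral_pelvis_y = 85,
                        caudal_pelvis_x = -12, caudal_pelvis_y = 87,
                        hip_x = 0, hip_y = 70)
  # knee at 180 deg: hip, knee, ankle collinear
  ang <- tibble::tibble(hip = 90, knee = 180, ankle = 90)
  pose <- forward_kinematics(ang, g, pel)
  v1 <- c(pose$knee_x - pose$hip_x, pose$knee_y - pose$hip_y)
  v2 <- c(pose$ankle_x - pose$knee_x, pose$ankle_y - pose$knee_y)
  expect_lt(abs(v1[1] * v2[2] - v1[2] * v2[1]), 1e-9)
  # constant angles, stationary pelvis: constant markers
  angc <- tibble::tibble(hip = rep(95, 10), knee = rep(120, 10),
                         ankle = rep(100, 10))
  posec <- forward_kinematics(angc, g, pel)
  for (col in setdiff(names(posec), "time_s")) {
    expect_equal(diff(range(posec[[col]])), 0)
  }
  expect_error(
    forward_kinematics(tibble::tibble(hip = 200, knee = 90, ankle = 90), g, pel),
    "0, 180"
  )
})

test_that("forward kinematics and joint angles are mutually inverse", {
  set.seed(12)
  g <- limb_geometry(38, 42, 20)
  n <- 300
  ang <- tibble::tibble(
    time_s = (seq_len(n) - 1) / 200,
    hip = runif(n, 20, 160), knee = runif(n, 15, 178), ankle = runif(n, 15, 170)
  )
  pel <- tibble::tibble(rostral_pelvis_x = 25, rostral_pelvis_y = 85,
                        caudal_pelvis_x = -12, caudal_pelvis_y = 87,
                        hip_x = 0, hip_y = 70)
  pose <- forward_kinematics(ang, g, pel)
  back <- joint_angles(pose)
  expect_lt(max(abs(back$hip - ang$hip)), 1e-9)
  expect_lt(max(abs(back$knee - ang$knee)), 1e-9)
  expect_lt(max(abs(back$ankle - ang$ankle)), 1e-9)
})

test_that("an abolished muscle leaves only baseline noise", {
  spec <- tiny_scenario(
    weeks = "week1", seed = 9, noise = noise_off(),
    gains = flat_gains("week1", VL_week1 = 0)
  )
  gen <- generate_experiment(spec)
  emg <- gen$trials[[1]]$emg
  bs <- spec$burst_spec
  vl_floor <- bs$baseline_mv[bs$muscle == "VL"]
  # VL never exceeds a few baseline SDs; RF carries full bursts
  expect_lt(max(abs(emg$VL)), 6 * vl_floor)
  expect_gt(max(abs(emg$RF)), 50 * vl_floor)
})

test_that("expected integrated envelope scales linearly with gain", {
  mk_spec <- function(gain) {
    tiny_scenario(
      weeks = "week1", strides_per_session = 50, seed = 33,
      noise = noise_off(),
      gains = flat_gains("week1", RF_week1 = gain),
      subject_sd = list(duration = 0, stance = 0, log_excursion = 0,
                        log_gain_int = 0, log_gain_slope = 0),
      session_sd = list(log_gain = 0, stance = 0, log_excursion = 0),
      stride_sd = list(log_gain = 0, log_excursion = 0)
    )
  }
  int_rf <- function(spec) {
    gen <- generate_experiment(spec)
    tr <- gen$trials[[1]]
    th <- gen$truth[[1]]
    env <- trial_envelopes(tr)
    sum(vapply(seq_len(nrow(th$strides)), function(i) {
      st <- th$strides[i, ]
      integrate_envelope(env$time_s, env$RF, st$start, st$end)
    }, numeric(1)))
  }
  i1 <- int_rf(mk_spec(1))
  i2 <- int_rf(mk_spec(2))
  bs <- gait_scenario()$burst_spec
  rf <- bs[bs$muscle == "RF", ]
  # subtract the shared baseline-floor contribution before comparing slopes
  expect_equal(i2 / i1, 2, tolerance = 0.06)
  # absolute scale agrees with the closed form E|x| = sqrt(2/pi) * envelope
  spec <- mk_spec(1)
  gen <- generate_experiment(spec)
  th <- gen$truth[[1]]
  burst_area <- rf$amp_mv * (rf$off_frac - rf$on_frac) / 2 *
    sum(th$strides$duration)
  base_area <- rf$baseline_mv * sum(th$strides$duration)
  expect_equal(i1, sqrt(2 / pi) * (burst_area + base_area), tolerance = 0.05)
})

test_that("without line interference the spectrum has no 60 Hz peak", {
  spec0 <- tiny_scenario(weeks = "base", seed = 41,
                         noise = noise_off(line_amp = 0),
                         gains = flat_gains("base", TA_base = 0, VL_base = 0,
                                            VM_base = 0, RF_base = 0,
                                            SM_base = 0, BFp_base = 0,
                                            GRc_base = 0))
  spec1 <- tiny_scenario(weeks = "base", seed = 41,
                         noise = noise_off(line_amp = 0.05),
                         gains = spec0$gains)
  peak60 <- function(spec) {
    gen <- generate_experiment(spec)
    x <- gen$trials[[1]]$emg$RF
    n <- 2^14
    sp <- Mod(stats::fft(x[seq_len(n)]))[seq_len(n / 2)]
    fr <- (seq_len(n / 2) - 1) * 5000 / n
    band <- fr > 55 & fr < 65
    ref <- fr > 35 & fr < 55
    max(sp[band]) / stats::median(sp[ref])
  }
  expect_lt(peak60(spec0), 6)     # no distinct mains line above the carrier
  expect_gt(peak60(spec1), 50)    # injected line towers over the floor
})

test_that("the feature-level simulator reproduces its generative means", {
  gains <- flat_gains(c("base", "week1"))
  gains <- gains[gains$muscle %in% c("RF", "VM"), ]
  gains$gain[gains$muscle == "RF" & gains$week == "week1"] <- 2
  f <- simulate_emg_features(gains, n_subjects = 40, strides_per_cell = 40,
                             sd_subject_int = 0.05, sd_subject_slope = 0.01,
                             sd_session = 0.02, sd_resid = 0.3, seed = 2)
  m <- tapply(log(f$value), paste(f$feature, f$week), mean)
  expect_equal(unname(m[["int_emg_RF week1"]]), log(2), tolerance = 0.05)
  expect_equal(unname(m[["int_emg_VM week1"]]), 0, tolerance = 0.05)
  f2 <- simulate_emg_features(gains, seed = 2)
  f3 <- simulate_emg_features(gains, seed = 2)
  expect_identical(f2, f3)
})

test_that("the synthetic mass table shows the expected asymmetries", {
  m <- simulate_mass_table(n_subjects = 30, seed = 6)
  w <- tidyr::pivot_wider(m, names_from = "side", values_from = "mass_g")
  ratio <- tapply(w$ipsi / w$contra, w$muscle, mean)
  expect_lt(ratio[["VL"]], 0.75)
  expect_gt(ratio[["RF"]], 1.05)
  expect_equal(unname(ratio[["VM"]]), 1, tolerance = 0.05)
})
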