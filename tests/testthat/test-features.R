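test_that("stance percentage is the stance share of the cycle", {
  expect_equal(stance_percentage(0.8, 0.1, 0.5), 50)
  expect_equal(stance_percentage(1.0, 0.2, 0.8), 60)
  expect_true(is.na(stance_percentage(0.8, NA, 0.5)))
  expect_true(is.na(stance_percentage(0, 0.1, 0.5)))
})

test_that("range of motion is max minus min over valid frames", {
  expect_equal(range_of_motion(c(60, 80, 100, 70)), 40)
  expect_equal(range_of_motion(rep(90, 10)), 0)
  expect_equal(range_of_motion(c(60, NA, 100)), 40)
  expect_true(is.na(range_of_motion(c(NA, 80))))
  expect_true(is.na(range_of_motion(numeric(0))))
})

test_that("event features index the normalized cycle correctly", {
  norm <- tibble::tibble(
    cycle_frac = (0:99) / 100,
    hip = 1:100, knee = 101:200, ankle = 201:300,
    limb_length = 301:400, limb_angle = 401:500
  )
  ev <- angles_at_event(norm, 0.59) # stance ending at sample 60
  expect_equal(ev$hip, 60)
  expect_equal(ev$knee, 160)
  ev_end <- angles_at_event(norm, 1)
  expect_equal(ev_end$hip, 100) # clamped to the last sample
  ev_na <- angles_at_event(norm, NA)
  expect_true(is.na(ev_na$knee))
})

test_that("envelope integration is a plain trapezoid in physical units", {
  fs <- 1000
  tt <- (0:999) / fs
  env <- rep(1, 1000) # constant 1 mV
  expect_equal(integrate_envelope(tt, env, 0.2, 0.7), 0.5, tolerance = 1e-6)
  expect_true(is.na(integrate_envelope(tt, env, NA, 0.7)))
  expect_true(is.na(integrate_envelope(tt, env, 0.7, 0.2)))
})

test_that("burst windows come from the threshold with a stance fallback", {
  fs <- 1000
  tt <- (0:999) / fs
  env <- rep(0, 1000)
  env[300:600] <- 1
  bw <- burst_window(tt, env, start = 0, foot_strike = 0.35, foot_off = 0.8,
                     threshold = 0.5)
  expect_lt(abs(bw$window_start - 0.3), 3 / fs)
  expect_lt(abs(bw$window_end - 0.6), 3 / fs)
  expect_false(bw$used_fallback)
  # sub-threshold everywhere: the stance-anchored fallback window
  bw2 <- burst_window(tt, rep(0, 1000), start = 0, foot_strike = 0.35,
                      foot_off = 0.8, threshold = 0.5)
  expect_true(bw2$used_fallback)
  expect_equal(bw2$window_start, 0.35 - 0.08)
  expect_equal(bw2$window_end, 0.8)
  bw3 <- burst_window(tt, rep(0, 1000), start = 0, foot_strike = 0.35,
                      foot_off = 0.8, threshold = 0.5, fallback = FALSE)
  expect_true(is.na(bw3$window_start))
})

test_that("baseline normalization divides by the subject's baseline mean", {
  feats <- tibble::tibble(
    subject = c("A", "A", "A", "B"),
    week = c("base", "base", "week1", "week1"),
    session = "s", stride_id = c(1L, 2L, 1L, 1L),
    feature = "raw_int_emg_RF",
    value = c(1.5, 2.5, 3.8, 4.0)
  )
  expect_message(out <- normalize_to_baseline(feats), "no baseline")
  norm <- out[out$feature == "int_emg_RF", ]
  # subject A: baseline mean 2.0 -> week-1 stride 3.8 becomes 1.9
  expect_equal(norm$value[norm$subject == "A" & norm$week == "week1"], 1.9)
  expect_equal(mean(norm$value[norm$subject == "A" & norm$week == "base"]), 1)
  # subject B has no baseline: no normalized rows at all
  expect_false(any(norm$subject == "B"))
})

test_that("normalized integrals are invariant to channel gain", {
  spec <- tiny_scenario(n_subjects = 1, weeks = c("base", "week1"),
                        strides_per_session = 8, seed = 15,
                        noise = noise_clean())
  gen <- generate_experiment(spec)
  trials <- gen$trials
  res1 <- analyze_experiment(trials)
  # a recording chain with 10x the electrode gain on RF
  trials10 <- lapply(trials, function(tr) { tr$emg$RF <- 10 * tr$emg$RF; tr })
  res10 <- analyze_experiment(trials10)
  n1 <- res1$features[res1$features$feature == "int_emg_RF", ]
  n10 <- res10$features[res10$features$feature == "int_emg_RF", ]
  expect_equal(n10$value, n1$value, tolerance = 1e-6)
  r1 <- res1$features[res1$features$feature == "raw_int_emg_RF", ]
  r10 <- res10$features[res10$features$feature == "raw_int_emg_RF", ]
  expect_equal(r10$value, 10 * r1$value, tolerance = 1e-6)
})

test_that("features are invariant to rigid translation of the marker set", {
  spec <- tiny_scenario(strides_per_session = 8, seed = 25,
                        noise = noise_clean())
  gen <- generate_experiment(spec)
  tr <- gen$trials[[1]]
  res1 <- process_trial(tr)
  tr2 <- tr
  for (mk in stridelab:::GAIT_MARKERS) {
    tr2$markers[[paste0(mk, "_x")]] <- tr2$markers[[paste0(mk, "_x")]] + 500
    tr2$markers[[paste0(mk, "_y")]] <- tr2$markers[[paste0(mk, "_y")]] - 200
  }
  res2 <- process_trial(tr2)
  expect_equal(res2$features$value, res1$features$value, tolerance = 1e-6)
})

test_that("recovered stance percentage matches the scenario stance fraction", {
  spec <- gait_scenario(n_subjects = 1, weeks = "base",
                        strides_per_session = 50, seed = 27,
                        noise = noise_clean())
  gen <- generate_experiment(spec)
  res <- process_trial(gen$trials[[1]])
  sp <- res$features$value[res$features$feature == "stance_pct"]
  truth <- 100 * mean(gen$truth[[1]]$strides$stance_frac)
  expect_equal(mean(sp), truth, tolerance = 2, ignore_attr = TRUE)
  expect_lt(abs(mean(sp) - truth), 2) # within 2 percentage points
})
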