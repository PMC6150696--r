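test_that("marker low-pass preserves slow motion and rejects jitter", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  mid <- seq(2 * fs, 8 * fs)
  mk <- tibble::tibble(time_s = t, hip_x = 100 + 0 * t)
  out <- lowpass_markers(mk, fs)
  expect_equal(out$hip_x, mk$hip_x, tolerance = 1e-6)
  mk$hip_x <- 10 * sin(2 * pi * 2 * t)
  out <- lowpass_markers(mk, fs)
  expect_equal(max(abs(out$hip_x[mid])), 10, tolerance = 0.02)
  mk$hip_x <- sin(2 * pi * 50 * t)
  out <- lowpass_markers(mk, fs)
  predicted <- filter_response("marker_lowpass", 50, fs)
  expect_lt(max(abs(out$hip_x[mid])), predicted * 10 + 1e-8)
  expect_error(lowpass_markers(mk, 15), "Nyquist")
})

test_that("mask patterns survive filtering and short gaps are bridged internally", {
  fs <- 200
  t <- (0:999) / fs
  x <- sin(2 * pi * 2 * t)
  x[c(100:102, 500:540)] <- NA # 3-frame gap (bridgeable), 41-frame gap (not)
  mk <- tibble::tibble(time_s = t, hip_x = x)
  out <- lowpass_markers(mk, fs)
  expect_identical(is.na(out$hip_x), is.na(x))
  # the short bridged gap must not distort neighbours
  expect_equal(out$hip_x[95], x[95], tolerance = 0.02)
  expect_equal(out$hip_x[110], x[110], tolerance = 0.02)
})

test_that("sagittal projection drops z and propagates masks", {
  mk <- tiny_marker_tbl(3)
  mk$hip_x[2] <- NA
  pose <- project_sagittal(mk)
  expect_false("hip_z" %in% names(pose))
  expect_true(all(c("hip_x", "hip_y") %in% names(pose)))
  expect_true(is.na(pose$hip_x[2]))
  expect_equal(pose$toe_x, mk$toe_x)
})

test_that("lateral offset does not affect the sagittal analysis", {
  s1 <- tiny_scenario(seed = 21, lateral_offset = 0)
  s2 <- tiny_scenario(seed = 21, lateral_offset = 15)
  g1 <- generate_experiment(s1)
  g2 <- generate_experiment(s2)
  p1 <- project_sagittal(g1$trials[[1]]$markers)
  p2 <- project_sagittal(g2$trials[[1]]$markers)
  expect_equal(as.matrix(p1), as.matrix(p2), tolerance = 1e-12)
})

test_that("knee triangulation solves the textbook configurations", {
  g <- limb_geometry(sqrt(2), sqrt(2))
  res <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(0, -2), 1), g)
  expect_true(res$feasible)
  expect_equal(res$knee[1, ], c(1, -1), tolerance = 1e-12)
  # posterior convention picks the mirror solution
  gp <- limb_geometry(sqrt(2), sqrt(2), knee_side = "posterior")
  resp <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(0, -2), 1), gp)
  expect_equal(resp$knee[1, ], c(-1, -1), tolerance = 1e-12)
  # boundary: hip-ankle distance exactly femur + tibia -> collinear, feasible
  g2 <- limb_geometry(38, 42)
  res2 <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(80, 0), 1), g2)
  expect_true(res2$feasible)
  expect_equal(res2$knee[1, ], c(38, 0), tolerance = 1e-9)
})

test_that("infeasible configurations are clamped and flagged", {
  g <- limb_geometry(38, 42)
  # too far: residual split equally between the two constraints
  far <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(90, 0), 1), g)
  expect_false(far$feasible)
  r1 <- abs(sqrt(sum(far$knee[1, ]^2)) - 38)
  r2 <- abs(sqrt(sum((far$knee[1, ] - c(90, 0))^2)) - 42)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(r1, (90 - 80) / 2, tolerance = 1e-9)
  # nested circles
  near <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(1, 0), 1), g)
  expect_false(near$feasible)
  # coincident centres
  expect_error(
    triangulate_knee(matrix(c(0, 0), 1), matrix(c(0, 0), 1),
                     limb_geometry(40, 40)),
    "circle"
  )
  same <- triangulate_knee(matrix(c(0, 0), 1), matrix(c(0, 0), 1), g)
  expect_false(same$feasible)
})

test_that("triangulation agrees with an independent root-finding solver", {
  set.seed(31)
  g <- limb_geometry(38, 42)
  for (i in 1:200) {
    hip <- runif(2, -50, 50)
    d <- runif(1, 6, 78)
    ang <- runif(1, 0, 2 * pi)
    ankle <- hip + d * c(cos(ang), sin(ang))
    res <- triangulate_knee(matrix(hip, 1), matrix(ankle, 1), g)
    expect_true(res$feasible)
    knee <- res$knee[1, ]
    expect_lt(abs(sqrt(sum((knee - hip)^2)) - 38), 1e-9)
    expect_lt(abs(sqrt(sum((knee - ankle)^2)) - 42), 1e-9)
    # independent solver: parameterize the femur circle by angle and find
    # the root of the tibia-length constraint on the anterior side
    f <- function(th) sqrt(sum((hip + 38 * c(cos(th), sin(th)) - ankle)^2)) - 42
    th_axis <- atan2(ankle[2] - hip[2], ankle[1] - hip[1])
    root <- uniroot(function(dd) f(th_axis + dd), c(1e-9, pi - 1e-9),
                    tol = 1e-14)$root
    ref <- hip + 38 * c(cos(th_axis + root), sin(th_axis + root))
    cr <- (ankle[1] - hip[1]) * (ref[2] - hip[2]) -
      (ankle[2] - hip[2]) * (ref[1] - hip[1])
    if (cr < 0) { # wrong branch; mirror
      ref <- hip + 38 * c(cos(th_axis - root), sin(th_axis - root))
    }
    expect_lt(max(abs(knee - ref)), 1e-6)
    # anterior side convention: positive signed area of hip -> ankle -> knee
    cr2 <- (ankle[1] - hip[1]) * (knee[2] - hip[2]) -
      (ankle[2] - hip[2]) * (knee[1] - hip[1])
    expect_gte(cr2, 0)
  }
})

test_that("joint angles follow the flexion-zero extension-180 convention", {
  pose <- tibble::tibble(
    time_s = 0,
    rostral_pelvis_x = 20, rostral_pelvis_y = 0,
    caudal_pelvis_x = -10, caudal_pelvis_y = 2,
    hip_x = 0, hip_y = 0,
    knee_x = 0, knee_y = -38,
    ankle_x = 0, ankle_y = -80,
    toe_x = 0, toe_y = -30
  )
  ang <- joint_angles(pose)
  expect_equal(ang$knee, 180) # hip, knee, ankle collinear = full extension
  expect_equal(ang$hip, 90)
  # knee folded back onto the femur: complete flexion = 0
  pose$ankle_x <- 0
  pose$ankle_y <- -38 + 42
  ang0 <- joint_angles(pose)
  expect_equal(ang0$knee, 0)
  # orthogonal global-limb case
  pose2 <- pose
  pose2$toe_x <- 0; pose2$toe_y <- -30
  ang2 <- joint_angles(pose2)
  expect_equal(ang2$limb_length, 30)
  expect_equal(ang2$limb_angle, 90)
})

test_that("joint angles are invariant under rigid motion", {
  spec <- tiny_scenario(seed = 17, noise = noise_off())
  gen <- generate_experiment(spec)
  mk <- gen$trials[[1]]$markers
  pose <- project_sagittal(mk)
  ang <- joint_angles(pose)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pose2 <- pose
  for (mkname in stridelab:::GAIT_MARKERS) {
    xy <- cbind(pose[[paste0(mkname, "_x")]], pose[[paste0(mkname, "_y")]])
    xy2 <- xy %*% t(R)
    pose2[[paste0(mkname, "_x")]] <- xy2[, 1] + 123
    pose2[[paste0(mkname, "_y")]] <- xy2[, 2] - 456
  }
  ang2 <- joint_angles(pose2)
  for (col in c("hip", "knee", "ankle", "limb_length", "limb_angle")) {
    expect_equal(ang2[[col]], ang[[col]], tolerance = 1e-9)
  }
})

test_that("stance detection finds the belt-locked toe phases", {
  spec <- tiny_scenario(strides_per_session = 6, seed = 19,
                        noise = noise_off())
  gen <- generate_experiment(spec)
  tr <- gen$trials[[1]]
  pose <- project_sagittal(lowpass_markers(tr$markers, tr$marker_rate))
  stance <- detect_stance(pose$toe_x, tr$marker_rate, tr$belt_speed)
  expect_equal(nrow(stance), 6)
  expect_true(all(stance$foot_off > stance$foot_strike))
  expect_true(all(diff(stance$foot_strike) > 0))
  # toe permanently moving forward: no stance
  none <- detect_stance(seq(0, 100, length.out = 500), 200, 12)
  expect_equal(nrow(none), 0)
  expect_error(detect_stance(pose$toe_x, tr$marker_rate, -1), "positive")
})

test_that("triangulated knee beats the artifact-corrupted marker", {
  spec <- tiny_scenario(strides_per_session = 8, seed = 23,
                        noise = noise_clean()) # skin artifact 3 mm, noise 0.5 mm
  gen <- generate_experiment(spec)
  tr <- gen$trials[[1]]
  truth <- gen$truth[[1]]$knee_true
  filt <- lowpass_markers(tr$markers, tr$marker_rate)
  pose_raw <- project_sagittal(filt)
  marker_err <- sqrt((pose_raw$knee_x - truth$knee_x)^2 +
                       (pose_raw$knee_y - truth$knee_y)^2)
  pose <- reconstruct_knee(pose_raw, tr$geometry)
  tri_err <- sqrt((pose$knee_x - truth$knee_x)^2 +
                    (pose$knee_y - truth$knee_y)^2)
  ok <- !is.na(marker_err) & !is.na(tri_err)
  expect_lt(sqrt(mean(tri_err[ok]^2)), sqrt(mean(marker_err[ok]^2)))
})
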