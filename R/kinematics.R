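#' Low-pass filter marker trajectories
#'
#' Zero-phase Butterworth low-pass (default 10 Hz, 5th order) applied to
#' every marker coordinate. Masked runs no longer than `gap_interp_frames`
#' are bridged linearly before filtering so the filter sees a continuous
#' series, and are re-masked afterwards: bridging stabilizes the filter but
#' never invents data, and bridged frames still count as missing for the
#' stride exclusion rule. Longer masked runs stay masked; each contiguous
#' valid segment is filtered independently. Segments too short to filter
#' (fewer than about three filter lengths) pass through unchanged.
#'
#' @param markers Tibble with `time_s` and `<marker>_x/_y/_z` columns (mm).
#' @param rate_hz Marker sampling rate (Hz); must exceed twice the cutoff.
#' @param cfg A [gait_config()]; uses `marker_lowpass_hz`,
#'   `marker_filter_order` and `gap_interp_frames`.
#' @return A tibble of the same shape with filtered coordinates; `NA`
#'   patterns are identical to the input.
#' @export
lowpass_markers <- function(markers, rate_hz, cfg = gait_config()) {
  flt <- butter_lowpass(cfg$marker_lowpass_hz, rate_hz, cfg$marker_filter_order)
  out <- markers
  cols <- setdiff(names(markers), "time_s")
  for (col in cols) {
    out[[col]] <- filter_masked_series(markers[[col]], flt, cfg$gap_interp_frames)
  }
  out
}

filter_masked_series <- function(x, flt, maxgap) {
  n <- length(x)
  na_in <- is.na(x)
  if (all(na_in)) return(x)
  ## bridge short gaps (interior only) so the filter sees continuous data
  bridged <- if (maxgap > 0) {
    zoo::na.approx(x, na.rm = FALSE, maxgap = maxgap)
  } else {
    x
  }
  y <- rep(NA_real_, n)
  still_na <- is.na(bridged)
  r <- rle(!still_na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- 3 * max(length(flt$a), length(flt$b)) + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    seg <- bridged[idx]
    y[idx] <- if (length(seg) >= min_len) filtfilt_pad(flt, seg) else seg
  }
  y[na_in] <- NA_real_
  y
}

#' Project markers onto the sagittal plane
#'
#' Drops the lateral (z) coordinate, keeping x (belt direction, rostral
#' positive) and y (up). Masks propagate: a frame missing either retained
#' coordinate stays missing.
#'
#' @param markers Tibble with `time_s` and `<marker>_x/_y/_z` columns.
#' @return A tibble with `time_s` and `<marker>_x/_y` columns (the sagittal
#'   pose).
#' @export
project_sagittal <- function(markers) {
  keep <- c("time_s", as.vector(t(outer(GAIT_MARKERS, c("x", "y"), paste, sep = "_"))))
  miss <- setdiff(keep, names(markers))
  if (length(miss) > 0) {
    abort(sprintf("marker table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  as_tibble(markers[keep])
}

#' Triangulate the knee from hip and ankle positions
#'
#' Reconstructs the sagittal-plane knee as the intersection of two circles:
#' one centred at the hip with radius `femur_length`, one at the ankle with
#' radius `tibia_length`. Of the two intersections, the branch on the
#' anatomical side (`knee_side` of the geometry) is returned: `"anterior"`
#' selects the solution for which the signed area of hip -> ankle -> knee is
#' positive. When the hip--ankle distance `d` exceeds `femur + tibia`
#' (over-extension under noise) or falls below `|femur - tibia|`, no
#' intersection exists; the closest point on the hip--ankle line that splits
#' the residual equally between the two length constraints is returned and
#' the frame is flagged infeasible.
#'
#' @param hip,ankle Two-column matrices (or data frames) of x/y positions in
#'   mm; rows are frames. `NA` rows yield `NA` knees flagged infeasible.
#' @param geometry A [limb_geometry()].
#' @return A list with `knee` (n x 2 matrix) and `feasible` (logical vector).
#' @export
triangulate_knee <- function(hip, ankle, geometry) {
  stopifnot(inherits(geometry, "limb_geometry"))
  hip <- as.matrix(hip); ankle <- as.matrix(ankle)
  stopifnot(ncol(hip) == 2, ncol(ankle) == 2, nrow(hip) == nrow(ankle))
  f <- geometry$femur_length
  t <- geometry$tibia_length
  side <- if (geometry$knee_side == "anterior") 1 else -1
  dx <- ankle[, 1] - hip[, 1]
  dy <- ankle[, 2] - hip[, 2]
  d <- sqrt(dx^2 + dy^2)
  n <- nrow(hip)
  knee <- matrix(NA_real_, n, 2)
  feasible <- rep(FALSE, n)
  valid <- is.finite(d)
  if (any(valid & d == 0)) {
    if (abs(f - t) < 1e-12) {
      abort("hip and ankle coincide with femur == tibia: knee position is a full circle")
    }
    ## coincident centres with unequal radii: no solution, flag infeasible
  }
  ok <- valid & d > 0
  ux <- dx / d; uy <- dy / d
  a <- (f^2 - t^2 + d^2) / (2 * d)
  h2 <- f^2 - a^2
  geom_ok <- ok & h2 >= 0 & d <= f + t & d >= abs(f - t)
  h <- sqrt(pmax(h2, 0))
  ## perpendicular on the anterior side: rotating the unit hip->ankle vector
  ## by +90 deg gives positive signed area of hip -> ankle -> knee
  knee[geom_ok, 1] <- hip[geom_ok, 1] + a[geom_ok] * ux[geom_ok] -
    side * h[geom_ok] * uy[geom_ok]
  knee[geom_ok, 2] <- hip[geom_ok, 2] + a[geom_ok] * uy[geom_ok] +
    side * h[geom_ok] * ux[geom_ok]
  feasible[geom_ok] <- TRUE
  ## out-of-range frames: equal-residual point on the hip--ankle line
  far <- ok & !geom_ok & d > f + t
  knee[far, 1] <- hip[far, 1] + (f + (d[far] - f - t) / 2) * ux[far]
  knee[far, 2] <- hip[far, 2] + (f + (d[far] - f - t) / 2) * uy[far]
  near <- ok & !geom_ok & d < abs(f - t)
  if (any(near)) {
    ## f >= t: knee beyond the ankle; t > f: knee behind the hip
    s <- if (f >= t) (f + t + d[near]) / 2 else -(f + t - d[near]) / 2
    knee[near, 1] <- hip[near, 1] + s * ux[near]
    knee[near, 2] <- hip[near, 2] + s * uy[near]
  }
  list(knee = knee, feasible = feasible)
}

#' Replace the measured knee marker by its triangulated position
#'
#' Applies [triangulate_knee()] frame-by-frame to a sagittal pose, replacing
#' the skin-marker knee (which carries skin-movement artifact) by the
#' reconstruction from hip and ankle. Frames with a masked hip or ankle, and
#' frames where triangulation is infeasible, leave the knee masked.
#'
#' @param pose A sagittal pose tibble (see [project_sagittal()]).
#' @param geometry A [limb_geometry()].
#' @return The pose with `knee_x`/`knee_y` replaced and a logical
#'   `knee_feasible` column appended.
#' @export
reconstruct_knee <- function(pose, geometry) {
  res <- triangulate_knee(
    cbind(pose$hip_x, pose$hip_y),
    cbind(pose$ankle_x, pose$ankle_y),
    geometry
  )
  pose$knee_x <- ifelse(res$feasible, res$knee[, 1], NA_real_)
  pose$knee_y <- ifelse(res$feasible, res$knee[, 2], NA_real_)
  pose$knee_feasible <- res$feasible
  pose
}

angle_between_deg <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2)
  nb <- sqrt(bx^2 + by^2)
  cosv <- (ax * bx + ay * by) / (na * nb)
  cosv[na == 0 | nb == 0] <- NA_real_
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Joint angles and global limb features from a sagittal pose
#'
#' Computes, per frame, the three sagittal joint angles and two global limb
#' features. Angles are unsigned, in degrees, and follow the convention that
#' 0 deg is complete flexion and larger values mean more extension:
#' \itemize{
#'   \item hip: angle at the hip between the vectors hip -> rostral pelvis
#'     and hip -> knee;
#'   \item knee: angle at the knee between knee -> hip and knee -> ankle;
#'   \item ankle: angle at the ankle between ankle -> knee and ankle -> toe;
#'   \item `limb_length`: length (mm) of the limb vector hip -> toe;
#'   \item `limb_angle`: angle between the limb vector and hip -> rostral
#'     pelvis.
#' }
#' A frame with any required point masked, or with a zero-length segment,
#' yields `NA` for the affected quantities.
#'
#' @param pose A sagittal pose tibble (knee typically reconstructed; see
#'   [reconstruct_knee()]).
#' @return A tibble with `time_s`, `hip`, `knee`, `ankle`, `limb_length`,
#'   `limb_angle`.
#' @export
joint_angles <- function(pose) {
  tibble(
    time_s = pose$time_s,
    hip = angle_between_deg(
      pose$rostral_pelvis_x - pose$hip_x, pose$rostral_pelvis_y - pose$hip_y,
      pose$knee_x - pose$hip_x, pose$knee_y - pose$hip_y
    ),
    knee = angle_between_deg(
      pose$hip_x - pose$knee_x, pose$hip_y - pose$knee_y,
      pose$ankle_x - pose$knee_x, pose$ankle_y - pose$knee_y
    ),
    ankle = angle_between_deg(
      pose$knee_x - pose$ankle_x, pose$knee_y - pose$ankle_y,
      pose$toe_x - pose$ankle_x, pose$toe_y - pose$ankle_y
    ),
    limb_length = sqrt((pose$toe_x - pose$hip_x)^2 + (pose$toe_y - pose$hip_y)^2),
    limb_angle = angle_between_deg(
      pose$rostral_pelvis_x - pose$hip_x, pose$rostral_pelvis_y - pose$hip_y,
      pose$toe_x - pose$hip_x, pose$toe_y - pose$hip_y
    )
  )
}

#' Detect stance intervals from the toe trajectory
#'
#' On a treadmill, the stance signature is the toe moving with the belt:
#' its forward (x) velocity in the lab frame is close to minus the belt
#' speed, whereas during swing the toe moves forward. Stance is declared
#' while the toe's forward velocity is below
#' `-stance_frac_threshold * belt speed`; foot-strike is the downward
#' crossing into that state and foot-off the crossing out of it. Intervals
#' shorter than `stance_min_s` are discarded. The returned intervals are
#' sorted and non-overlapping.
#'
#' @param toe_x Toe forward-coordinate series (mm), ideally low-pass
#'   filtered. Masked runs up to 0.1 s are bridged linearly for the velocity
#'   estimate (occlusions should not split a stance in two); longer runs
#'   interrupt stance.
#' @param rate_hz Marker sampling rate (Hz).
#' @param belt_speed Belt speed in m/min (> 0).
#' @param cfg A [gait_config()]; uses `stance_frac_threshold` and
#'   `stance_min_s`.
#' @return A tibble with columns `foot_strike` and `foot_off` (s).
#' @export
detect_stance <- function(toe_x, rate_hz, belt_speed, cfg = gait_config()) {
  if (!is.numeric(belt_speed) || belt_speed <= 0) {
    abort("'belt_speed' must be positive (m/min)")
  }
  n <- length(toe_x)
  if (n < 3) abort("toe series too short for stance detection")
  belt_mm_s <- belt_speed * 1000 / 60
  ## bridge short occlusion runs so they do not split stance intervals
  toe_x <- zoo::na.approx(toe_x, na.rm = FALSE,
                          maxgap = max(1, round(0.1 * rate_hz)))
  ## central-difference forward velocity (mm/s)
  vx <- c(NA_real_, (toe_x[3:n] - toe_x[1:(n - 2)]) * rate_hz / 2, NA_real_)
  in_stance <- !is.na(vx) & vx < -cfg$stance_frac_threshold * belt_mm_s
  r <- rle(in_stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  fs <- (starts[keep] - 1L) / rate_hz
  fo <- (ends[keep] - 1L) / rate_hz
  ## merge fragments separated by gaps shorter than a credible swing phase
  ## (velocity blips from noise or unbridged occlusions must not split
  ## stance); 3 x stance_min_s is far below any real swing duration
  if (length(fs) > 1) {
    merged_fs <- fs[1]; merged_fo <- fo[1]
    for (k in 2:length(fs)) {
      if (fs[k] - merged_fo[length(merged_fo)] < 3 * cfg$stance_min_s) {
        merged_fo[length(merged_fo)] <- fo[k]
      } else {
        merged_fs <- c(merged_fs, fs[k])
        merged_fo <- c(merged_fo, fo[k])
      }
    }
    fs <- merged_fs; fo <- merged_fo
  }
  long_enough <- (fo - fs) >= cfg$stance_min_s
  tibble(foot_strike = fs[long_enough], foot_off = fo[long_enough])
}
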