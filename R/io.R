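#' Limb segment geometry
#'
#' Segment lengths used to reconstruct the knee by triangulation, plus the
#' circle-intersection branch that is anatomical for the instrumented limb.
#' The chain is planar: femur (hip to knee), tibia (knee to ankle) and foot
#' (ankle to toe, used only when synthesizing marker data).
#'
#' @param femur_length,tibia_length Segment lengths in mm (> 0).
#' @param foot_length Ankle-to-toe distance in mm (> 0); only consumed by the
#'   forward-kinematics generator.
#' @param knee_side One of `"anterior"` or `"posterior"`: the side of the
#'   hip-to-ankle line on which the knee lies. With x pointing along the belt
#'   (rostral positive) and y up, `"anterior"` means the signed area of the
#'   triangle hip -> ankle -> knee is positive.
#' @return An object of class `limb_geometry`.
#' @examples
#' limb_geometry(38, 42)
#' @export
limb_geometry <- function(femur_length, tibia_length, foot_length = 20,
                          knee_side = c("anterior", "posterior")) {
  knee_side <- match.arg(knee_side)
  for (v in c(femur_length = femur_length, tibia_length = tibia_length,
              foot_length = foot_length)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort("limb segment lengths must be single positive numbers (mm)")
    }
  }
  structure(
    list(femur_length = femur_length, tibia_length = tibia_length,
         foot_length = foot_length, knee_side = knee_side),
    class = "limb_geometry"
  )
}

#' @export
print.limb_geometry <- function(x, ...) {
  cat(sprintf("<limb_geometry> femur %.1f mm, tibia %.1f mm, foot %.1f mm, knee %s\n",
              x$femur_length, x$tibia_length, x$foot_length, x$knee_side))
  invisible(x)
}

#' Construct a trial recording
#'
#' One subject-by-session treadmill recording: six-marker 3D trajectories at
#' the marker rate and seven-muscle EMG at the EMG rate, with metadata.
#' Missing marker samples are explicit `NA`s (never interpolated at
#' construction); EMG must be gap-free.
#'
#' @param subject,week,session Identifiers. `week` is typically one of
#'   `"base"`, `"week1"`, `"week2"`, `"week7"`.
#' @param markers Tibble with column `time_s` and columns
#'   `<marker>_x/_y/_z` for the six markers (`rostral_pelvis`,
#'   `caudal_pelvis`, `hip`, `knee`, `ankle`, `toe`), positions in mm.
#'   Axis convention: x along the belt (rostral positive), y up, z lateral.
#' @param emg Tibble with column `time_s` and one column per muscle
#'   (`VL`, `VM`, `RF`, `SM`, `BFp`, `TA`, `GRc`), voltages in mV.
#' @param marker_rate,emg_rate Sampling rates in Hz.
#' @param belt_speed Treadmill belt speed in m/min.
#' @param geometry A [limb_geometry()].
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject, week, session, markers, emg,
                            marker_rate = 200, emg_rate = 5000,
                            belt_speed = 13, geometry = limb_geometry(38, 42)) {
  stopifnot(is_tibble(markers) || is.data.frame(markers),
            is_tibble(emg) || is.data.frame(emg))
  markers <- as_tibble(markers)
  emg <- as_tibble(emg)
  need_m <- c("time_s", marker_cols())
  miss <- setdiff(need_m, names(markers))
  if (length(miss) > 0) {
    abort(sprintf("marker table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  need_e <- c("time_s", GAIT_MUSCLES)
  miss <- setdiff(need_e, names(emg))
  if (length(miss) > 0) {
    abort(sprintf("EMG table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyNA(emg[GAIT_MUSCLES])) {
    abort("EMG channels must not contain missing samples")
  }
  if (marker_rate <= 0 || emg_rate <= 0) abort("sampling rates must be positive")
  dur_m <- nrow(markers) / marker_rate
  dur_e <- nrow(emg) / emg_rate
  if (abs(dur_m - dur_e) > 1 / marker_rate + 1e-9) {
    abort(sprintf(
      "marker (%.4f s) and EMG (%.4f s) stream durations differ by more than one marker frame",
      dur_m, dur_e
    ))
  }
  structure(
    list(subject = as.character(subject), week = as.character(week),
         session = as.character(session),
         markers = markers[need_m], emg = emg[need_e],
         marker_rate = marker_rate, emg_rate = emg_rate,
         belt_speed = belt_speed, geometry = geometry),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> subject %s, %s, session %s\n  markers: %d frames @ %g Hz (%.1f s), %.2f%% masked\n  EMG:     %d samples @ %g Hz, belt %g m/min\n",
    x$subject, x$week, x$session, nrow(x$markers), x$marker_rate,
    nrow(x$markers) / x$marker_rate,
    100 * mean(is.na(as.matrix(x$markers[marker_cols()]))),
    nrow(x$emg), x$emg_rate, x$belt_speed
  ))
  invisible(x)
}

#' Read a trial from interchange files
#'
#' Reads the delimited interchange format: `markers.tsv` (columns `time_s`,
#' `<marker>_x/_y/_z`), `emg.tsv` (columns `time_s`, one per muscle) and a
#' YAML metadata sidecar naming subject, week, session, rates, belt speed and
#' limb geometry. Unparseable or empty marker cells become masked (`NA`)
#' samples; missing EMG cells are an error because the acquisition model
#' never drops EMG samples.
#'
#' @param markers_path,emg_path Paths to the marker and EMG tables.
#' @param meta Either a path to a YAML sidecar or a named list with elements
#'   `subject`, `week`, `session`, `marker_rate`, `emg_rate`, `belt_speed`,
#'   `femur_length`, `tibia_length` and optionally `foot_length`,
#'   `knee_side`.
#' @return A [trial_recording()].
#' @seealso [write_trial()] for the inverse operation.
#' @export
read_trial <- function(markers_path, emg_path, meta) {
  if (is.character(meta) && length(meta) == 1) {
    if (!file.exists(meta)) abort(sprintf("metadata file not found: %s", meta))
    meta <- yaml::read_yaml(meta)
  }
  need <- c("subject", "week", "session", "marker_rate", "emg_rate",
            "belt_speed", "femur_length", "tibia_length")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    abort(sprintf("trial metadata is missing field(s): %s", paste(miss, collapse = ", ")))
  }
  markers <- read_numeric_tsv(markers_path, c("time_s", marker_cols()))
  emg <- read_numeric_tsv(emg_path, c("time_s", GAIT_MUSCLES))
  geometry <- limb_geometry(
    meta$femur_length, meta$tibia_length,
    foot_length = meta$foot_length %||% 20,
    knee_side = meta$knee_side %||% "anterior"
  )
  trial_recording(
    subject = meta$subject, week = meta$week, session = meta$session,
    markers = markers, emg = emg,
    marker_rate = meta$marker_rate, emg_rate = meta$emg_rate,
    belt_speed = meta$belt_speed, geometry = geometry
  )
}

read_numeric_tsv <- function(path, required_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    na = c("", "NA", "NaN"), progress = FALSE
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    p <- prob[1, ]
    abort(sprintf(
      "format error in %s: row %s, column %s (%s)",
      path, p$row, p$col, p$expected
    ))
  }
  miss <- setdiff(required_cols, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  as_tibble(tbl[required_cols])
}

#' Write a trial to interchange files
#'
#' Writes `markers.tsv`, `emg.tsv` and `meta.yaml` into `dir`. Numbers are
#' written with 15 significant digits so that a read-back reproduces the
#' trial to better than 1e-12 relative error, and identical trials produce
#' byte-identical files.
#'
#' @param trial A [trial_recording()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_num_tsv(trial$markers, file.path(dir, "markers.tsv"))
  write_num_tsv(trial$emg, file.path(dir, "emg.tsv"))
  g <- trial$geometry
  yaml::write_yaml(
    list(subject = trial$subject, week = trial$week, session = trial$session,
         marker_rate = trial$marker_rate, emg_rate = trial$emg_rate,
         belt_speed = trial$belt_speed,
         femur_length = g$femur_length, tibia_length = g$tibia_length,
         foot_length = g$foot_length, knee_side = g$knee_side),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

## fixed-format numeric TSV writer: deterministic bytes, 15 significant digits
write_num_tsv <- function(tbl, path) {
  cols <- lapply(tbl, function(v) {
    if (is.numeric(v)) {
      out <- sprintf("%.15g", v)
      out[is.na(v)] <- "NA"
      out
    } else {
      as.character(v)
    }
  })
  lines <- c(
    paste(names(tbl), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write stride feature tables
#'
#' The long interchange format for per-stride features: one row per
#' stride-by-feature with columns `subject`, `week`, `session`, `stride_id`,
#' `feature`, `value`. `NA` values are written as literal `NA` and round-trip
#' to `NA`.
#'
#' @param features A feature tibble.
#' @param path File path.
#' @return `read_feature_table()` returns a tibble; `write_feature_table()`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  need <- c("subject", "week", "session", "stride_id", "feature", "value")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) {
    abort(sprintf("feature table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  write_num_tsv(features[need], path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(), week = readr::col_character(),
      session = readr::col_character(), stride_id = readr::col_integer(),
      feature = readr::col_character(), value = readr::col_double()
    ),
    na = c("NA", "NaN"), progress = FALSE
  )
  as_tibble(tbl)
}

#' Read and write muscle mass tables
#'
#' Per subject and muscle, the wet mass (g) of the instrumented (`ipsi`) and
#' contralateral (`contra`) limb, used for the paired mass comparisons.
#' Columns: `subject`, `muscle`, `side`, `mass_g`.
#'
#' @param masses A mass tibble.
#' @param path File path.
#' @return `read_mass_table()` returns a tibble; `write_mass_table()` returns
#'   `path` invisibly.
#' @export
read_mass_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(), muscle = readr::col_character(),
      side = readr::col_character(), mass_g = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(!tbl$side %in% c("ipsi", "contra"))) {
    abort("mass table 'side' must be 'ipsi' or 'contra'")
  }
  if (any(!is.finite(tbl$mass_g)) || any(tbl$mass_g <= 0)) {
    abort("muscle masses must be positive")
  }
  as_tibble(tbl)
}

#' @rdname read_mass_table
#' @export
write_mass_table <- function(masses, path) {
  need <- c("subject", "muscle", "side", "mass_g")
  miss <- setdiff(need, names(masses))
  if (length(miss) > 0) {
    abort(sprintf("mass table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  write_num_tsv(masses[need], path)
}
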