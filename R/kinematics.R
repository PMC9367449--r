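# Per-step kinematics and the six locomotor endpoints.
#
# All angular quantities are in degrees, matching the field's units for
# angular velocity (deg/s) and meandering (deg/um). Headings and turning
# angles live in (-180, 180]; turns are the circular difference of
# consecutive headings, so a heading flip from 170 to -170 is a +20 turn.

wrap_angle <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

locf <- function(v) {
  pos <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
  out <- rep(NA_real_, length(v))
  out[pos > 0L] <- v[pos[pos > 0L]]
  out
}

# Step table for one cell: one row per pair of consecutive valid frames.
cell_steps <- function(frame, x_um, y_um, fps, max_gap_frames) {
  n <- length(frame)
  if (n < 2L) {
    return(tibble(
      frame_from = integer(), frame_to = integer(), dt_frames = integer(),
      step_um = double(), speed_um_s = double(), heading_deg = double(),
      turn_deg = double(), step_valid = logical(), segment = integer()
    ))
  }
  dt <- diff(frame)
  dx <- diff(x_um)
  dy <- diff(y_um)
  step_um <- sqrt(dx^2 + dy^2)
  speed <- step_um * fps / dt
  heading <- atan2(dy, dx) * 180 / pi
  heading[step_um == 0] <- NA_real_ # zero-length: inherit the previous heading
  step_valid <- dt <= max_gap_frames

  # contiguous runs of valid steps form segments; long gaps break them
  seg_run <- cumsum(!step_valid) + 1L
  segment <- ifelse(step_valid, seg_run, NA_integer_)

  # carry headings forward through zero-length steps, per segment
  filled <- heading
  for (s in unique(segment[!is.na(segment)])) {
    i <- which(!is.na(segment) & segment == s)
    filled[i] <- locf(heading[i])
  }

  # turn between consecutive valid steps of the same segment; a zero-length
  # step is "no reorientation", turn 0, even at the start of a segment
  turn <- rep(NA_real_, n - 1L)
  if (n >= 3L) {
    j <- 2:(n - 1L)
    same_seg <- !is.na(segment[j]) & !is.na(segment[j - 1L]) & segment[j] == segment[j - 1L]
    turn[j][same_seg] <- wrap_angle(filled[j] - filled[j - 1L])[same_seg]
    zero_here <- same_seg & step_um[j] == 0
    turn[j][zero_here] <- 0
  }

  tibble(
    frame_from = frame[-n], frame_to = frame[-1L], dt_frames = as.integer(dt),
    step_um = step_um, speed_um_s = speed, heading_deg = filled,
    turn_deg = turn, step_valid = step_valid, segment = segment
  )
}

#' Per-step kinematic series
#'
#' Decomposes each trajectory into steps between consecutive valid frames:
#' step length (um), instantaneous speed (um/s, time-corrected when a step
#' spans a short tracker gap), heading, and signed turning angle. Steps that
#' would bridge a gap longer than `max_gap_frames` are marked invalid and
#' split the track into segments; turning angles are never computed across a
#' segment break. Zero-length steps inherit the previous heading (turn = 0),
#' so stationary cells have zero, not undefined, angular motion.
#'
#' @param trajectories Long trajectory tibble (see [merge_tracks()]). May
#'   contain several cells.
#' @param meta A [recording_meta()]; defaults to the table's attribute.
#' @param max_gap_frames Longest tracker dropout (in frames) a step may span
#'   before the track is split (default 5, i.e. 1/6 s at 30 fps).
#'
#' @return A tibble of steps with columns `cell_id`, `frame_from`,
#'   `frame_to`, `dt_frames`, `step_um`, `speed_um_s`, `heading_deg`,
#'   `turn_deg`, `step_valid`, `segment`.
#' @export
step_series <- function(trajectories, meta = NULL, max_gap_frames = 5) {
  meta <- resolve_meta(trajectories, meta)
  stopifnot(max_gap_frames >= 1)
  valid <- trajectories |> dplyr::filter(.data$valid)
  n_valid <- table(valid$cell_id)
  short <- names(n_valid)[n_valid < 3]
  if (length(short) > 0) {
    abort(sprintf(
      "Trajectories with fewer than 3 valid frames (turning angles undefined): %s",
      paste(short, collapse = ", ")
    ))
  }
  valid |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(~ cell_steps(.x$frame, .x$x_um, .x$y_um, meta$fps, max_gap_frames)) |>
    dplyr::ungroup()
}

#' Burst-speed threshold
#'
#' A "burst" is a step whose instantaneous speed exceeds the upper quartile
#' (Q3) of a reference speed distribution. The default pooling policy takes
#' Q3 over all valid step speeds of the reference set (usually the untreated
#' control of the recording), so burst counts are comparable across
#' treatments; a per-cell policy is available through
#' [compute_endpoints()].
#'
#' @param speeds_um_s Numeric vector of instantaneous step speeds (um/s).
#' @param quartile_type Quantile convention passed to [stats::quantile()]
#'   (default 7: linear interpolation between order statistics).
#' @return The Q3 threshold in um/s.
#' @examples
#' burst_threshold(c(1, 2, 3, 4)) # 3.25
#' @export
burst_threshold <- function(speeds_um_s, quartile_type = 7) {
  speeds_um_s <- speeds_um_s[is.finite(speeds_um_s)]
  if (length(speeds_um_s) < 4) {
    abort("Need at least 4 speed observations to estimate an upper quartile.")
  }
  unname(quantile(speeds_um_s, 0.75, type = quartile_type))
}

#' @rdname burst_threshold
#' @param steps A step table from [step_series()].
#' @export
pooled_speeds <- function(steps) {
  steps$speed_um_s[steps$step_valid]
}

# Rotation counter: accumulate signed turns; every time the running sum
# reaches +180 (counter-clockwise) or -180 (clockwise) a half-turn excursion
# is tallied and the accumulator keeps only the overshoot. The accumulator
# restarts at each segment break. The half-turn trigger carries a 1e-9 deg
# tolerance: turning angles recovered from coordinates via atan2 differ from
# their nominal values at rounding level, and a swimmer turning an exact
# multiple of 180 deg must not lose its final excursion to that rounding.
rotation_eps <- 1e-9

rotation_from_turns <- function(turn_deg, segment) {
  cw <- 0L
  ccw <- 0L
  acc <- 0
  prev_seg <- NA_integer_
  for (i in seq_along(turn_deg)) {
    t <- turn_deg[i]
    s <- segment[i]
    if (is.na(s)) next
    if (is.na(prev_seg) || s != prev_seg) acc <- 0
    prev_seg <- s
    if (is.na(t)) next
    acc <- acc + t
    while (acc >= 180 - rotation_eps) {
      ccw <- ccw + 1L
      acc <- acc - 180
    }
    while (acc <= -(180 - rotation_eps)) {
      cw <- cw + 1L
      acc <- acc + 180
    }
  }
  c(cw = cw, ccw = ccw, total = cw + ccw)
}

endpoints_one_cell <- function(steps, fps, thr) {
  vs <- steps[steps$step_valid, , drop = FALSE]
  turns <- vs$turn_deg[!is.na(vs$turn_deg)]
  total_um <- sum(vs$step_um)
  time_s <- sum(vs$dt_frames) / fps
  rot <- rotation_from_turns(steps$turn_deg, steps$segment)
  flag <- if (nrow(vs) == 0) {
    "no-valid-steps"
  } else if (length(turns) == 0) {
    "too-short"
  } else if (total_um == 0) {
    "zero-distance"
  } else {
    "ok"
  }
  tibble(
    n_steps = nrow(vs),
    observed_time_s = time_s,
    total_distance_mm = total_um / 1000,
    avg_speed_mm_s = if (time_s > 0) total_um / 1000 / time_s else NA_real_,
    burst_count = sum(vs$speed_um_s > thr),
    angular_velocity_deg_s = if (length(turns) > 0) mean(abs(turns)) * fps else NA_real_,
    meandering_deg_um = if (total_um > 0) sum(abs(turns)) / total_um else NA_real_,
    rotation_cw = rot[["cw"]],
    rotation_ccw = rot[["ccw"]],
    rotation_count = rot[["total"]],
    flag = flag
  )
}

#' Compute the six locomotor endpoints per cell
#'
#' For every cell in a QC-passed trajectory set this derives the six
#' endpoints used to quantify ciliate locomotion:
#' total distance (mm), average speed (mm/s, total distance over the time
#' the cell was validly observed), burst count (valid steps faster than the
#' upper-quartile speed threshold), angular velocity (mean absolute turning
#' rate, deg/s), meandering (total absolute turning per path length,
#' deg/um), and rotation count (half-turn excursions of the cumulative
#' turning angle, tallied clockwise and counter-clockwise).
#'
#' Degenerate cells never abort a batch: a stationary cell gets 0 distance
#' and an undefined (NA) meandering, flagged in the `flag` column.
#'
#' @inheritParams step_series
#' @param group_label Treatment label for the `group` column; defaults to the
#'   set's attribute.
#' @param burst_policy `"pooled"` (one Q3 threshold over the reference speed
#'   pool) or `"per-cell"` (each cell against its own Q3).
#' @param burst_threshold_um_s Externally supplied threshold in um/s (e.g. the
#'   control group's pooled Q3, so treatments are scored against the control
#'   distribution). Overrides `burst_policy`.
#' @param quartile_type Quantile convention (see [burst_threshold()]).
#'
#' @return A tibble with one row per cell: `cell_id`, `group`, the six
#'   endpoints, `rotation_cw`/`rotation_ccw`, `n_steps`, `observed_time_s`
#'   and a `flag` column (`"ok"` or a degeneracy code). The burst threshold
#'   actually used is attached as attribute `burst_threshold_um_s`.
#' @export
compute_endpoints <- function(trajectories, meta = NULL, group_label = NULL,
                              max_gap_frames = 5,
                              burst_policy = c("pooled", "per-cell"),
                              burst_threshold_um_s = NULL,
                              quartile_type = 7) {
  meta <- resolve_meta(trajectories, meta)
  burst_policy <- match.arg(burst_policy)
  group_label <- group_label %||% trajectory_group(trajectories)

  # flag (not fail) cells too short for turning angles
  n_valid <- trajectories |>
    dplyr::filter(.data$valid) |>
    dplyr::count(.data$cell_id, name = "n_valid")
  admissible <- n_valid$cell_id[n_valid$n_valid >= 3]
  flagged_short <- n_valid$cell_id[n_valid$n_valid < 3]

  steps <- step_series(
    trajectories |> dplyr::filter(.data$cell_id %in% admissible),
    meta = meta, max_gap_frames = max_gap_frames
  )

  thr <- burst_threshold_um_s
  if (is.null(thr) && burst_policy == "pooled") {
    thr <- burst_threshold(pooled_speeds(steps), quartile_type = quartile_type)
  }

  per_cell <- steps |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(st, key) {
      t_cell <- thr %||% burst_threshold(st$speed_um_s[st$step_valid], quartile_type = quartile_type)
      endpoints_one_cell(st, meta$fps, t_cell)
    }) |>
    dplyr::ungroup()

  if (length(flagged_short) > 0) {
    per_cell <- dplyr::bind_rows(
      per_cell,
      tibble(
        cell_id = flagged_short, n_steps = 0L, observed_time_s = 0,
        total_distance_mm = NA_real_, avg_speed_mm_s = NA_real_,
        burst_count = NA_integer_, angular_velocity_deg_s = NA_real_,
        meandering_deg_um = NA_real_, rotation_cw = NA_integer_,
        rotation_ccw = NA_integer_, rotation_count = NA_integer_,
        flag = "too-short"
      )
    )
  }

  out <- per_cell |>
    dplyr::mutate(group = group_label, .after = "cell_id") |>
    dplyr::arrange(.data$cell_id) |>
    dplyr::select(
      "cell_id", "group", "total_distance_mm", "avg_speed_mm_s", "burst_count",
      "angular_velocity_deg_s", "meandering_deg_um", "rotation_count",
      "rotation_cw", "rotation_ccw", "n_steps", "observed_time_s", "flag"
    )
  attr(out, "burst_threshold_um_s") <- if (is.null(thr)) NA_real_ else thr
  out
}

endpoint_names <- c(
  "total_distance_mm", "avg_speed_mm_s", "burst_count",
  "angular_velocity_deg_s", "meandering_deg_um", "rotation_count"
)

#' Endpoint column names
#'
#' The six locomotor endpoint columns produced by [compute_endpoints()], in
#' canonical order.
#' @return A character vector of length 6.
#' @export
locomotor_endpoints <- function() endpoint_names
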