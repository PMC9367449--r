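# Synthetic swimmers with known ground truth.
#
# The generator emulates the statistical structure of ciliate swimming that
# the endpoint battery is sensitive to — heading-persistent runs, occasional
# large reorientations (tumbles), and a fast "burst" speed mode — not the
# hydrodynamics. Three models: straight (constant heading), circular
# (constant signed turn per frame), and run-and-tumble (heading noise plus
# Bernoulli tumbles and a burst speed mixture).

#' Swimmer simulation parameters
#'
#' Defaults describe a healthy wild-type ciliate in a 10 s, 30 fps recording:
#' mean speed 180 um/s (about 0.18 mm/s), modest speed noise, a 5% per-frame
#' tumble probability and a 25% burst-mode fraction. Probabilities are per
#' frame; angles in degrees; speeds in um/s.
#'
#' @param model One of `"straight"`, `"circular"`, `"run_and_tumble"`.
#' @param speed_um_s Mean swimming speed (um/s).
#' @param speed_sd Per-frame speed noise SD (um/s).
#' @param turn_per_frame_deg Deterministic signed turn per frame (circular
#'   model; positive = counter-clockwise).
#' @param heading_sd_deg Per-frame heading noise SD during runs.
#' @param tumble_prob Per-frame probability of a tumble (run-and-tumble).
#' @param tumble_turn_sd_deg SD of the wrapped-normal tumble angle.
#' @param burst_prob Per-frame probability of burst mode.
#' @param burst_multiplier Speed multiplier while in burst mode.
#' @param n_frames Number of frames (positions); `n_frames - 1` steps.
#' @param fps Frames per second.
#' @param start_xy_um Starting position (um).
#' @return A `swimmer_params` list.
#' @export
swimmer_params <- function(model = c("run_and_tumble", "straight", "circular"),
                           speed_um_s = 180, speed_sd = 0,
                           turn_per_frame_deg = 0, heading_sd_deg = 0,
                           tumble_prob = 0, tumble_turn_sd_deg = 120,
                           burst_prob = 0, burst_multiplier = 2,
                           n_frames = 300, fps = 30,
                           start_xy_um = c(0, 0)) {
  model <- match.arg(model)
  stopifnot(
    speed_um_s >= 0, speed_sd >= 0,
    tumble_prob >= 0, tumble_prob <= 1,
    burst_prob >= 0, burst_prob <= 1,
    burst_multiplier > 0, tumble_turn_sd_deg >= 0, heading_sd_deg >= 0,
    n_frames >= 2, fps > 0, length(start_xy_um) == 2
  )
  structure(
    list(
      model = model, speed_um_s = speed_um_s, speed_sd = speed_sd,
      turn_per_frame_deg = turn_per_frame_deg, heading_sd_deg = heading_sd_deg,
      tumble_prob = tumble_prob, tumble_turn_sd_deg = tumble_turn_sd_deg,
      burst_prob = burst_prob, burst_multiplier = burst_multiplier,
      n_frames = as.integer(n_frames), fps = fps, start_xy_um = as.numeric(start_xy_um)
    ),
    class = "swimmer_params"
  )
}

#' Wild-type-like run-and-tumble parameter preset
#'
#' The cohort conditions used throughout the package's own validation:
#' mean speed 180 um/s with 15% per-frame speed noise, heading persistence
#' with 8 deg/frame wobble, 5% tumbles, and a 25% burst fraction at twice
#' the base speed, over 300 frames at 30 fps.
#'
#' @param speed_um_s Target overall mean speed (um/s), burst mixture
#'   included; the base (non-burst) speed is deflated accordingly.
#' @param ... Overrides passed to [swimmer_params()].
#' @export
wildtype_params <- function(speed_um_s = 180, ...) {
  defaults <- list(
    model = "run_and_tumble", heading_sd_deg = 8,
    tumble_prob = 0.05, tumble_turn_sd_deg = 120,
    burst_prob = 0.25, burst_multiplier = 2
  )
  args <- utils::modifyList(defaults, list(...))
  base <- speed_um_s / (1 + args$burst_prob * (args$burst_multiplier - 1))
  args$speed_um_s <- base
  args$speed_sd <- args$speed_sd %||% 0.15 * base
  do.call(swimmer_params, args)
}

#' Simulate one swimmer
#'
#' Heading-persistent stepping: each frame the heading changes by the
#' deterministic circular turn plus Gaussian noise, with probability
#' `tumble_prob` an additional wrapped-normal tumble; the step length is the
#' per-frame speed draw (doubled during burst frames) divided by fps. Fully
#' reproducible given `seed`.
#'
#' @param params A [swimmer_params()] object.
#' @param seed Integer seed.
#' @param cell_id Identifier for the generated cell.
#' @return A trajectory tibble (`frame`, `x_um`, `y_um`, ... as in
#'   [read_track_file()], with `x_px = x_um` under a 1 um/px convention until
#'   written by [write_tracker_fixture()]), with attribute `ground_truth`: a
#'   list of analytically expected endpoint values where closed forms exist.
#' @export
simulate_swimmer <- function(params, seed = 1L, cell_id = "cell_1") {
  stopifnot(inherits(params, "swimmer_params"))
  set.seed(as.integer(seed))
  p <- params
  n_steps <- p$n_frames - 1L

  heading0 <- runif(1, -180, 180)
  dturn <- rep(0, n_steps)
  if (p$model == "circular") dturn <- dturn + p$turn_per_frame_deg
  if (p$heading_sd_deg > 0) dturn <- dturn + rnorm(n_steps, 0, p$heading_sd_deg)
  if (p$model == "run_and_tumble" && p$tumble_prob > 0) {
    tumbles <- runif(n_steps) < p$tumble_prob
    dturn[tumbles] <- dturn[tumbles] + rnorm(sum(tumbles), 0, p$tumble_turn_sd_deg)
  }
  heading <- wrap_angle(heading0 + cumsum(dturn))

  speed <- rep(p$speed_um_s, n_steps)
  if (p$speed_sd > 0) speed <- pmax(rnorm(n_steps, p$speed_um_s, p$speed_sd), 0)
  burst <- rep(FALSE, n_steps)
  if (p$burst_prob > 0) {
    burst <- runif(n_steps) < p$burst_prob
    speed[burst] <- speed[burst] * p$burst_multiplier
  }

  step_um <- speed / p$fps
  x <- p$start_xy_um[1] + cumsum(c(0, step_um * cos(heading * pi / 180)))
  y <- p$start_xy_um[2] + cumsum(c(0, step_um * sin(heading * pi / 180)))

  truth <- list(
    model = p$model,
    expected_speed_mm_s = p$speed_um_s * (1 + p$burst_prob * (p$burst_multiplier - 1)) / 1000,
    burst_fraction = p$burst_prob
  )
  if (p$model == "straight" && p$speed_sd == 0 && p$heading_sd_deg == 0) {
    truth$total_distance_mm <- p$speed_um_s * n_steps / p$fps / 1000
    truth$avg_speed_mm_s <- p$speed_um_s / 1000
    truth$angular_velocity_deg_s <- 0
    truth$meandering_deg_um <- 0
    truth$rotation_count <- 0L
  }
  if (p$model == "circular" && p$heading_sd_deg == 0) {
    total_turn <- abs(p$turn_per_frame_deg) * (n_steps - 1L)
    truth$angular_velocity_deg_s <- abs(p$turn_per_frame_deg) * p$fps
    truth$rotation_count <- as.integer(floor(total_turn / 180))
    truth$rotation_ccw <- if (p$turn_per_frame_deg > 0) truth$rotation_count else 0L
    truth$rotation_cw <- truth$rotation_count - truth$rotation_ccw
    if (p$speed_sd == 0 && p$speed_um_s > 0) {
      # (n_steps - 1) turns over n_steps equal chords
      truth$meandering_deg_um <- abs(p$turn_per_frame_deg) * (n_steps - 1L) /
        ((p$speed_um_s / p$fps) * n_steps)
    }
  }

  out <- tibble(
    cell_id = cell_id,
    frame = seq_len(p$n_frames) - 1L,
    x_px = x, y_px = y, # px equals um until a calibration is chosen at write time
    x_um = x, y_um = y,
    valid = TRUE
  )
  attr(out, "ground_truth") <- truth
  out
}

#' Simulate a cohort of independent swimmers
#'
#' Each cell gets its own deterministic seed derived from the master seed and
#' the cell index, so cohorts are reproducible cell-by-cell and insensitive
#' to the order of generation.
#'
#' @param n_cells Number of cells (default 158, a typical per-group sample
#'   size for this assay).
#' @param params A [swimmer_params()] object shared by all cells.
#' @param seed Master integer seed.
#' @param group_label Treatment label for the set.
#' @param meta Optional [recording_meta()] to attach; defaults to one built
#'   from `params` with a 1.62 um/px calibration.
#' @return A long trajectory tibble with attributes `meta` and `group_label`.
#' @export
simulate_cohort <- function(n_cells = 158, params = wildtype_params(), seed = 1L,
                            group_label = "control", meta = NULL) {
  stopifnot(n_cells >= 1)
  width <- max(3L, nchar(as.character(n_cells)))
  cells <- purrr::map(seq_len(n_cells), function(i) {
    simulate_swimmer(
      params,
      seed = derive_seed(seed, i),
      cell_id = sprintf(paste0("cell_%0", width, "d"), i)
    )
  })
  meta <- meta %||% recording_meta(
    fps = params$fps,
    duration_s = params$n_frames / params$fps,
    um_per_px = 1.62,
    recording_id = group_label
  )
  out <- dplyr::bind_rows(cells) |>
    dplyr::mutate(
      x_px = .data$x_um / meta$um_per_px,
      y_px = .data$y_um / meta$um_per_px
    )
  new_trajectory_set(out, meta, group_label)
}

# Deterministic per-cell seed below 2^31, decoupled from the master stream.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 69621) %% 2147483647) + 1L
}

#' Write a cohort as per-cell tracker fixture files
#'
#' Writes one file per cell in either supported tracker dialect so the full
#' reading path ([read_track_file()], [merge_tracks()]) can be exercised on
#' data with known ground truth. Pixel coordinates are derived from the
#' micrometre coordinates with the calibration in `meta`; frames with
#' `valid = FALSE` are written as non-finite positions, as trackers do.
#'
#' @param trajectories Long trajectory tibble (e.g. from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param dialect `"csv"` or `"npz"`.
#' @param meta A [recording_meta()]; defaults to the set's attribute.
#' @return The directory path, invisibly.
#' @export
write_tracker_fixture <- function(trajectories, dir, dialect = c("csv", "npz"), meta = NULL) {
  dialect <- match.arg(dialect)
  meta <- resolve_meta(trajectories, meta)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in unique(trajectories$cell_id)) {
    tr <- trajectories[trajectories$cell_id == id, , drop = FALSE]
    x_px <- ifelse(tr$valid, tr$x_um / meta$um_per_px, NaN)
    y_px <- ifelse(tr$valid, tr$y_um / meta$um_per_px, NaN)
    path <- file.path(dir, paste0(id, ".", dialect))
    if (dialect == "csv") {
      readr::write_csv(
        tibble(frame = tr$frame, X = x_px, Y = y_px),
        path,
        progress = FALSE
      )
    } else {
      npz_write(list(frame = as.numeric(tr$frame), X = x_px, Y = y_px), path)
    }
  }
  invisible(dir)
}
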