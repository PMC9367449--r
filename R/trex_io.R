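#' Read one per-cell tracker export
#'
#' Trackers such as TRex save one file per tracked cell, holding the per-frame
#' centroid position in pixel coordinates. Two dialects are supported,
#' auto-detected by extension: plain CSV (columns for frame, X and Y) and the
#' numpy `.npz` array container (one 1-D array per quantity). Frames the
#' tracker could not resolve — absent rows or non-finite coordinates, the
#' footprint of identity loss — are kept as invalid entries rather than
#' interpolated; downstream kinematics owns the gap policy.
#'
#' @param path Path to a `.csv` or `.npz` per-cell export.
#' @param meta A [recording_meta()] object; supplies the frame grid and the
#'   pixel-to-micrometre calibration.
#' @param key_map Named character vector mapping the roles `frame`, `x`, `y`
#'   to the column/array names used in the export.
#' @param cell_id Identifier for the cell; defaults to the file name stem.
#'
#' @return A tibble with one row per expected frame (`0` to `n_frames - 1`)
#'   and columns `cell_id`, `frame`, `x_px`, `y_px`, `x_um`, `y_um`, `valid`.
#'   `x_um = x_px * um_per_px` (same for y); `valid` is `FALSE` wherever the
#'   export had no finite position.
#' @examples
#' meta <- recording_meta(fps = 30, duration_s = 1, um_per_px = 2)
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(frame = 0:29, X = 0:29, Y = 0), f, row.names = FALSE)
#' read_track_file(f, meta)
#' @export
read_track_file <- function(path, meta,
                            key_map = c(frame = "frame", x = "X", y = "Y"),
                            cell_id = NULL) {
  assert_meta(meta)
  if (!file.exists(path)) abort(sprintf("Track file '%s' does not exist.", path))
  stopifnot(all(c("frame", "x", "y") %in% names(key_map)))
  cell_id <- cell_id %||% sub("\\.(csv|npz)$", "", basename(path), ignore.case = TRUE)

  ext <- tolower(tools::file_ext(path))
  cols <- if (ext == "npz") {
    arrays <- tryCatch(npz_read(path), error = function(e) {
      abort(sprintf("Could not read '%s' as an npz track export: %s", path, conditionMessage(e)))
    })
    missing_keys <- setdiff(unname(key_map), names(arrays))
    if (length(missing_keys) > 0) {
      abort(sprintf("'%s' lacks required array(s): %s", path, paste(missing_keys, collapse = ", ")))
    }
    list(frame = arrays[[key_map[["frame"]]]], x = arrays[[key_map[["x"]]]], y = arrays[[key_map[["y"]]]])
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE), # correctly-rounded double parse
      error = function(e) abort(sprintf("Could not read '%s' as a CSV track export: %s", path, conditionMessage(e)))
    )
    missing_keys <- setdiff(unname(key_map), names(df))
    if (length(missing_keys) > 0) {
      abort(sprintf("'%s' lacks required column(s): %s", path, paste(missing_keys, collapse = ", ")))
    }
    list(frame = df[[key_map[["frame"]]]], x = df[[key_map[["x"]]]], y = df[[key_map[["y"]]]])
  }

  frame <- suppressWarnings(as.integer(round(as.numeric(cols$frame))))
  if (anyNA(frame)) abort(sprintf("'%s': frame indices must be numeric.", path))
  if (any(frame < 0L | frame >= meta$n_frames)) {
    abort(sprintf(
      "'%s': frame indices outside [0, %d) — check fps/duration metadata.",
      path, meta$n_frames
    ))
  }
  if (anyDuplicated(frame)) abort(sprintf("'%s': duplicated frame indices.", path))
  if (length(frame) != length(cols$x) || length(frame) != length(cols$y)) {
    abort(sprintf("'%s': frame, X and Y lengths differ.", path))
  }

  x_px <- rep(NA_real_, meta$n_frames)
  y_px <- rep(NA_real_, meta$n_frames)
  x_px[frame + 1L] <- as.numeric(cols$x)
  y_px[frame + 1L] <- as.numeric(cols$y)
  valid <- is.finite(x_px) & is.finite(y_px)
  x_px[!valid] <- NA_real_
  y_px[!valid] <- NA_real_
  if (!any(valid)) abort(sprintf("'%s': no valid positions (empty track).", path))

  tibble(
    cell_id = cell_id,
    frame = seq_len(meta$n_frames) - 1L,
    x_px = x_px,
    y_px = y_px,
    x_um = x_px * meta$um_per_px,
    y_um = y_px * meta$um_per_px,
    valid = valid
  )
}

#' Merge a directory of per-cell tracker exports
#'
#' Replaces the spreadsheet-macro consolidation step of the original workflow:
#' every per-cell export in `dir` is read and stacked into one long trajectory
#' table, ordered lexicographically by file name. The cell identifier is the
#' file name stem; duplicate stems (e.g. `cell_1.csv` next to `cell_1.npz`)
#' are an identity ambiguity and raise an error.
#'
#' @param dir Directory containing `.csv` and/or `.npz` per-cell exports.
#' @param meta A [recording_meta()] object.
#' @param group_label Treatment-group label attached to the set.
#' @inheritParams read_track_file
#'
#' @return A long trajectory tibble (columns as in [read_track_file()]) with
#'   attributes `meta` and `group_label`.
#' @export
merge_tracks <- function(dir, meta, group_label = "group",
                         key_map = c(frame = "frame", x = "X", y = "Y")) {
  assert_meta(meta)
  if (!dir.exists(dir)) abort(sprintf("Directory '%s' does not exist.", dir))
  files <- list.files(dir, pattern = "\\.(csv|npz)$", ignore.case = TRUE, full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0) abort(sprintf("Directory '%s' contains no track files.", dir))
  stems <- sub("\\.(csv|npz)$", "", basename(files), ignore.case = TRUE)
  if (anyDuplicated(stems)) {
    abort(sprintf(
      "Duplicate cell id(s) in '%s': %s",
      dir, paste(unique(stems[duplicated(stems)]), collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(purrr::map(files, read_track_file, meta = meta, key_map = key_map))
  new_trajectory_set(out, meta, group_label)
}

new_trajectory_set <- function(data, meta, group_label) {
  attr(data, "meta") <- meta
  attr(data, "group_label") <- group_label
  data
}

#' @rdname merge_tracks
#' @param trajectories A long trajectory tibble.
#' @export
trajectory_meta <- function(trajectories) attr(trajectories, "meta", exact = TRUE)

#' @rdname merge_tracks
#' @export
trajectory_group <- function(trajectories) {
  attr(trajectories, "group_label", exact = TRUE) %||% "group"
}

resolve_meta <- function(trajectories, meta) {
  meta <- meta %||% trajectory_meta(trajectories)
  if (is.null(meta)) {
    abort("No recording metadata: pass `meta` or use a table produced by `merge_tracks()`.")
  }
  assert_meta(meta)
  meta
}

#' Quality-control filtering of merged tracks
#'
#' Trackers lose identities when cells collide or swim out of frame; such
#' tracks carry gaps or cover only part of the recording and would distort
#' time-based endpoints. This filter drops tracks whose valid-frame coverage
#' or absolute valid-frame count is too low, and accounts for every input
#' track in an attached QC report.
#'
#' @param trajectories Long trajectory tibble from [merge_tracks()].
#' @param meta A [recording_meta()]; defaults to the table's attribute.
#' @param min_coverage Minimum fraction of expected frames with a valid
#'   position, in (0, 1]. Default 0.85 — sized so that tracks in the error
#'   range reported for machine-vision tracking of ciliates are excluded.
#' @param min_frames Minimum absolute number of valid frames (default 30,
#'   i.e. one second at 30 fps).
#'
#' @return The filtered trajectory tibble, with a `qc_report` attached as
#'   attribute `qc` (retrieve with [qc_report()]).
#' @export
filter_tracks <- function(trajectories, meta = NULL, min_coverage = 0.85, min_frames = 30) {
  meta <- resolve_meta(trajectories, meta)
  stopifnot(min_coverage > 0, min_coverage <= 1, min_frames >= 0)
  per_cell <- trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      out_of_frame = any(.data$frame < 0L | .data$frame >= meta$n_frames),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage = .data$n_valid / meta$n_frames,
      reason = dplyr::case_when(
        .data$out_of_frame ~ "out-of-frame",
        .data$n_valid < min_frames ~ "too-short",
        .data$coverage < min_coverage ~ "low-coverage",
        TRUE ~ NA_character_
      )
    )
  dropped <- per_cell |> dplyr::filter(!is.na(.data$reason))
  report <- structure(
    list(
      n_input = nrow(per_cell),
      n_kept = nrow(per_cell) - nrow(dropped),
      n_dropped = nrow(dropped),
      drop_reasons = dropped |> dplyr::select("cell_id", "reason", "n_valid", "coverage"),
      min_coverage = min_coverage,
      min_frames = min_frames
    ),
    class = "qc_report"
  )
  kept <- trajectories |>
    dplyr::filter(!(.data$cell_id %in% dropped$cell_id))
  kept <- new_trajectory_set(kept, meta, trajectory_group(trajectories))
  attr(kept, "qc") <- report
  kept
}

#' @rdname filter_tracks
#' @param x A table returned by [filter_tracks()], or a `qc_report`.
#' @export
qc_report <- function(x) {
  if (inherits(x, "qc_report")) x else attr(x, "qc", exact = TRUE)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d tracks in, %d kept, %d dropped (min_coverage=%g, min_frames=%d)\n",
    x$n_input, x$n_kept, x$n_dropped, x$min_coverage, x$min_frames
  ))
  if (x$n_dropped > 0) print(table(x$drop_reasons$reason))
  invisible(x)
}

#' @rdname filter_tracks
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @export
write_qc_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(
      n_input = report$n_input, n_kept = report$n_kept, n_dropped = report$n_dropped,
      min_coverage = report$min_coverage, min_frames = report$min_frames,
      drop_reasons = report$drop_reasons
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

combined_cols <- c("cell_id", "frame", "x_px", "y_px", "x_um", "y_um", "valid")

#' Read/write the combined long-format trajectory CSV
#'
#' The merged table is persisted as one long CSV (`cell_id, frame, x_px, y_px,
#' x_um, y_um, valid`), the analysis-ready equivalent of the original
#' workflow's consolidated spreadsheet. `read_combined_csv()` inverts
#' `write_combined_csv()` exactly, including the validity mask.
#'
#' @param trajectories Long trajectory tibble.
#' @param path CSV path.
#' @export
write_combined_csv <- function(trajectories, path) {
  if (nrow(trajectories) == 0) abort("Refusing to write an empty trajectory set.")
  stopifnot(all(combined_cols %in% names(trajectories)))
  readr::write_csv(trajectories[combined_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_combined_csv
#' @param meta A [recording_meta()] describing the recording the CSV came from.
#' @param group_label Treatment label to attach.
#' @export
read_combined_csv <- function(path, meta, group_label = "group") {
  assert_meta(meta)
  # base read.csv: its double parser is correctly rounded, so the combined
  # CSV round-trips coordinates bitwise
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("frame" %in% names(df)) df$frame <- as.integer(df$frame)
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  missing_cols <- setdiff(combined_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("'%s' is not a combined trajectory CSV: missing %s.", path, paste(missing_cols, collapse = ", ")))
  }
  new_trajectory_set(df[combined_cols], meta, group_label)
}
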