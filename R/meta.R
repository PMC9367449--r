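#' Recording metadata
#'
#' Describes one video recording: frame rate, duration, and the spatial
#' calibration used to convert tracker pixel coordinates to micrometres.
#' The calibration has no default because it depends on the objective and
#' sensor of each microscope setup; it must be measured (e.g. with a stage
#' micrometer) and supplied explicitly.
#'
#' @param fps Frames per second of the recording (positive).
#' @param duration_s Recording duration in seconds (positive).
#' @param um_per_px Micrometres per pixel (positive). Required, no default.
#' @param recording_id Text label identifying the recording.
#'
#' @return A `recording_meta` object (a named list with fields `fps`,
#'   `duration_s`, `um_per_px`, `recording_id`, and the derived `n_frames =
#'   round(fps * duration_s)`).
#' @examples
#' meta <- recording_meta(fps = 30, duration_s = 10, um_per_px = 1.62)
#' meta$n_frames
#' @export
recording_meta <- function(fps = 30, duration_s = 10, um_per_px, recording_id = "recording") {
  if (missing(um_per_px)) {
    abort("`um_per_px` is required: the pixel-to-micrometre calibration must be supplied.")
  }
  stopifnot(is.numeric(fps), length(fps) == 1, is.finite(fps), fps > 0)
  stopifnot(is.numeric(duration_s), length(duration_s) == 1, is.finite(duration_s), duration_s > 0)
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1, is.finite(um_per_px), um_per_px > 0)
  structure(
    list(
      fps = as.numeric(fps),
      duration_s = as.numeric(duration_s),
      um_per_px = as.numeric(um_per_px),
      recording_id = as.character(recording_id),
      n_frames = as.integer(round(fps * duration_s))
    ),
    class = "recording_meta"
  )
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(
    sprintf(
      "<recording_meta> %s: %g fps x %g s (%d frames), %g um/px\n",
      x$recording_id, x$fps, x$duration_s, x$n_frames, x$um_per_px
    )
  )
  invisible(x)
}

is_recording_meta <- function(x) inherits(x, "recording_meta")

assert_meta <- function(meta) {
  if (!is_recording_meta(meta)) {
    abort("`meta` must be a `recording_meta` object (see `recording_meta()`).")
  }
  invisible(meta)
}
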