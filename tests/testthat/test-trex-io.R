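meta300 <- recording_meta(fps = 30, duration_s = 10, um_per_px = 2, recording_id = "r1")

write_cell_csv <- function(dir, name, frame, X, Y) {
  path <- file.path(dir, name)
  readr::write_csv(tibble::tibble(frame = frame, X = X, Y = Y), path, progress = FALSE)
  path
}

test_that("CSV track read-through preserves positions and applies calibration", {
  d <- withr::local_tempdir()
  p <- write_cell_csv(d, "cell_a.csv", 0:299, X = seq(10, 309), Y = rep(5, 300))
  tr <- read_track_file(p, meta300)
  expect_equal(nrow(tr), 300)
  expect_true(all(tr$valid))
  expect_equal(tr$x_px, seq(10, 309))
  expect_equal(tr$x_um, seq(10, 309) * 2) # pixel times um-per-px
  expect_equal(tr$cell_id[1], "cell_a")
})

test_that("non-finite and absent frames become invalid entries, never values", {
  d <- withr::local_tempdir()
  X <- seq(0, 299)
  X[101:111] <- NaN # frames 100-110
  p <- write_cell_csv(d, "c.csv", 0:299, X, Y = rep(1, 300))
  tr <- read_track_file(p, meta300)
  expect_equal(which(!tr$valid), 101:111)
  expect_true(all(is.na(tr$x_um[!tr$valid])))

  # absent rows are invalid too
  p2 <- write_cell_csv(d, "c2.csv", c(0:99, 200:299), X = rep(1, 200), Y = rep(1, 200))
  tr2 <- read_track_file(p2, meta300)
  expect_equal(sum(tr2$valid), 200)
  expect_false(any(tr2$valid[101:200]))
})

test_that("npz dialect reads through a configurable key map", {
  d <- withr::local_tempdir()
  meta <- tiny_meta(5)
  path <- file.path(d, "cell_1.npz")
  ciliotrack:::npz_write(
    list(frame = 0:4, posx = c(1, 2, 3, NaN, 5), posy = rep(0, 5)),
    path
  )
  tr <- read_track_file(path, meta, key_map = c(frame = "frame", x = "posx", y = "posy"))
  expect_equal(tr$x_um, c(1, 2, 3, NA, 5))
  expect_equal(tr$valid, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_error(
    read_track_file(path, meta),
    "lacks required array"
  )
})

test_that("track read errors are informative", {
  d <- withr::local_tempdir()
  expect_error(read_track_file(file.path(d, "nope.csv"), meta300), "does not exist")
  # zero valid frames
  p <- write_cell_csv(d, "empty.csv", 0:2, X = rep(NaN, 3), Y = rep(NaN, 3))
  expect_error(read_track_file(p, meta300), "empty track")
  # frame outside the recording window
  p2 <- write_cell_csv(d, "oob.csv", c(0, 300), X = c(1, 2), Y = c(1, 2))
  expect_error(read_track_file(p2, meta300), "outside")
})

test_that("merge_tracks orders lexicographically and fails on duplicates / empties", {
  d <- withr::local_tempdir()
  write_cell_csv(d, "cell_3.csv", 0:9, X = 1:10, Y = 1:10)
  write_cell_csv(d, "cell_1.csv", 0:9, X = 1:10, Y = 1:10)
  meta <- tiny_meta(10)
  set <- merge_tracks(d, meta, group_label = "g")
  expect_equal(unique(set$cell_id), c("cell_1", "cell_3"))
  expect_equal(trajectory_group(set), "g")
  expect_s3_class(trajectory_meta(set), "recording_meta")

  ciliotrack:::npz_write(list(frame = 0:9, X = 1:10, Y = 1:10), file.path(d, "cell_1.npz"))
  expect_error(merge_tracks(d, meta), "Duplicate cell id")

  empty <- withr::local_tempdir()
  expect_error(merge_tracks(empty, meta), "no track files")
})

test_that("combined CSV round-trips bitwise and rejects malformed tables", {
  meta <- tiny_meta(10)
  set <- simulate_cohort(3, wildtype_params(n_frames = 10), seed = 4, meta = meta)
  f <- withr::local_tempfile(fileext = ".csv")
  write_combined_csv(set, f)
  back <- read_combined_csv(f, meta, group_label = trajectory_group(set))
  expect_identical(back$x_um, set$x_um)
  expect_identical(back$y_um, set$y_um)
  expect_identical(back$valid, set$valid)
  expect_equal(nrow(back), 3 * 10)

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(cell_id = "a", x_px = 1), bad, progress = FALSE)
  expect_error(suppressWarnings(read_combined_csv(bad, meta)), "missing")
})

test_that("QC filter applies coverage and length thresholds and conserves counts", {
  meta <- recording_meta(fps = 30, duration_s = 10, um_per_px = 1)
  good <- make_traj(seq(0, 299), rep(0, 300), meta, cell_id = "good")
  partial <- make_traj(seq_len(250), rep(0, 250), meta,
    cell_id = "partial", frame = 0:249
  ) # 250/300 = 0.833 < 0.9
  short <- make_traj(1:10, rep(0, 10), meta, cell_id = "short", frame = 0:9)
  all3 <- dplyr::bind_rows(good, partial, short)
  attr(all3, "meta") <- meta

  kept <- filter_tracks(all3, min_coverage = 0.9, min_frames = 30)
  rep <- qc_report(kept)
  expect_equal(rep$n_input, 3)
  expect_equal(rep$n_kept, 1)
  expect_equal(rep$n_dropped, 2)
  expect_equal(rep$n_kept + rep$n_dropped, rep$n_input)
  reasons <- setNames(rep$drop_reasons$reason, rep$drop_reasons$cell_id)
  expect_equal(unname(reasons["partial"]), "low-coverage")
  expect_equal(unname(reasons["short"]), "too-short")
  expect_equal(unique(kept$cell_id), "good")

  # idempotence: filtering a filtered set drops nothing further
  again <- filter_tracks(kept, min_coverage = 0.9, min_frames = 30)
  expect_equal(qc_report(again)$n_dropped, 0)
  expect_equal(unique(again$cell_id), unique(kept$cell_id))

  j <- withr::local_tempfile(fileext = ".json")
  write_qc_json(rep, j)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$n_input, 3)
  expect_equal(length(parsed$drop_reasons), 2)
})

test_that("calibration scaling rescales micrometre columns only", {
  d <- withr::local_tempdir()
  write_cell_csv(d, "c.csv", 0:9, X = 1:10, Y = 10:1)
  t1 <- read_track_file(file.path(d, "c.csv"), tiny_meta(10, um_per_px = 1))
  t2 <- read_track_file(file.path(d, "c.csv"), tiny_meta(10, um_per_px = 3))
  expect_equal(t2$x_px, t1$x_px)
  expect_equal(t2$x_um, 3 * t1$x_um)
  expect_equal(t2$y_um, 3 * t1$y_um)
})
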