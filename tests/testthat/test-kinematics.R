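test_that("step primitives: 3-4-5 collinear steps, right-angle turn, shortest wrap", {
  meta <- tiny_meta(3)
  tr <- make_traj(c(0, 3, 6), c(0, 4, 8), meta)
  st <- step_series(tr, meta)
  expect_equal(st$step_um, c(5, 5))
  expect_equal(st$speed_um_s, c(150, 150))
  expect_equal(st$turn_deg, c(NA, 0))

  tr2 <- make_traj(c(0, 1, 1), c(0, 0, 1), meta)
  st2 <- step_series(tr2, meta)
  expect_equal(st2$heading_deg, c(0, 90))
  expect_equal(st2$turn_deg[2], 90)

  # headings 170 then -170: shortest signed wrap is +20, not -340
  h1 <- 170 * pi / 180
  h2 <- -170 * pi / 180
  tr3 <- make_traj(
    cumsum(c(0, cos(h1), cos(h2))), cumsum(c(0, sin(h1), sin(h2))), meta
  )
  st3 <- step_series(tr3, meta)
  expect_equal(st3$turn_deg[2], 20)
})

test_that("zero-length steps inherit heading and contribute zero turn", {
  meta <- tiny_meta(4)
  tr <- make_traj(c(0, 1, 1, 2), c(0, 0, 0, 0), meta)
  st <- step_series(tr, meta)
  expect_equal(st$step_um, c(1, 0, 1))
  expect_equal(st$heading_deg, c(0, 0, 0))
  expect_equal(st$turn_deg, c(NA, 0, 0))
})

test_that("gaps split tracks: over-long gaps invalidate steps, short gaps keep time-correct speed", {
  meta <- tiny_meta(30)
  # valid frames 0,1,2, 10,11,12 with max_gap 5: the 2->10 step is invalid
  tr <- make_traj(
    c(0, 1, 2, 10, 11, 12), rep(0, 6), meta,
    frame = c(0L, 1L, 2L, 10L, 11L, 12L)
  )
  st <- step_series(tr, meta, max_gap_frames = 5)
  expect_equal(st$step_valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(st$turn_deg[4])) # no turn across a segment break
  expect_equal(length(unique(na.omit(st$segment))), 2)

  # a 3-frame gap within max_gap: speed uses frames spanned, not 1
  tr2 <- make_traj(c(0, 9, 10), rep(0, 3), meta, frame = c(0L, 3L, 4L))
  st2 <- step_series(tr2, meta, max_gap_frames = 5)
  expect_equal(st2$speed_um_s, c(9 * 30 / 3, 30))
  expect_equal(st2$dt_frames, c(3L, 1L))
})

test_that("too-short trajectories error in step_series and are flagged in batch mode", {
  meta <- tiny_meta(5)
  short <- make_traj(c(0, 1), c(0, 0), meta)
  expect_error(step_series(short, meta), "fewer than 3 valid frames")
  ok <- make_traj(c(0, 1, 2, 3, 4), rep(0, 5), meta, cell_id = "ok")
  both <- dplyr::bind_rows(short, ok)
  attr(both, "meta") <- meta
  ep <- compute_endpoints(both, burst_threshold_um_s = 10)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$flag[ep$cell_id == "c1"], "too-short")
  expect_equal(ep$flag[ep$cell_id == "ok"], "ok")
})

test_that("total distance and average speed use valid path and observed time", {
  meta <- recording_meta(fps = 30, duration_s = 10, um_per_px = 1)
  # 299 steps of 5 um
  tr <- make_traj(seq(0, by = 5, length.out = 300), rep(0, 300), meta)
  ep <- compute_endpoints(tr, burst_threshold_um_s = Inf)
  expect_equal(ep$total_distance_mm, 299 * 5 / 1000)
  expect_equal(ep$avg_speed_mm_s, ep$total_distance_mm / ep$observed_time_s)
  expect_equal(ep$observed_time_s, 299 / 30)

  # track observed only 5 of 10 s at the same step length: same speed
  tr5 <- make_traj(seq(0, by = 5, length.out = 150), rep(0, 150), meta, frame = 0:149)
  ep5 <- compute_endpoints(tr5, burst_threshold_um_s = Inf)
  expect_equal(ep5$observed_time_s, 149 / 30)
  expect_equal(ep5$avg_speed_mm_s, ep$avg_speed_mm_s)

  # stationary cell: zero distance, meandering undefined and flagged
  stat <- make_traj(rep(1, 10), rep(1, 10), tiny_meta(10))
  eps <- compute_endpoints(stat, burst_threshold_um_s = 1)
  expect_equal(eps$total_distance_mm, 0)
  expect_true(is.na(eps$meandering_deg_um))
  expect_equal(eps$flag, "zero-distance")
  expect_equal(eps$angular_velocity_deg_s, 0)
})

test_that("polygonal circle distance is slightly below the true circumference", {
  meta <- recording_meta(fps = 30, duration_s = 10, um_per_px = 1)
  theta <- seq(0, 2 * pi, length.out = 301)[1:300]
  tr <- make_traj(100 * cos(theta), 100 * sin(theta), meta)
  ep <- compute_endpoints(tr, burst_threshold_um_s = Inf)
  # closed-form chord sum for 299 chords of a 300-gon arc
  chord <- 2 * 100 * sin(pi / 300)
  expect_equal(ep$total_distance_mm, 299 * chord / 1000, tolerance = 1e-12)
  expect_lt(ep$total_distance_mm, 2 * pi * 100 / 1000)
})

test_that("burst threshold follows the linear-interpolation Q3 convention and strict exceedance", {
  expect_equal(burst_threshold(c(1, 2, 3, 4)), 3.25)
  expect_equal(burst_threshold(rep(7, 10)), 7)
  expect_error(burst_threshold(c(1, 2, 3)), "at least 4")

  meta <- tiny_meta(6)
  # integer step lengths 1,5,1,5,5 um at 30 fps -> speeds 30,150,30,150,150 exactly
  tr <- make_traj(cumsum(c(0, 1, 5, 1, 5, 5)), rep(0, 6), meta)
  st <- step_series(tr, meta)
  expect_identical(st$speed_um_s, c(30, 150, 30, 150, 150))
  ep4 <- compute_endpoints(tr, burst_threshold_um_s = 120)
  expect_equal(ep4$burst_count, 3)
  # all fast speeds equal to the threshold: strict inequality counts none
  epeq <- compute_endpoints(tr, burst_threshold_um_s = 150)
  expect_equal(epeq$burst_count, 0)
})

test_that("per-cell burst policy thresholds each cell against its own speeds", {
  meta <- tiny_meta(10)
  slow <- purrr::map(1:3, ~ make_traj(cumsum(c(0, rep(1, 9))), rep(0, 10), meta,
    cell_id = paste0("slow", .x)
  ))
  fast <- make_traj(cumsum(c(0, rep(10, 9))), rep(0, 10), meta, cell_id = "fast")
  both <- dplyr::bind_rows(c(slow, list(fast)))
  attr(both, "meta") <- meta
  per <- compute_endpoints(both, burst_policy = "per-cell")
  # constant speeds: each cell's Q3 equals its speed, so no exceedances
  expect_equal(per$burst_count, rep(0L, 4), ignore_attr = TRUE)
  pooled <- compute_endpoints(both, burst_policy = "pooled")
  # pooled Q3 of 27 slow + 9 fast speeds = 30 + 0.25*(300-30) = 97.5
  expect_equal(attr(pooled, "burst_threshold_um_s"), 97.5)
  expect_equal(pooled$burst_count[pooled$cell_id == "fast"], 9)
  expect_true(all(pooled$burst_count[pooled$cell_id != "fast"] == 0))
})

test_that("angular endpoints: magnitude averaging, meandering ratio, coordinate scaling", {
  meta <- recording_meta(fps = 30, duration_s = 1, um_per_px = 1)
  n <- 30
  # alternating +10/-10 turns
  turns <- rep(c(10, -10), length.out = n - 2)
  head <- cumsum(c(0, turns)) * pi / 180
  x <- cumsum(c(0, cos(head)))
  y <- cumsum(c(0, sin(head)))
  tr <- make_traj(x, y, meta)
  ep <- compute_endpoints(tr, burst_threshold_um_s = Inf)
  expect_equal(ep$angular_velocity_deg_s, 10 * 30, tolerance = 1e-9)

  # circle: 3 deg per 5 um step -> 0.6 deg/um in the long-track limit;
  # exactly (n-2) turns over (n-1) steps here
  turns2 <- rep(3, n - 2)
  head2 <- cumsum(c(0, turns2)) * pi / 180
  tr2 <- make_traj(cumsum(c(0, 5 * cos(head2))), cumsum(c(0, 5 * sin(head2))), meta)
  ep2 <- compute_endpoints(tr2, burst_threshold_um_s = Inf)
  expect_equal(ep2$meandering_deg_um, 3 * (n - 2) / (5 * (n - 1)), tolerance = 1e-9)

  # doubling coordinates doubles distance, leaves angles: meandering halves
  tr2x <- tr2
  tr2x$x_um <- 2 * tr2$x_um
  tr2x$y_um <- 2 * tr2$y_um
  ep2x <- compute_endpoints(tr2x, meta = meta, burst_threshold_um_s = Inf)
  expect_equal(ep2x$meandering_deg_um, ep2$meandering_deg_um / 2, tolerance = 1e-9)
  expect_equal(ep2x$angular_velocity_deg_s, ep2$angular_velocity_deg_s, tolerance = 1e-9)
})

test_that("rotation counting: half-turn excursions with overshoot carry, by sign", {
  # 900 deg accumulated -> 5; 897 deg -> 4; mirror swaps cw/ccw
  build_circular <- function(turn_deg, n_turns, meta) {
    head <- cumsum(c(0, rep(turn_deg, n_turns))) * pi / 180
    make_traj(cumsum(c(0, 5 * cos(head))), cumsum(c(0, 5 * sin(head))), meta)
  }
  meta <- recording_meta(fps = 30, duration_s = 11, um_per_px = 1)
  tr900 <- build_circular(3, 300, meta)
  ep900 <- compute_endpoints(tr900, burst_threshold_um_s = Inf)
  expect_equal(ep900$rotation_ccw, 5)
  expect_equal(ep900$rotation_cw, 0)

  tr897 <- build_circular(3, 299, meta)
  ep897 <- compute_endpoints(tr897, burst_threshold_um_s = Inf)
  expect_equal(ep897$rotation_ccw, 4)

  mirror <- tr900
  mirror$y_um <- -mirror$y_um
  epm <- compute_endpoints(mirror, meta = meta, burst_threshold_um_s = Inf)
  expect_equal(epm$rotation_cw, 5)
  expect_equal(epm$rotation_ccw, 0)
  expect_equal(epm$rotation_count, ep900$rotation_count)
})

test_that("endpoints are invariant to translation and rotation of the arena", {
  meta <- tiny_meta(10)
  cols <- c(
    "total_distance_mm", "avg_speed_mm_s", "burst_count",
    "angular_velocity_deg_s", "meandering_deg_um",
    "rotation_cw", "rotation_ccw", "rotation_count"
  )
  set.seed(42)
  for (i in 1:20) {
    tr <- random_short_traj(meta)
    ep0 <- compute_endpoints(tr, burst_threshold_um_s = 30)

    shift <- tr
    shift$x_um <- shift$x_um + 123.4
    shift$y_um <- shift$y_um - 98.7
    eps <- compute_endpoints(shift, meta = meta, burst_threshold_um_s = 30)
    expect_equal(eps[cols], ep0[cols], tolerance = 1e-9)

    a <- runif(1, 0, 2 * pi)
    rot <- tr
    rot$x_um <- cos(a) * tr$x_um - sin(a) * tr$y_um
    rot$y_um <- sin(a) * tr$x_um + cos(a) * tr$y_um
    epr <- compute_endpoints(rot, meta = meta, burst_threshold_um_s = 30)
    expect_equal(epr[cols], ep0[cols], tolerance = 1e-9)
  }
})

test_that("bookkeeping invariants hold on random trajectories", {
  meta <- tiny_meta(10)
  set.seed(99)
  for (i in 1:50) {
    tr <- random_short_traj(meta)
    st <- step_series(tr, meta)
    ep <- compute_endpoints(tr, burst_threshold_um_s = 0)
    # speed x time = distance
    if (ep$observed_time_s > 0) {
      expect_equal(ep$avg_speed_mm_s * ep$observed_time_s, ep$total_distance_mm,
        tolerance = 1e-9
      )
    }
    # path length >= net displacement (first to last valid position)
    v <- tr[tr$valid, ]
    net <- sqrt((v$x_um[nrow(v)] - v$x_um[1])^2 + (v$y_um[nrow(v)] - v$y_um[1])^2)
    if (all(st$step_valid)) expect_gte(ep$total_distance_mm * 1000 + 1e-9, net)
    # turns wrapped, counts bounded
    turns <- st$turn_deg[!is.na(st$turn_deg)]
    expect_true(all(turns > -180 & turns <= 180))
    expect_lte(ep$burst_count, sum(st$step_valid))
    if (!is.na(ep$meandering_deg_um)) expect_gte(ep$meandering_deg_um, 0)
  }
})

test_that("halving the frame rate preserves average speed for smooth swimmers", {
  p <- wildtype_params(tumble_prob = 0, heading_sd_deg = 2, burst_prob = 0)
  meta <- recording_meta(fps = 30, duration_s = 10, um_per_px = 1.62)
  tr <- simulate_swimmer(p, seed = 11)
  full <- compute_endpoints(tr, meta = meta, burst_threshold_um_s = Inf)
  half <- tr[tr$frame %% 2 == 0, ]
  meta15 <- recording_meta(fps = 15, duration_s = 10, um_per_px = 1.62)
  half$frame <- half$frame %/% 2L
  ep_half <- compute_endpoints(half, meta = meta15, burst_threshold_um_s = Inf)
  expect_equal(ep_half$avg_speed_mm_s, full$avg_speed_mm_s, tolerance = 0.1)
})

test_that("endpoints match the brute-force oracle on random short trajectories", {
  meta <- tiny_meta(10)
  set.seed(7)
  for (i in 1:50) {
    res <- endpoints_vs_oracle(random_short_traj(meta), meta)
    expect_equal(res$got$total_distance_mm, res$want$total_distance_mm, tolerance = 1e-9)
    expect_equal(res$got$avg_speed_mm_s, res$want$avg_speed_mm_s, tolerance = 1e-9)
    expect_identical(as.integer(res$got$burst_count), as.integer(res$want$burst_count))
    expect_equal(res$got$angular_velocity_deg_s, res$want$angular_velocity_deg_s, tolerance = 1e-9)
    expect_equal(res$got$meandering_deg_um, res$want$meandering_deg_um, tolerance = 1e-9)
    expect_identical(
      c(res$got$rotation_cw, res$got$rotation_ccw),
      c(res$want$rotation_cw, res$want$rotation_ccw)
    )
  }
})
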