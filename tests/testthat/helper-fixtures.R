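# In-code fixtures shared across test files.

tiny_meta <- function(n_frames = 10, fps = 30, um_per_px = 1) {
  recording_meta(
    fps = fps, duration_s = n_frames / fps,
    um_per_px = um_per_px, recording_id = "test"
  )
}

# Build a one-cell trajectory tibble from micrometre coordinates.
make_traj <- function(x_um, y_um, meta, cell_id = "c1",
                      frame = seq_along(x_um) - 1L, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(x_um) & is.finite(y_um)
  full <- tibble::tibble(
    cell_id = cell_id,
    frame = seq_len(meta$n_frames) - 1L,
    x_px = NA_real_, y_px = NA_real_, x_um = NA_real_, y_um = NA_real_,
    valid = FALSE
  )
  full$x_um[frame + 1L] <- ifelse(valid, x_um, NA_real_)
  full$y_um[frame + 1L] <- ifelse(valid, y_um, NA_real_)
  full$x_px <- full$x_um / meta$um_per_px
  full$y_px <- full$y_um / meta$um_per_px
  full$valid[frame + 1L] <- valid
  attr(full, "meta") <- meta
  full
}

# Random short trajectory (<= 10 frames) with occasional dropouts and
# occasional repeated positions, for oracle-equivalence sweeps.
random_short_traj <- function(meta, cell_id = "c1") {
  n <- sample(3:meta$n_frames, 1)
  frame <- sort(sample(seq_len(meta$n_frames) - 1L, n))
  x <- round(runif(n, -50, 50), 2)
  y <- round(runif(n, -50, 50), 2)
  if (n >= 5 && runif(1) < 0.3) { # occasional stationary stretch
    i <- sample(seq_len(n - 1), 1)
    x[i + 1] <- x[i]
    y[i + 1] <- y[i]
  }
  valid <- runif(n) > 0.1
  if (sum(valid) < 3) valid[sample(n, 3)] <- TRUE
  make_traj(x, y, meta, cell_id = cell_id, frame = frame, valid = valid)
}

endpoints_vs_oracle <- function(traj, meta, max_gap = 5) {
  st <- step_series(traj, meta, max_gap_frames = max_gap)
  thr <- if (sum(st$step_valid) >= 4) {
    burst_threshold(pooled_speeds(st))
  } else {
    0
  }
  got <- compute_endpoints(
    traj,
    meta = meta, max_gap_frames = max_gap,
    burst_threshold_um_s = thr
  )
  want <- oracle_endpoints(
    traj$frame, traj$x_um, traj$y_um, traj$valid,
    fps = meta$fps, max_gap_frames = max_gap, burst_thr = thr
  )
  list(got = got, want = want)
}

# Three programmed behaviour regimes for cluster-recovery checks:
# normal, slowed-but-straight, slow-and-tortuous.
regime_params <- function(regime) {
  switch(regime,
    normal = wildtype_params(180, n_frames = 120),
    slow_straight = wildtype_params(90,
      n_frames = 120, tumble_prob = 0.01,
      heading_sd_deg = 4
    ),
    slow_tortuous = wildtype_params(90,
      n_frames = 120, tumble_prob = 0.25,
      heading_sd_deg = 25, tumble_turn_sd_deg = 150
    )
  )
}

regime_endpoints <- function(n_groups_per_regime = 2, n_cells = 20, seed0 = 100) {
  grid <- expand.grid(
    regime = c("normal", "slow_straight", "slow_tortuous"),
    rep = seq_len(n_groups_per_regime), stringsAsFactors = FALSE
  )
  purrr::map2_dfr(grid$regime, grid$rep, function(rg, rp) {
    compute_endpoints(
      simulate_cohort(n_cells, regime_params(rg),
        seed = seed0 + match(rg, c("normal", "slow_straight", "slow_tortuous")) * 10 + rp,
        group_label = paste0(rg, "_", rp)
      ),
      burst_threshold_um_s = 200
    )
  })
}
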