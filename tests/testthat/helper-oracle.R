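# Brute-force endpoint oracle: a direct frame-by-frame transcription of the
# endpoint definitions, written independently of the package internals.
# Everything is plain loops; angles are wrapped with a different formula than
# the package uses.

oracle_wrap <- function(d) {
  w <- d %% 360
  if (w > 180) w <- w - 360
  w
}

# frame/x_um/y_um/valid: one cell, frame-indexed vectors of equal length.
# Returns the six endpoints plus observed time and step/turn series.
oracle_endpoints <- function(frame, x_um, y_um, valid, fps,
                             max_gap_frames = 5, burst_thr = Inf) {
  vi <- which(valid)
  f <- frame[vi]
  x <- x_um[vi]
  y <- y_um[vi]
  n <- length(f)

  step_len <- c()
  step_speed <- c()
  step_dt <- c()
  step_seg <- c()
  headings <- c()
  seg <- 1L
  for (i in seq_len(max(n - 1, 0))) {
    dt <- f[i + 1] - f[i]
    if (dt > max_gap_frames) {
      seg <- seg + 1L
      step_len <- c(step_len, NA)
      step_speed <- c(step_speed, NA)
      step_dt <- c(step_dt, NA)
      step_seg <- c(step_seg, NA)
      headings <- c(headings, NA)
      next
    }
    len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    h <- if (len == 0) {
      # zero-length: inherit the last defined heading of this segment
      last <- NA
      for (j in rev(seq_len(i - 1))) {
        if (!is.na(step_seg[j]) && step_seg[j] == seg && !is.na(headings[j])) {
          last <- headings[j]
          break
        }
      }
      last
    } else {
      atan2(y[i + 1] - y[i], x[i + 1] - x[i]) * 180 / pi
    }
    step_len <- c(step_len, len)
    step_speed <- c(step_speed, len * fps / dt)
    step_dt <- c(step_dt, dt)
    step_seg <- c(step_seg, seg)
    headings <- c(headings, h)
  }

  turns <- c()
  turn_seg <- c()
  for (i in seq_len(max(length(headings) - 1, 0))) {
    same <- !is.na(step_seg[i]) && !is.na(step_seg[i + 1]) && step_seg[i] == step_seg[i + 1]
    t <- if (same && step_len[i + 1] == 0) {
      0 # a zero-length step reorients by nothing
    } else if (same && !is.na(headings[i]) && !is.na(headings[i + 1])) {
      oracle_wrap(headings[i + 1] - headings[i])
    } else {
      NA
    }
    turns <- c(turns, t)
    turn_seg <- c(turn_seg, if (same) step_seg[i + 1] else NA)
  }

  keep <- !is.na(step_len)
  total_um <- sum(step_len[keep])
  time_s <- sum(step_dt[keep]) / fps
  tk <- which(!is.na(turns))

  cw <- 0L
  ccw <- 0L
  acc <- 0
  cur_seg <- NA
  for (i in tk) {
    if (is.na(cur_seg) || turn_seg[i] != cur_seg) acc <- 0
    cur_seg <- turn_seg[i]
    acc <- acc + turns[i]
    # half-turn trigger with the same stated 1e-9 deg rounding tolerance
    while (acc >= 180 - 1e-9) {
      ccw <- ccw + 1L
      acc <- acc - 180
    }
    while (acc <= -(180 - 1e-9)) {
      cw <- cw + 1L
      acc <- acc + 180
    }
  }

  list(
    total_distance_mm = total_um / 1000,
    avg_speed_mm_s = if (time_s > 0) (total_um / 1000) / time_s else NA_real_,
    burst_count = sum(step_speed[keep] > burst_thr),
    angular_velocity_deg_s = if (length(tk) > 0) mean(abs(turns[tk])) * fps else NA_real_,
    meandering_deg_um = if (total_um > 0) sum(abs(turns[tk])) / total_um else NA_real_,
    rotation_cw = cw,
    rotation_ccw = ccw,
    rotation_count = cw + ccw,
    observed_time_s = time_s
  )
}

# Exact two-sided Mann-Whitney p value by exhaustive enumeration of all
# C(n1+n2, n1) assignments of the pooled ranks (tie-free data only).
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}
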