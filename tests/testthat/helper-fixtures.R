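# shared fixtures, built in code

# a small uniform trial with sinusoidal channels (no gait structure)
make_uniform_trial <- function(n = 500, rate = 50, walkway_length = 25) {
  t <- (seq_len(n) - 1) / rate
  sensor_trial(
    t = t,
    acc_forward = sin(2 * pi * 1.8 * t),
    acc_vertical = cos(2 * pi * 1.8 * t),
    acc_ml = sin(2 * pi * 0.9 * t),
    azimuth = rep(90, n),
    walkway_length = walkway_length
  )
}

# a hand-made calibration profile for micro-tests of the detector
make_profile <- function(locking_period = 0.3, axis = "forward",
                         bt = 1, bt_v = 1, rate = 50) {
  structure(
    list(locking_period = locking_period, primary_axis = axis,
         boundary_threshold = bt, boundary_threshold_vertical = bt_v,
         calib_window = c(0, 5), rate = rate),
    class = "calib_profile"
  )
}

# a single walkway segment covering [start, end]
make_walkway <- function(start, end) {
  seg <- data.frame(kind = "walkway", start = start, end = end,
                    index = 1L, degenerate = FALSE)
  class(seg) <- c("walk_segments", "data.frame")
  seg
}

# triangular pulse train on a flat baseline: peak k has height `heights[k]`
# at time `centers[k]`, rising/falling over `width` seconds
make_pulse_signal <- function(centers, heights, t, width = 0.12) {
  x <- numeric(length(t))
  for (k in seq_along(centers)) {
    tri <- pmax(0, 1 - abs(t - centers[k]) / width)
    x <- x + heights[k] * tri
  }
  x
}

# step_events row builder for outcome tests
make_events <- function(times, sides, walkway) {
  ev <- data.frame(
    peak_idx = seq_along(times), peak_time = times, peak_value = 1,
    left_diff = 1, right_diff = 1, foot_strike_time = times,
    side = sides, side_margin = 1, walkway_index = walkway,
    recovered = FALSE
  )
  class(ev) <- c("step_events", "data.frame")
  ev
}
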