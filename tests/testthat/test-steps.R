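test_that("locking-period rule follows its three branches", {
  expect_equal(locking_period_rule(c(0.50, 0.52, 0.55)), 0.275)
  expect_equal(locking_period_rule(c(0.30, 0.80)), 0.275)  # mean/2 branch
  expect_equal(locking_period_rule(c(0.35, 0.30)), 0.21)   # max*0.6 branch
  expect_error(locking_period_rule(numeric(0)))
})

test_that("locking period from a signal matches the crossing intervals", {
  # 2 Hz sinusoid: positive zero crossings every 0.5 s -> max/2 = 0.25 s
  t <- (0:499) / 50
  x <- sin(2 * pi * 2 * t)
  expect_equal(compute_locking_period(x, 50), 0.25, tolerance = 0.01)
  expect_error(compute_locking_period(rep(1, 100), 50), "zero crossings")
})

test_that("axis selection follows the direction-reversal ratio", {
  t <- (0:249) / 50
  slow <- sin(2 * pi * 2 * t)   # 2 reversals per cycle, 10 cycles
  fast <- sin(2 * pi * 3.2 * t) # 16 cycles -> ratio 1.6
  expect_equal(select_axis(slow, slow + 0), "forward")     # ratio 1.0
  expect_equal(select_axis(fast, slow), "vertical")        # ratio > 1.4
  expect_equal(select_axis(slow, fast), "forward")         # ratio < 1
  expect_warning(out <- select_axis(slow, rep(0, 250)), "forward")
  expect_equal(out, "forward")
})

test_that("shape-similarity ratios accept and reject per the 0.35 rule", {
  rate <- 50
  t <- (0:(6 * rate)) / rate
  prof <- make_profile(locking_period = 0.3, bt = 1, rate = rate)
  seg <- make_walkway(0, 6)
  # peak 1 height 2.0 (diffs 2/2); peak 2 height varies; then a stable tail
  base <- c(1, 2, 3.5, 4.5)
  run_heights <- function(h2) {
    x <- make_pulse_signal(base, c(2, h2, 2, 2), t)
    detect_steps(x, t, prof, seg)
  }
  # ratio 0.6/2 = 0.30 <= 0.35: rejected
  ev_rej <- run_heights(0.6)
  expect_false(any(abs(ev_rej$peak_time - 2) < 0.15))
  # ratio 0.8/2 = 0.40 > 0.35: accepted
  ev_acc <- run_heights(0.8)
  expect_true(any(abs(ev_acc$peak_time - 2) < 0.15))
  # the amplitude floor rejects low-prominence candidates outright
  x_low <- make_pulse_signal(base, c(2, 0.3, 2, 2), t)
  ev_low <- detect_steps(x_low, t, prof, seg)
  expect_false(any(abs(ev_low$peak_time - 2) < 0.15))
})

test_that("missed steps are recovered and unexplained gaps become stops", {
  rate <- 50
  t <- (0:(8 * rate)) / rate
  prof <- make_profile(locking_period = 0.25, bt = 1, bt_v = 0.5,
                       rate = rate)
  seg <- make_walkway(0, 8)
  centers <- seq(1, 7, by = 0.5)
  drop_idx <- 6  # remove the peak at 3.5 s
  heights <- rep(2, length(centers))
  x_full <- make_pulse_signal(centers, heights, t)
  x_gap <- make_pulse_signal(centers[-drop_idx], heights[-drop_idx], t)
  # a weak echo of the missing step remains in the gap: its shape ratio
  # (0.325) fails the 0.35 detection rule but passes the 0.30 recovery rule
  x_gap2 <- x_gap + make_pulse_signal(3.5, 0.65, t)
  other <- make_pulse_signal(centers, rep(2, length(centers)), t)

  ev <- detect_steps(x_gap2, t, prof, seg)
  rec <- recover_missed_steps(ev, x_gap2, other, t, prof)
  hit <- abs(rec$events$peak_time - 3.5) < 0.1
  expect_true(any(hit))
  expect_true(all(rec$events$recovered[hit]))
  expect_equal(nrow(rec$stops), 0L)

  # monotonicity: recovery can only add events
  expect_gte(nrow(rec$events), nrow(ev))

  # a long silent gap becomes a stop spanning it
  x_stop <- make_pulse_signal(centers[centers < 3 | centers > 6],
                              rep(2, sum(centers < 3 | centers > 6)), t)
  ev2 <- detect_steps(x_stop, t, prof, seg)
  rec2 <- recover_missed_steps(ev2, x_stop, 0 * t, t, prof)
  expect_equal(nrow(rec2$events), nrow(ev2))
  expect_equal(nrow(rec2$stops), 1L)
  expect_lte(rec2$stops[1, 1], 3)
  expect_gte(rec2$stops[1, 2], 6)
})

test_that("foot strikes are timed at the raw forward minimum, ties to the earlier sample", {
  rate <- 50
  t <- (0:199) / rate
  prof <- make_profile(locking_period = 0.4, rate = rate)
  ev <- make_events(2.0, "left", 1L)
  ev$peak_idx <- which.min(abs(t - 2.0))
  raw <- rep(0, length(t))
  raw[which.min(abs(t - 1.96))] <- -8  # spike 40 ms before the peak
  out <- time_foot_strikes(ev, raw, t, prof)
  expect_equal(out$foot_strike_time, 1.96)

  raw2 <- rep(0, length(t))
  raw2[which.min(abs(t - 1.92))] <- -8
  raw2[which.min(abs(t - 2.08))] <- -8  # symmetric equal-depth double spike
  out2 <- time_foot_strikes(ev, raw2, t, prof)
  expect_equal(out2$foot_strike_time, 1.92)
})

test_that("clean synthetic trials are fully detected within the video tolerance", {
  sc <- gait_scenario(cadence = 115, step_length_mean = 0.9, noise_sd = 0,
                      n_minutes = 2, seed = 302)
  g <- generate_trial(sc)
  res <- run_sixmwt(g$trial)
  ev <- evaluate_detection(res, g$truth)
  expect_equal(ev$n_detected, ev$n_true)
  expect_true(all(ev$abs_dt <= 0.07))

  # locking-period exclusion: no two steps closer than the locking period
  for (w in unique(res$events$walkway_index)) {
    pt <- res$events$peak_time[res$events$walkway_index == w]
    if (length(pt) > 1) {
      expect_gte(min(diff(pt)), res$profile$locking_period - 1e-9)
    }
  }
  # count bound per walkway
  ws <- res$segments[res$segments$kind == "walkway", ]
  for (i in seq_len(nrow(ws))) {
    n_w <- sum(res$events$walkway_index == ws$index[i])
    expect_lte(n_w,
               (ws$end[i] - ws$start[i]) / res$profile$locking_period + 1)
  }
})

test_that("the atypical archetype switches detection to the vertical axis", {
  g_t <- generate_trial(gait_scenario(cadence = 110, noise_sd = 0.2,
                                      seed = 303, n_minutes = 2))
  g_a <- generate_trial(gait_scenario(cadence = 110, noise_sd = 0.2,
                                      archetype = "atypical_multipeak",
                                      seed = 303, n_minutes = 2))
  expect_equal(run_sixmwt(g_t$trial)$profile$primary_axis, "forward")
  expect_equal(run_sixmwt(g_a$trial)$profile$primary_axis, "vertical")
})
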