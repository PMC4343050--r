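# build a trial's segments and events: `counts[i]` steps in walkway i at the
# given step interval; the last walkway is the partial one
make_trial_layout <- function(counts, intervals, turn_dur = 2) {
  stopifnot(length(counts) == length(intervals))
  segs <- NULL
  events <- NULL
  cur <- 0
  for (i in seq_along(counts)) {
    fs <- cur + intervals[i] * seq_len(counts[i])
    w_end <- max(fs) + intervals[i] / 2
    segs <- rbind(segs, data.frame(kind = "walkway", start = cur,
                                   end = w_end, index = i,
                                   degenerate = FALSE))
    events <- rbind(events, make_events(
      fs, rep(c("left", "right"), length.out = counts[i]), i
    ))
    if (i < length(counts)) {
      segs <- rbind(segs, data.frame(kind = "turn", start = w_end,
                                     end = w_end + turn_dur,
                                     index = NA_integer_,
                                     degenerate = FALSE))
      cur <- w_end + turn_dur
    }
  }
  class(segs) <- c("walk_segments", "data.frame")
  class(events) <- c("step_events", "data.frame")
  list(segments = segs, events = events)
}

test_that("walkway-decomposed distance follows the reference-walkway formula", {
  # 22 full walkways, reference (last full) has 36 steps, last partial 10;
  # last-walkway step duration ratio 0.95 (no slowdown scaling)
  lay <- make_trial_layout(c(rep(30, 21), 36, 10),
                           c(rep(0.5, 21), 0.5, 0.475))
  d <- compute_distance(lay$segments, lay$events, 25)
  expect_equal(d$n_full_walkways, 22L)
  expect_equal(d$reference_walkway, 22L)
  expect_equal(d$total_distance, 22 * 25 + 10 * 25 / 36, tolerance = 1e-9)

  # ratio 0.85 < 0.9: step length scaled by the ratio
  lay2 <- make_trial_layout(c(rep(30, 21), 36, 10),
                            c(rep(0.5, 21), 0.5, 0.425))
  d2 <- compute_distance(lay2$segments, lay2$events, 25)
  expect_equal(d2$duration_ratio, 0.85, tolerance = 1e-9)
  expect_equal(d2$total_distance, 22 * 25 + 10 * (25 / 36) * 0.85,
               tolerance = 1e-9)
})

test_that("distance identity holds exactly and degenerates correctly", {
  lay <- make_trial_layout(c(28, 27, 29, 12), rep(0.5, 4))
  d <- compute_distance(lay$segments, lay$events, 25)
  expect_identical(d$total_distance,
                   d$n_full_walkways * 25 + d$last_walkway_distance)

  # empty last walkway: total is exactly n_full * L
  ev_nolast <- lay$events[lay$events$walkway_index != 4, ]
  d0 <- compute_distance(lay$segments, ev_nolast, 25)
  expect_equal(d0$total_distance, 3 * 25)
  expect_equal(d0$last_walkway_distance, 0)
})

test_that("a stop in the last full walkway moves the reference earlier", {
  lay <- make_trial_layout(c(28, 27, 29, 12), rep(0.5, 4))
  # stop inside walkway 3 (the last full one)
  w3 <- lay$segments[lay$segments$index == 3 &
                       lay$segments$kind == "walkway", ]
  stops <- rbind(c(mean(c(w3$start, w3$end)) - 1,
                   mean(c(w3$start, w3$end)) + 1))
  d <- compute_distance(lay$segments, lay$events, 25, stops = stops)
  expect_equal(d$reference_walkway, 2L)
  expect_equal(d$reference_step_length, 25 / 27)
})

test_that("uniform alternating gait yields the textbook outcome values", {
  ev <- make_events(c(0.5, 1.0, 1.5, 2.0),
                    c("left", "right", "left", "right"), 1L)
  seg <- make_walkway(0, 2.5)
  oc <- suppressWarnings(compute_gait_outcomes(ev, seg, walkway_length = 25))
  sc <- oc$scalars
  expect_equal(sc[["stride_time_mean"]], 1.0)
  expect_equal(sc[["symmetry_index"]], 1.0)
  expect_equal(sc[["step_time_mean_left"]], 0.5)
  expect_equal(sc[["step_time_mean_right"]], 0.5)
})

test_that("asymmetric step times give the ratio-form symmetry index", {
  # intervals alternate 0.55 (landing left) / 0.45 (landing right)
  times <- cumsum(c(0.5, rep(c(0.55, 0.45), 8)))
  sides <- c("right", rep(c("left", "right"), 8))
  ev <- make_events(times, sides, 1L)
  oc <- suppressWarnings(compute_gait_outcomes(ev, make_walkway(0, max(times) + 0.3), 25))
  expect_equal(oc$scalars[["step_time_mean_left"]], 0.55)
  expect_equal(oc$scalars[["step_time_mean_right"]], 0.45)
  expect_equal(oc$scalars[["symmetry_index"]], 0.55 / 0.45)

  oc2 <- suppressWarnings(
    compute_gait_outcomes(ev, make_walkway(0, max(times) + 0.3), 25,
                          symmetry_form = "asymmetry")
  )
  expect_equal(oc2$scalars[["symmetry_index"]], 0.1 / 0.5)
})

test_that("sides with fewer than 2 steps report NA, not zero", {
  ev <- make_events(c(0.5, 1.0), c("left", "right"), 1L)
  oc <- suppressWarnings(compute_gait_outcomes(ev, make_walkway(0, 1.5), 25))
  expect_true(is.na(oc$scalars[["step_time_mean_left"]]))
  expect_true(is.na(oc$scalars[["stride_time_mean"]]))
})

test_that("cadence excludes scripted stop time on synthetic trials", {
  sc <- gait_scenario(cadence = 113, step_length_mean = 0.9,
                      noise_sd = 0.25, stops = list(c(60, 3)),
                      n_minutes = 2, seed = 305)
  g <- generate_trial(sc)
  res <- run_sixmwt(g$trial)
  expect_equal(nrow(res$stops), 1L)
  cad <- res$outcomes$scalars[["cadence_overall"]]
  expect_lt(abs(cad - sc$cadence) / sc$cadence, 0.02)
})
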