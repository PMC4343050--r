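test_that("generation is deterministic given the scenario seed", {
  sc <- gait_scenario(seed = 42, n_minutes = 2)
  a <- generate_trial(sc)
  b <- generate_trial(sc)
  expect_identical(a$trial, b$trial)
  expect_identical(a$truth$foot_strikes, b$truth$foot_strikes)
  # a different seed changes the realisation
  c <- generate_trial(gait_scenario(seed = 43, n_minutes = 2))
  expect_false(identical(a$trial$acc_forward, c$trial$acc_forward))
})

test_that("the schedule matches its closed form and distance is exact", {
  sc <- gait_scenario(cadence = 110, step_length_mean = 0.9,
                      turn_duration = 2.5, seed = 306)
  g <- generate_trial(sc)
  truth <- g$truth
  p <- 60 / sc$cadence
  # closed form: steps ~ T / (step period + per-step share of turn time)
  expected <- 360 / (p + sc$step_length_mean * sc$turn_duration / 25)
  expect_lt(abs(length(truth$foot_strikes) - expected), 30)
  # one turn per completed walkway; the last may not finish before 6 min
  cycles <- 360 / ((25 / sc$step_length_mean) * p + sc$turn_duration)
  expect_gte(nrow(truth$turn_intervals), floor(cycles) - 1)
  # completed walkways contribute exactly L each
  n_turns <- nrow(truth$turn_intervals)
  expect_gte(truth$true_distance, n_turns * 25)
  expect_lte(truth$true_distance, (n_turns + 1) * 25)
  # invariants on the annotation object
  expect_true(all(diff(truth$foot_strikes) > 0))
  expect_equal(length(truth$sides), length(truth$foot_strikes))
})

test_that("trial channels respect their declared ranges", {
  g <- generate_trial(gait_scenario(seed = 307, n_minutes = 2))
  tr <- g$trial
  expect_true(all(tr$azimuth >= 0 & tr$azimuth < 360))
  expect_true(all(diff(tr$t) > 0))
  rates <- 1 / diff(tr$t)
  expect_lt(abs(mean(rates) - 50), 2)
  expect_lt(abs(sd(rates) - 3.84), 1.5)
})

test_that("a noise-free trial is detected perfectly", {
  g <- generate_trial(gait_scenario(noise_sd = 0, azimuth_noise_sd = 0,
                                    n_minutes = 2, seed = 308))
  res <- run_sixmwt(g$trial)
  ev <- evaluate_detection(res, g$truth)
  expect_equal(ev$count_accuracy_pct, 100)
  expect_equal(ev$within_tolerance_pct, 100)
})

test_that("evaluation metrics follow their definitions", {
  truth <- ground_truth(foot_strikes = seq(0.5, by = 0.5, length.out = 650),
                        sides = rep(c("left", "right"), 325),
                        true_distance = 550)
  det_same <- list(foot_strikes = truth$foot_strikes, sides = truth$sides)
  m <- evaluate_detection(det_same, truth)
  expect_equal(m$count_accuracy_pct, 100)
  expect_equal(m$mean_abs_dt, 0)
  expect_equal(m$side_agreement_pct, 100)

  det_shift <- list(foot_strikes = truth$foot_strikes + 0.05)
  m2 <- evaluate_detection(det_shift, truth)
  expect_equal(m2$within_tolerance_pct, 100)
  expect_equal(m2$mean_abs_dt, 0.05, tolerance = 1e-9)

  det_miss <- list(foot_strikes = truth$foot_strikes[-100])
  m3 <- evaluate_detection(det_miss, truth)
  expect_equal(m3$count_accuracy_pct, 100 * 649 / 650)
  expect_equal(round(m3$count_accuracy_pct, 2), 99.85)
  # one-to-one: no true event matched twice
  expect_lte(m3$n_matched, min(m3$n_detected, m3$n_true))
})

test_that("scripted stops and dropouts enter the ground truth correctly", {
  g_stop <- generate_trial(gait_scenario(stops = list(c(40, 3)),
                                         n_minutes = 2, seed = 309))
  expect_equal(nrow(g_stop$truth$stop_intervals), 1L)
  si <- g_stop$truth$stop_intervals
  expect_gt(si[1, 2] - si[1, 1], 2.9)
  # no strikes inside the stop
  expect_false(any(g_stop$truth$foot_strikes > si[1, 1] &
                     g_stop$truth$foot_strikes < si[1, 2]))

  g_drop <- generate_trial(gait_scenario(dropouts = list(c(40, 2.2)),
                                         cadence = 125, n_minutes = 2,
                                         seed = 310))
  di <- g_drop$truth$dropout_intervals
  expect_equal(nrow(di), 1L)
  # the walker keeps stepping through a dropout: strikes remain in truth
  hidden <- sum(g_drop$truth$foot_strikes > di[1, 1] &
                  g_drop$truth$foot_strikes < di[1, 2])
  expect_equal(hidden, 4L)
})
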