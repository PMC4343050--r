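test_that("read_trial reads well-formed files and filters bad rows", {
  df <- data.frame(time = (0:4) / 50, acc_forward = 1:5, acc_vertical = 0,
                   acc_ml = 0, azimuth = 90)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tr <- read_trial(path, walkway_length = 25)
  expect_s3_class(tr, "sensor_trial")
  expect_equal(n_samples(tr), 5L)
  expect_equal(tr$acc_forward, as.numeric(1:5))

  df$acc_ml[3] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_warning(tr2 <- read_trial(path, 25), "non-finite")
  expect_equal(n_samples(tr2), 4L)

  write.csv(df[, setdiff(names(df), "azimuth")], path, row.names = FALSE)
  expect_error(read_trial(path, 25), "azimuth")
})

test_that("regularize is the identity on uniform grids and interpolates linearly", {
  tr <- make_uniform_trial(n = 200, rate = 50)
  reg <- regularize(tr, 50)
  expect_equal(reg$t, tr$t, tolerance = 1e-9)
  expect_equal(reg$acc_forward, tr$acc_forward, tolerance = 1e-9)

  two <- sensor_trial(t = c(0, 1), acc_forward = c(0, 10),
                      acc_vertical = c(0, 10), acc_ml = c(0, 10),
                      azimuth = c(0, 10), walkway_length = 25)
  reg20 <- regularize(two, 20)
  expect_equal(n_samples(reg20), 21L)
  expect_equal(reg20$acc_forward, seq(0, 10, by = 0.5))

  expect_error(regularize(tr, 500), "target_rate")
  expect_error(regularize(tr, 4), "target_rate")
})

test_that("regularize is idempotent and respects the grid-length formula", {
  set.seed(7)
  # jittered grid, mean 50 Hz, SD 3.84 Hz
  dts <- 1 / pmax(rnorm(600, 50, 3.84), 30)
  t <- cumsum(c(0, dts))
  f <- function(t) 1.5 * sin(2 * pi * 1.7 * t) + 0.4 * cos(2 * pi * 0.6 * t)
  tr <- sensor_trial(t, f(t), f(t + 0.1), f(t + 0.2),
                     (20 * t) %% 360, walkway_length = 25)
  reg <- regularize(tr, 50)
  expect_equal(n_samples(reg),
               floor((t[length(t)] - t[1]) * 50) + 1)
  expect_lt(max(abs(diff(diff(reg$t)))), 1e-9)
  reg2 <- regularize(reg, 50)
  expect_lt(max(abs(reg2$acc_forward - reg$acc_forward)), 1e-9)

  # resampling error small against the analytic (dense oracle) values
  truth <- f(reg$t)
  expect_lt(sqrt(mean((reg$acc_forward - truth)^2)),
            0.05 * sqrt(mean(truth^2)))
})

test_that("regularize never interpolates azimuth across the wrap seam", {
  set.seed(8)
  dts <- 1 / pmax(rnorm(300, 50, 3.84), 30)
  t <- cumsum(c(0, dts))
  az <- (355 + 2 * t) %% 360  # drifts through north
  tr <- sensor_trial(t, sin(t), cos(t), sin(t), az, 25)
  reg <- regularize(tr, 50)
  # unwrapped output must be smooth: no artificial mid-seam values near 180
  cont <- correct_azimuth(reg$azimuth)
  expect_lt(max(abs(diff(cont))), 1)
})

test_that("outcome files round-trip at 6 decimals", {
  oc <- structure(
    list(
      scalars = c(total_distance_m = 542.42, total_steps = 650,
                  cadence_mean = 108.123456, symmetry_index = 1.0123),
      per_walkway = data.frame(walkway = 1:2, steps = c(27L, 26L),
                               duration_s = c(14.2, 13.9),
                               cadence = c(114.08, 112.23),
                               mean_step_length = c(0.9259, 0.9615))
    ),
    class = "trial_outcomes"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes(oc, path)
  txt <- readLines(path)
  expect_true(any(grepl("^total_distance_m,542.42", txt)))
  back <- read_outcomes(path)
  expect_equal(back$scalars, oc$scalars, tolerance = 1e-6)
  expect_equal(back$per_walkway$mean_step_length,
               oc$per_walkway$mean_step_length, tolerance = 1e-6)

  # degenerate per-walkway block: header only
  oc$per_walkway <- oc$per_walkway[0, ]
  write_outcomes(oc, path)
  back2 <- read_outcomes(path)
  expect_equal(nrow(back2$per_walkway), 0L)
})

test_that("ground-truth annotations round-trip", {
  gt <- ground_truth(
    foot_strikes = c(0.5, 1.0, 1.6), sides = c("left", "right", "left"),
    turn_intervals = rbind(c(14, 16.5)), stop_intervals = rbind(c(8, 10)),
    true_distance = 123.456
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$foot_strikes, gt$foot_strikes)
  expect_equal(back$sides, gt$sides)
  expect_equal(back$turn_intervals, gt$turn_intervals)
  expect_equal(back$stop_intervals, gt$stop_intervals)
  expect_equal(back$true_distance, 123.456)
})
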