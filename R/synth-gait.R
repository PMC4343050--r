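#' Define a synthetic walk-test scenario
#'
#' A `gait_scenario` fixes everything about one simulated 6-minute walk:
#' walkway geometry, gait (cadence, step length), turn duration, sensor
#' properties (jittery sampling, noise), waveform archetype, and scripted
#' events (true stops, signal dropouts). [generate_trial()] turns it into a
#' sensor recording plus exact ground truth.
#'
#' The waveforms emulate a phone worn backward at the mid lower back: each
#' foot strike puts a sharp negative transient in the raw forward channel
#' (riding on a smooth positive push-off lobe), the vertical channel carries
#' a smooth oscillation at step frequency peaking shortly *after* foot
#' strike plus its own strike transient, and the mediolateral channel
#' oscillates at stride frequency with a phase that encodes the stepping
#' side. The first/last steps of each walkway are attenuated (starting from
#' / slowing for a turn). Azimuth alternates between plateaus 180 degrees
#' apart with constant-rate ramps during turns, wrapped into `[0, 360)`.
#'
#' @param walkway_length Walkway length in metres (default 25).
#' @param cadence Steps per minute (default 112).
#' @param step_length_mean,step_length_sd Per-step length distribution in
#'   metres.
#' @param turn_duration Turn duration in seconds.
#' @param n_minutes Test duration in minutes (default 6).
#' @param noise_sd Accelerometer white-noise SD in m/s^2.
#' @param azimuth_noise_sd Azimuth noise SD in degrees.
#' @param sampling_rate_mean,sampling_rate_sd Jittery sampling-rate model in
#'   Hz (defaults 50 and 3.84).
#' @param archetype `"typical"` or `"atypical_multipeak"` (extra forward
#'   sub-peaks per cycle, forcing vertical-axis detection).
#' @param stops List of `c(time, duration)` true walking pauses.
#' @param dropouts List of `c(time, duration)` sensor dropouts: the walker
#'   keeps stepping but the acceleration channels go nearly flat.
#' @param boundary_attenuation Amplitude factor for the first/last 2 steps
#'   of each walkway, in `(0, 1]`.
#' @param lr_amplitude Mediolateral oscillation amplitude in m/s^2.
#' @param end_after_turn If `TRUE`, truncate the trial shortly (2 steps)
#'   after a turn, probing the hardest case for the last-walkway estimate.
#' @param seed Integer seed; generation is deterministic given the scenario.
#' @param label Optional scenario name.
#' @return A `gait_scenario` list.
#' @export
gait_scenario <- function(walkway_length = 25, cadence = 112,
                          step_length_mean = 0.95, step_length_sd = 0.02,
                          turn_duration = 2.5, n_minutes = 6,
                          noise_sd = 0.25, azimuth_noise_sd = 2,
                          sampling_rate_mean = 50, sampling_rate_sd = 3.84,
                          archetype = c("typical", "atypical_multipeak"),
                          stops = list(), dropouts = list(),
                          boundary_attenuation = 0.85, lr_amplitude = 1.2,
                          end_after_turn = FALSE, seed = 1L,
                          label = "scenario") {
  archetype <- match.arg(archetype)
  stopifnot(
    walkway_length > 0, cadence > 0, step_length_mean > 0,
    step_length_sd >= 0, turn_duration > 0, n_minutes > 0, noise_sd >= 0,
    azimuth_noise_sd >= 0, sampling_rate_mean > 0, sampling_rate_sd >= 0,
    boundary_attenuation > 0, boundary_attenuation <= 1, lr_amplitude >= 0
  )
  structure(
    list(walkway_length = walkway_length, cadence = cadence,
         step_length_mean = step_length_mean,
         step_length_sd = step_length_sd, turn_duration = turn_duration,
         n_minutes = n_minutes, noise_sd = noise_sd,
         azimuth_noise_sd = azimuth_noise_sd,
         sampling_rate_mean = sampling_rate_mean,
         sampling_rate_sd = sampling_rate_sd, archetype = archetype,
         stops = stops, dropouts = dropouts,
         boundary_attenuation = boundary_attenuation,
         lr_amplitude = lr_amplitude, end_after_turn = end_after_turn,
         seed = as.integer(seed), label = label),
    class = "gait_scenario"
  )
}

# waveform constants (m/s^2, s): push-off lobe, strike transient, vertical
# oscillation, and the atypical extra sub-peaks
.wave <- list(
  push_amp = 2.5, push_off = 0.00, push_sd = 0.055,
  spike_depth = 12.0, spike_sd = 0.02,
  vert_amp = 2.0, vert_off = 0.06, vert_sd = 0.06,
  vert_spike = 6.0, vert_spike_sd = 0.02,
  vert_base_frac = 0.35,
  atyp_amp = 2.4, atyp_sd = 0.05
)

# sharp biphasic strike transient: a narrow negative shock plus a wider
# rebound of equal area, so the 4 Hz-filtered signal keeps a single smooth
# peak per step while the raw channel shows a deep spike at foot strike
add_strike_transients <- function(y, t, centers, depths, sd) {
  y <- add_pulses(y, t, centers, -depths, sd)
  add_pulses(y, t, centers, depths / 2, 2 * sd)
}

# add Gaussian pulses of the given centres/amplitudes to y sampled at t
add_pulses <- function(y, t, centers, amps, sd) {
  if (length(centers) == 0L) return(y)
  half <- 4 * sd
  lo <- findInterval(centers - half, t) + 1L
  hi <- findInterval(centers + half, t)
  for (i in seq_along(centers)) {
    if (hi[i] < lo[i]) next
    idx <- lo[i]:hi[i]
    y[idx] <- y[idx] + amps[i] * exp(-0.5 * ((t[idx] - centers[i]) / sd)^2)
  }
  y
}

#' Generate a synthetic walk-test trial with ground truth
#'
#' Schedules strikes, turns, stops and dropouts from the scenario, then
#' renders the four sensor channels on a jittered time grid. Deterministic
#' given `scenario$seed`. The ground-truth foot-strike time is the centre of
#' the raw forward transient, i.e. the same instant the detection algorithm
#' defines as foot strike; the true distance is the exact sum of scheduled
#' step lengths (completed walkways sum exactly to the walkway length).
#'
#' @param scenario A [gait_scenario()].
#' @return A list with elements `trial` (a [sensor_trial()]) and `truth`
#'   (a [ground_truth()]).
#' @export
generate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(scenario$seed)

  sch <- schedule_gait(scenario)
  st <- sch$strikes
  w <- .wave
  p <- 60 / scenario$cadence

  # jittered time grid
  t_end <- sch$t_end
  dts <- 1 / pmin(pmax(stats::rnorm(ceiling(t_end * 80),
                                    scenario$sampling_rate_mean,
                                    scenario$sampling_rate_sd), 35), 70)
  t <- cumsum(c(0, dts))
  t <- t[t <= t_end]

  n <- length(t)
  fwd <- stats::rnorm(n, 0, scenario$noise_sd)
  vert <- stats::rnorm(n, 0, scenario$noise_sd)
  ml <- stats::rnorm(n, 0, scenario$noise_sd)

  amp_jit <- function(k) stats::runif(k, 0.9, 1.1)
  ns <- nrow(st)
  fwd <- add_pulses(fwd, t, st$time + w$push_off,
                    w$push_amp * st$att * amp_jit(ns), w$push_sd)
  fwd <- add_strike_transients(fwd, t, st$time,
                               w$spike_depth * st$att * amp_jit(ns),
                               w$spike_sd)
  vert <- add_pulses(vert, t, st$time + w$vert_off,
                     w$vert_amp * st$att * amp_jit(ns), w$vert_sd)
  vert <- add_strike_transients(vert, t, st$time,
                                w$vert_spike * st$att * amp_jit(ns),
                                w$vert_spike_sd)
  if (scenario$archetype == "atypical_multipeak") {
    fwd <- add_pulses(fwd, t, st$time + 0.25 * p,
                      w$atyp_amp * st$att * amp_jit(ns), w$atyp_sd)
    fwd <- add_pulses(fwd, t, st$time + 0.55 * p,
                      -w$atyp_amp * st$att * amp_jit(ns), w$atyp_sd)
    fwd <- add_pulses(fwd, t, st$time + 0.78 * p,
                      w$atyp_amp * st$att * amp_jit(ns), w$atyp_sd)
  }
  # mediolateral: phase encodes side (rightward acceleration during a right
  # step); one lobe per step at stride frequency
  sgn <- ifelse(st$side == "right", 1, -1)
  ml <- add_pulses(ml, t, st$time + 0.25 * p,
                   scenario$lr_amplitude * sgn * amp_jit(ns), 0.30 * p)

  # vertical baseline offset while walking, so the filtered vertical signal
  # crosses zero once per step
  base <- w$vert_base_frac * w$vert_amp
  walk_mask <- logical(n)
  for (wi in unique(st$walkway)) {
    ws <- st[st$walkway == wi, ]
    i0 <- findInterval(min(ws$time) - 0.6 * p, t) + 1L
    i1 <- findInterval(max(ws$time) + 0.8 * p, t)
    if (i1 >= i0) walk_mask[i0:i1] <- TRUE
  }
  for (s in seq_len(nrow(sch$stop_intervals))) {
    i0 <- findInterval(sch$stop_intervals[s, 1L], t) + 1L
    i1 <- findInterval(sch$stop_intervals[s, 2L], t)
    if (i1 >= i0) walk_mask[i0:i1] <- FALSE
  }
  vert[walk_mask] <- vert[walk_mask] - base

  # sensor dropouts: channels go nearly flat while the walker keeps going
  for (d in seq_len(nrow(sch$dropout_intervals))) {
    i0 <- findInterval(sch$dropout_intervals[d, 1L], t) + 1L
    i1 <- findInterval(sch$dropout_intervals[d, 2L], t)
    if (i1 >= i0) {
      flat <- i0:i1
      fwd[flat] <- 0.03 * fwd[flat]
      vert[flat] <- 0.03 * vert[flat]
      ml[flat] <- 0.03 * ml[flat]
    }
  }

  az <- synth_azimuth(t, sch$turns_render, scenario$azimuth_noise_sd)

  trial <- sensor_trial(
    t = t, acc_forward = fwd, acc_vertical = vert, acc_ml = ml, azimuth = az,
    walkway_length = scenario$walkway_length,
    meta = list(label = scenario$label, seed = scenario$seed,
                archetype = scenario$archetype)
  )
  truth <- ground_truth(
    foot_strikes = st$time, sides = st$side,
    turn_intervals = sch$turn_intervals,
    stop_intervals = sch$stop_intervals,
    true_distance = sum(st$length)
  )
  truth$cadence <- scenario$cadence
  truth$dropout_intervals <- sch$dropout_intervals
  list(trial = trial, truth = truth)
}

# schedule foot strikes, turns, stops and dropouts for a scenario
schedule_gait <- function(sc) {
  p <- 60 / sc$cadence
  L <- sc$walkway_length
  t_lim <- sc$n_minutes * 60
  horizon <- t_lim + 30  # overrun, trimmed after truncation

  strikes <- list()
  turns <- matrix(numeric(0), ncol = 2L)
  stop_iv <- matrix(numeric(0), ncol = 2L)
  stops_pending <- sc$stops
  cur <- p
  side <- "left"
  wi <- 1L
  while (cur < horizon) {
    # draw one walkway's step lengths summing exactly to L
    lens <- numeric(0)
    while (sum(lens) < L) {
      lens <- c(lens, max(0.2, stats::rnorm(1L, sc$step_length_mean,
                                            sc$step_length_sd)))
    }
    lens <- lens * (L / sum(lens))
    k <- length(lens)
    times <- numeric(k)
    for (j in seq_len(k)) {
      if (j > 1L) cur <- cur + p * (1 + stats::rnorm(1L, 0, 0.008))
      # scripted true stop: pause mid-walkway, then resume
      if (length(stops_pending) && j > 1L) {
        s0 <- stops_pending[[1L]]
        if (cur >= s0[1L]) {
          start <- times[j - 1L] + 0.35 * p
          stop_iv <- rbind(stop_iv, c(start, start + s0[2L]))
          cur <- cur + s0[2L]
          stops_pending <- stops_pending[-1L]
        }
      }
      times[j] <- cur
    }
    att <- rep(1, k)
    att[c(1L, min(2L, k))] <- sc$boundary_attenuation
    att[c(max(1L, k - 1L), k)] <- sc$boundary_attenuation
    strikes[[wi]] <- data.frame(
      time = times, side = rep(c(side, setdiff(c("left", "right"), side)),
                               length.out = k),
      length = lens, walkway = wi, att = att
    )
    side <- if (k %% 2L == 0L) side else setdiff(c("left", "right"), side)
    ts <- cur + 0.5 * p
    turns <- rbind(turns, c(ts, ts + sc$turn_duration))
    # the first stride out of a turn blends into the turn itself, so the
    # first strike follows the turn end after ~0.7 step periods
    cur <- ts + sc$turn_duration + 0.7 * p
    wi <- wi + 1L
  }
  st <- do.call(rbind, strikes)

  # truncation: nominal duration, or shortly after a turn when scripted
  t_end <- t_lim
  if (isTRUE(sc$end_after_turn)) {
    ok <- which(turns[, 2L] < t_lim - 3 * p)
    te <- turns[max(ok), 2L]
    after <- st$time[st$time > te]
    t_end <- after[2L] + 0.35
  }
  keep <- st$time <= t_end - 0.12
  st <- st[keep, , drop = FALSE]
  turns <- turns[turns[, 1L] < t_end, , drop = FALSE]
  # a turn in progress at the end of the trial keeps its rotation rate for
  # signal rendering; the truth interval is clipped to the trial span
  turns_render <- turns
  if (nrow(turns)) {
    # a turn barely begun when the trial ends is not a turn the walker made:
    # keep it in the truth only if the in-span rotation reaches the full
    # turning criterion (>= 100 of the 180 degrees)
    frac <- pmin(1, (t_end - turns[, 1L]) / (turns[, 2L] - turns[, 1L]))
    rot <- 180 * frac
    turns <- turns[rot >= 100, , drop = FALSE]
    turns[, 2L] <- pmin(turns[, 2L], t_end)
  }
  stop_iv <- stop_iv[stop_iv[, 1L] < t_end, , drop = FALSE]

  # dropouts snap to the strike schedule so a fixed number of strikes is
  # hidden regardless of timing jitter
  drop_iv <- matrix(numeric(0), ncol = 2L)
  for (d in sc$dropouts) {
    s0 <- st$time[st$time >= d[1L]][1L]
    if (is.na(s0)) next
    drop_iv <- rbind(drop_iv, c(s0 + 0.25 * p, s0 + 0.25 * p + d[2L]))
  }
  if (nrow(stop_iv) && nrow(turns)) {
    for (i in seq_len(nrow(stop_iv))) {
      if (any(stop_iv[i, 1L] < turns[, 2L] & stop_iv[i, 2L] > turns[, 1L])) {
        stop("scripted stop overlaps a turn; adjust the scenario",
             call. = FALSE)
      }
    }
  }
  list(strikes = st, turn_intervals = turns, turns_render = turns_render,
       stop_intervals = stop_iv, dropout_intervals = drop_iv, t_end = t_end)
}

# azimuth: plateaus 180 degrees apart with constant-rate ramps during turns
synth_azimuth <- function(t, turns, noise_sd) {
  az <- numeric(length(t))
  h <- 0
  last <- 1L
  if (nrow(turns)) {
    for (i in seq_len(nrow(turns))) {
      i0 <- findInterval(turns[i, 1L], t) + 1L
      i1 <- findInterval(turns[i, 2L], t)
      if (i0 > last) az[last:(i0 - 1L)] <- h
      delta <- if (h == 0) 180 else -180
      if (i1 >= i0) {
        frac <- (t[i0:i1] - turns[i, 1L]) / (turns[i, 2L] - turns[i, 1L])
        az[i0:i1] <- h + delta * frac
      }
      h <- h + delta
      last <- max(i1 + 1L, i0)
    }
  }
  if (last <= length(t)) az[last:length(t)] <- h
  az <- az + stats::rnorm(length(t), 0, noise_sd)
  wrap360(az)
}

#' The default 15-scenario synthetic evaluation suite
#'
#' Fifteen seeded scenarios mirroring an able-bodied walk-test cohort:
#' twelve typical gaits spanning cadences 100-125 steps/min and distances
#' roughly 455-675 m (one of them with a scripted 3 s mid-test stop), one
#' atypical multi-peak forward waveform (vertical-axis detection), one with
#' a ~2 s sensor dropout hiding four strikes, and one trial that ends just
#' after a turn (the hardest case for the final-walkway estimate).
#'
#' @param seed Master seed; each scenario derives its own sub-seed from it.
#' @return A list of 15 [gait_scenario()] objects.
#' @export
default_scenarios <- function(seed = 1L) {
  sub <- function(i) as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
  base <- list(
    list(cadence = 100, sl = 0.86, noise = 0.25, td = 2.5),
    list(cadence = 104, sl = 0.88, noise = 0.20, td = 2.5),
    list(cadence = 108, sl = 0.90, noise = 0.25, td = 3.0),
    list(cadence = 110, sl = 0.92, noise = 0.25, td = 2.5),
    list(cadence = 112, sl = 0.90, noise = 0.25, td = 2.0),
    list(cadence = 115, sl = 0.88, noise = 0.20, td = 2.5),
    list(cadence = 118, sl = 0.94, noise = 0.25, td = 2.5),
    list(cadence = 120, sl = 0.92, noise = 0.25, td = 2.0),
    list(cadence = 122, sl = 0.90, noise = 0.25, td = 2.5),
    list(cadence = 125, sl = 0.95, noise = 0.20, td = 2.0),
    list(cadence = 113, sl = 0.85, noise = 0.25, td = 2.5),
    list(cadence = 117, sl = 0.93, noise = 0.25, td = 2.5)
  )
  out <- vector("list", 15L)
  for (i in seq_along(base)) {
    b <- base[[i]]
    out[[i]] <- gait_scenario(
      cadence = b$cadence, step_length_mean = b$sl, noise_sd = b$noise,
      turn_duration = b$td, seed = sub(i),
      stops = if (i == 11L) list(c(150, 3)) else list(),
      label = sprintf("typical_%02d", i)
    )
  }
  out[[13L]] <- gait_scenario(
    cadence = 110, step_length_mean = 0.92, noise_sd = 0.20,
    turn_duration = 2.5, archetype = "atypical_multipeak", seed = sub(13L),
    label = "atypical_multipeak"
  )
  out[[14L]] <- gait_scenario(
    cadence = 125, step_length_mean = 0.88, noise_sd = 0.20,
    turn_duration = 1.8, dropouts = list(c(150, 2.2)), seed = sub(14L),
    label = "dropout"
  )
  out[[15L]] <- gait_scenario(
    cadence = 112, step_length_mean = 0.95, noise_sd = 0.25,
    turn_duration = 2.5, end_after_turn = TRUE, seed = sub(15L),
    label = "end_after_turn"
  )
  out
}

#' Compare pipeline output against ground truth
#'
#' Detected and true foot strikes are matched greedily one-to-one by nearest
#' time (closest pairs first, each event used at most once, pairs further
#' apart than 0.5 s never matched).
#'
#' @param result A `sixmwt_result` from [run_sixmwt()], or a list with
#'   `foot_strikes` (numeric), and optionally `sides`, `turns` (two-column
#'   matrix) and `total_distance`.
#' @param truth A [ground_truth()] object.
#' @param tolerance Timing tolerance in seconds for the within-tolerance
#'   fraction (default 0.07, i.e. 2 video frames at ~30 fps).
#' @return A list of metrics: `n_detected`, `n_true`, `count_accuracy_pct`
#'   (100 x detected/true), `n_matched`, `within_tolerance_pct` (matched
#'   within tolerance as % of true steps), `mean_abs_dt`, `sd_abs_dt`,
#'   `side_agreement_pct`, `turn_count_diff`, `distance_error_m`,
#'   `distance_error_pct`, and `abs_dt` (per-match vector).
#' @export
evaluate_detection <- function(result, truth, tolerance = 0.07) {
  if (inherits(result, "sixmwt_result")) {
    det <- list(
      foot_strikes = result$events$foot_strike_time,
      sides = result$events$side,
      turns = result$turns,
      total_distance = result$outcomes$scalars[["total_distance_m"]]
    )
  } else {
    det <- result
  }
  dt_det <- det$foot_strikes
  dt_tru <- truth$foot_strikes
  if (length(dt_det) == 0L || length(dt_tru) == 0L) {
    stop("need at least one detected and one true foot strike", call. = FALSE)
  }
  m <- abs(outer(dt_det, dt_tru, "-"))
  m[m > 0.5] <- NA
  ord <- order(m, na.last = NA)
  used_d <- logical(length(dt_det))
  used_t <- logical(length(dt_tru))
  pairs <- matrix(integer(0), ncol = 2L)
  for (o in ord) {
    i <- (o - 1L) %% length(dt_det) + 1L
    j <- (o - 1L) %/% length(dt_det) + 1L
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE
      used_t[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  abs_dt <- abs(dt_det[pairs[, 1L]] - dt_tru[pairs[, 2L]])
  side_agree <- if (!is.null(det$sides) && length(truth$sides)) {
    100 * mean(det$sides[pairs[, 1L]] == truth$sides[pairs[, 2L]])
  } else {
    NA_real_
  }
  dist_err <- if (!is.null(det$total_distance) &&
                  is.finite(truth$true_distance)) {
    abs(det$total_distance - truth$true_distance)
  } else {
    NA_real_
  }
  list(
    n_detected = length(dt_det),
    n_true = length(dt_tru),
    count_accuracy_pct = 100 * length(dt_det) / length(dt_tru),
    n_matched = nrow(pairs),
    within_tolerance_pct = 100 * sum(abs_dt <= tolerance) / length(dt_tru),
    mean_abs_dt = mean(abs_dt),
    sd_abs_dt = stats::sd(abs_dt),
    side_agreement_pct = side_agree,
    turn_count_diff = if (!is.null(det$turns)) {
      nrow(det$turns) - nrow(truth$turn_intervals)
    } else {
      NA_integer_
    },
    distance_error_m = dist_err,
    distance_error_pct = if (is.finite(dist_err)) {
      100 * dist_err / truth$true_distance
    } else {
      NA_real_
    },
    abs_dt = abs_dt
  )
}
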