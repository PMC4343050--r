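#' Locking period from zero-crossing intervals
#'
#' The locking period is the refractory window after a detected step during
#' which no second step is accepted. It is derived from the times between
#' consecutive positive-going zero crossings of the filtered vertical
#' acceleration in the self-calibration window:
#'
#' * default: half the maximum interval;
#' * if the maximum interval exceeds `long_threshold` (longer than a typical
#'   step, so crossings were missed): half the *mean* interval;
#' * if the maximum interval is below `short_threshold` (shorter than a
#'   typical step, so extra crossings occurred): the maximum interval times
#'   `short_factor`.
#'
#' @param intervals Numeric vector of times (seconds) between consecutive
#'   positive-going zero crossings.
#' @param long_threshold,short_threshold,short_factor Rule constants
#'   (defaults 0.7 s, 0.4 s, 0.6).
#' @return Locking period in seconds.
#' @export
locking_period_rule <- function(intervals, long_threshold = 0.7,
                                short_threshold = 0.4, short_factor = 0.6) {
  if (length(intervals) < 1L) {
    stop("need at least one zero-crossing interval", call. = FALSE)
  }
  mx <- max(intervals)
  if (mx > long_threshold) {
    mean(intervals) / 2
  } else if (mx < short_threshold) {
    mx * short_factor
  } else {
    mx / 2
  }
}

# times of positive-going zero crossings (linear interpolation between samples)
positive_zero_crossings <- function(x, t) {
  i <- which(x[-length(x)] < 0 & x[-1L] >= 0)
  if (length(i) == 0L) return(numeric(0))
  frac <- -x[i] / (x[i + 1L] - x[i])
  t[i] + frac * (t[i + 1L] - t[i])
}

#' Locking period from a filtered vertical acceleration window
#'
#' Finds positive-going zero crossings of the signal and applies
#' [locking_period_rule()] to the intervals between them.
#'
#' @param vertical_f4 Filtered (4 Hz low-pass) vertical acceleration over the
#'   calibration window.
#' @param rate Sampling rate in Hz.
#' @param ... Passed to [locking_period_rule()].
#' @return Locking period in seconds.
#' @export
compute_locking_period <- function(vertical_f4, rate, ...) {
  t <- (seq_along(vertical_f4) - 1L) / rate
  zc <- positive_zero_crossings(vertical_f4, t)
  if (length(zc) < 2L) {
    stop("calibration window has fewer than 2 positive zero crossings",
         call. = FALSE)
  }
  locking_period_rule(diff(zc), ...)
}

# number of direction reversals (sign changes of the first difference)
direction_reversals <- function(x) {
  d <- diff(x)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(d[-length(d)] * d[-1L] < 0)
}

#' Choose the primary step-detection axis
#'
#' The filtered forward acceleration is the default detection signal. Gait
#' patterns that produce multiple peaks per step in the forward channel are
#' detected more reliably on the vertical channel; the choice is made by
#' comparing direction-reversal counts (positive or negative peaks) in the
#' calibration window: vertical is selected when the forward/vertical
#' reversal-count ratio exceeds `ratio_threshold`.
#'
#' @param forward_f4,vertical_f4 Filtered calibration-window signals.
#' @param ratio_threshold Ratio above which vertical is selected
#'   (default 1.4).
#' @return `"forward"` or `"vertical"`.
#' @export
select_axis <- function(forward_f4, vertical_f4, ratio_threshold = 1.4) {
  nf <- direction_reversals(forward_f4)
  nv <- direction_reversals(vertical_f4)
  if (nv == 0L) {
    warning("no direction reversals in vertical channel; using forward",
            call. = FALSE)
    return("forward")
  }
  if (nf / nv > ratio_threshold) "vertical" else "forward"
}

#' Self-calibrate locking period, detection axis and boundary thresholds
#'
#' Uses the first `calib_seconds` of the first usable walkway segment (after
#' any leading turn) — no separate training data are required. If the window
#' contains fewer than 2 positive zero crossings of the filtered vertical
#' signal, it is widened in 1 s increments up to `max_seconds`.
#'
#' The boundary threshold is the maximum minus the mean of the filtered
#' forward acceleration in the window; it grades the attenuated first/last
#' steps of each walkway, which have lower peaks because the person is
#' starting from, or slowing for, a turn. The analogous vertical-channel
#' threshold is kept for the missed-step recovery cross-check.
#'
#' @param fs A `filtered_signals` object from [filter_trial()].
#' @param segments A `walk_segments` tiling from [segment_trial()].
#' @param calib_seconds Initial calibration window length (default 5 s).
#' @param max_seconds Maximum widened window length (default 10 s).
#' @param ratio_threshold Axis-selection ratio, see [select_axis()].
#' @return A `calib_profile` list: `locking_period` (s), `primary_axis`,
#'   `boundary_threshold` (m/s^2, forward), `boundary_threshold_vertical`,
#'   `calib_window` (start, end in s), `rate`.
#' @export
calibrate_trial <- function(fs, segments, calib_seconds = 5,
                            max_seconds = 10, ratio_threshold = 1.4) {
  w <- segments[segments$kind == "walkway" & !segments$degenerate, ,
                drop = FALSE]
  if (nrow(w) == 0L) stop("no usable walkway segment to calibrate on",
                          call. = FALSE)
  w0 <- w[1L, ]
  rate <- fs$rate
  win_len <- calib_seconds
  repeat {
    t_end <- min(w0$start + win_len, w0$end)
    idx <- which(fs$t >= w0$start & fs$t <= t_end)
    zc <- positive_zero_crossings(fs$vertical_f4[idx], fs$t[idx])
    if (length(zc) >= 2L || win_len >= max_seconds) break
    win_len <- win_len + 1
  }
  if (length(zc) < 2L) {
    stop("calibration failed: fewer than 2 vertical zero crossings in the ",
         "first ", max_seconds, " s of walking", call. = FALSE)
  }
  lock <- locking_period_rule(diff(zc))
  lock <- min(max(lock, 2 / rate), 1.5)
  axis <- select_axis(fs$forward_f4[idx], fs$vertical_f4[idx],
                      ratio_threshold)
  structure(
    list(
      locking_period = lock,
      primary_axis = axis,
      boundary_threshold = max(fs$forward_f4[idx]) - mean(fs$forward_f4[idx]),
      boundary_threshold_vertical =
        max(fs$vertical_f4[idx]) - mean(fs$vertical_f4[idx]),
      calib_window = c(w0$start, t_end),
      rate = rate
    ),
    class = "calib_profile"
  )
}

#' @export
print.calib_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<calib_profile> locking period %.3f s, axis %s, ",
           "boundary threshold %.3f m/s^2 (window %.1f-%.1f s)\n"),
    x$locking_period, x$primary_axis, x$boundary_threshold,
    x$calib_window[1L], x$calib_window[2L]
  ))
  invisible(x)
}

# hill-climb from a candidate index to the nearest local maximum in [lo, hi]
climb_to_max <- function(x, i, lo, hi) {
  while (i < hi && x[i + 1L] > x[i]) i <- i + 1L
  while (i > lo && x[i - 1L] > x[i]) i <- i - 1L
  i
}

# shape descriptors of a candidate peak: peak minus the minimum on each side
# of the locking period centred on the peak (clamped to [lo, hi])
peak_diffs <- function(x, peak, hw, lo = 1L, hi = length(x)) {
  a <- max(lo, peak - hw)
  b <- min(hi, peak + hw)
  c(left = x[peak] - min(x[a:peak]),
    right = x[peak] - min(x[peak:b]))
}

empty_steps <- function() {
  ev <- data.frame(
    peak_idx = integer(0), peak_time = numeric(0), peak_value = numeric(0),
    left_diff = numeric(0), right_diff = numeric(0),
    foot_strike_time = numeric(0), side = character(0),
    side_margin = numeric(0), walkway_index = integer(0),
    recovered = logical(0)
  )
  class(ev) <- c("step_events", "data.frame")
  ev
}

#' Detect steps with a locking-period window and shape similarity
#'
#' Within each walkway segment a window the width of the locking period
#' advances through the chosen filtered acceleration signal; the window
#' maximum is a candidate peak. Instead of a fixed amplitude threshold, a
#' candidate is accepted as a step when its shape is similar to the previous
#' step: the differences between the peak and the minima on either side
#' (within the locking window) must each exceed `shape_ratio` times the
#' previous step's differences. Every candidate must additionally clear a
#' self-calibrated amplitude floor: its peak prominence (the smaller of the
#' two side differences) must exceed `boundary_fraction` times the boundary
#' threshold of the detection channel (default 0.65, between the noise
#' prominence tail and the attenuated boundary-step prominence). The floor accepts the
#' attenuated first step of each walkway (which has no previous step for the
#' similarity test) and what rejects low-amplitude fluctuations around turn
#' onsets and during pauses. After an acceptance the window jumps one
#' locking period past the peak; candidates inside turn segments are never
#' produced.
#'
#' @param signal_f4 The filtered detection signal (forward or vertical, per
#'   the calibration profile).
#' @param t Uniform time grid in seconds.
#' @param profile A `calib_profile` from [calibrate_trial()].
#' @param segments A `walk_segments` tiling.
#' @param shape_ratio Similarity acceptance ratio (default 0.35).
#' @param boundary_fraction Fraction of the detection channel's boundary
#'   threshold that a candidate's peak prominence must exceed (default 0.5);
#'   sized so attenuated walkway-boundary steps pass while noise-level
#'   candidates fail.
#' @return A `step_events` data frame (one row per detected step) with peak
#'   index/time/value, left/right shape differences and walkway index.
#'   `foot_strike_time` and `side` are filled by later stages.
#' @export
detect_steps <- function(signal_f4, t, profile, segments,
                         shape_ratio = 0.35, boundary_fraction = 0.65) {
  rate <- profile$rate
  L <- max(2L, round(profile$locking_period * rate))
  hw <- L  # side minima searched one locking period out (valleys between steps)
  bt <- if (profile$primary_axis == "vertical") {
    profile$boundary_threshold_vertical
  } else {
    profile$boundary_threshold
  }
  out <- list()
  walks <- segments[segments$kind == "walkway" & !segments$degenerate, ,
                    drop = FALSE]
  for (wi in seq_len(nrow(walks))) {
    seg <- walks[wi, ]
    i0 <- which(t >= seg$start)[1L]
    i1 <- max(which(t <= seg$end))
    if (is.na(i0) || i1 - i0 < L) next
    prev <- NULL
    ws <- i0
    while (ws + L <= i1) {
      win <- ws:(ws + L)
      peak <- win[which.max(signal_f4[win])]
      if (peak == ws || peak == ws + L) {
        # maximum on the window edge: peak not yet enclosed, slide on
        ws <- ws + 1L
        next
      }
      # the window locates the step; the candidate is the local maximum
      # (the crest apex may sit just past the window edge)
      peak <- climb_to_max(signal_f4, peak, i0, i1)
      # side minima are a property of the waveform, not of the segment
      # tiling, so they may be sought beyond the walkway boundary
      d <- peak_diffs(signal_f4, peak, hw)
      # self-calibrated amplitude floor: catches attenuated boundary steps
      # (first/last of a walkway) while rejecting low-prominence candidates
      # such as turn-onset fluctuations after the final step
      floor_ok <- min(d) > boundary_fraction * bt
      accept <- if (is.null(prev)) {
        floor_ok
      } else {
        floor_ok &&
          d[["left"]] / prev[["left"]] > shape_ratio &&
          d[["right"]] / prev[["right"]] > shape_ratio
      }
      if (accept) {
        out[[length(out) + 1L]] <- data.frame(
          peak_idx = peak, peak_time = t[peak], peak_value = signal_f4[peak],
          left_diff = d[["left"]], right_diff = d[["right"]],
          walkway_index = seg$index
        )
        prev <- d
        ws <- peak + L
      } else {
        ws <- peak + 1L
      }
    }
  }
  if (length(out) == 0L) return(empty_steps())
  ev <- do.call(rbind, out)
  ev$foot_strike_time <- NA_real_
  ev$side <- NA_character_
  ev$side_margin <- NA_real_
  ev$recovered <- FALSE
  ev <- ev[order(ev$peak_time), c(
    "peak_idx", "peak_time", "peak_value", "left_diff", "right_diff",
    "foot_strike_time", "side", "side_margin", "walkway_index", "recovered"
  )]
  rownames(ev) <- NULL
  class(ev) <- c("step_events", "data.frame")
  ev
}

#' Recover missed steps and declare stops
#'
#' Whenever the duration between two consecutive detected steps exceeds
#' `gap_factor` times the previous step duration, the gap is re-analysed.
#' Each unclaimed local maximum in the gap becomes a recovered step if
#' (a) both shape differences exceed `recover_ratio` times the previous
#' step's, (b) its timing continues the prior inter-step interval within
#' `timing_tolerance` of that interval, and (c) the acceleration channel not
#' used for detection rises above its own boundary threshold near the
#' candidate. If the gap (after any recoveries) still exceeds `gap_factor`
#' times the previous step duration, the pause is recorded as a stop.
#'
#' @param events A `step_events` data frame from [detect_steps()].
#' @param signal_f4 The detection signal used by [detect_steps()].
#' @param other_f4 The filtered channel *not* used for detection.
#' @param t Uniform time grid in seconds.
#' @param profile A `calib_profile`.
#' @param gap_factor Gap trigger as a multiple of the previous step duration
#'   (default 1.75).
#' @param recover_ratio Shape-similarity ratio for recovered steps
#'   (default 0.30).
#' @param timing_tolerance Allowed deviation of a recovered step from the
#'   extrapolated timing pattern, as a fraction of the previous inter-step
#'   interval (default 0.25).
#' @return A list: `events` (with recovered steps inserted and flagged) and
#'   `stops` (two-column matrix of stop intervals in seconds).
#' @export
recover_missed_steps <- function(events, signal_f4, other_f4, t, profile,
                                 gap_factor = 1.75, recover_ratio = 0.30,
                                 timing_tolerance = 0.25) {
  L <- max(2L, round(profile$locking_period * profile$rate))
  hw <- L  # side minima searched one locking period out (valleys between steps)
  other_thresh <- if (profile$primary_axis == "forward") {
    profile$boundary_threshold_vertical
  } else {
    profile$boundary_threshold
  }
  stops <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  new_rows <- list()
  for (w in unique(events$walkway_index)) {
    ev <- events[events$walkway_index == w, ]
    if (nrow(ev) < 3L) next
    other_mean <- mean(other_f4[min(ev$peak_idx):max(ev$peak_idx)])
    for (i in 2L:(nrow(ev) - 1L)) {
      prev_dur <- ev$peak_time[i] - ev$peak_time[i - 1L]
      gap <- ev$peak_time[i + 1L] - ev$peak_time[i]
      if (gap <= gap_factor * prev_dur || prev_dur <= 0) next
      lo <- ev$peak_idx[i] + L
      hi <- ev$peak_idx[i + 1L] - L
      recovered_times <- numeric(0)
      if (hi - lo >= 2L) {
        sub <- signal_f4[lo:hi]
        cand <- which(diff(sign(diff(sub))) < 0) + 1L + lo - 1L
        expected <- ev$peak_time[i] + prev_dur
        prev_d <- c(left = ev$left_diff[i], right = ev$right_diff[i])
        for (ci in cand) {
          d <- peak_diffs(signal_f4, ci, hw)
          near <- max(1L, ci - L):min(length(other_f4), ci + L)
          ok <- d[["left"]] / prev_d[["left"]] > recover_ratio &&
            d[["right"]] / prev_d[["right"]] > recover_ratio &&
            abs(t[ci] - expected) <= timing_tolerance * prev_dur &&
            (max(other_f4[near]) - other_mean) > other_thresh
          if (ok) {
            new_rows[[length(new_rows) + 1L]] <- data.frame(
              peak_idx = ci, peak_time = t[ci], peak_value = signal_f4[ci],
              left_diff = d[["left"]], right_diff = d[["right"]],
              foot_strike_time = NA_real_, side = NA_character_,
              side_margin = NA_real_, walkway_index = w, recovered = TRUE
            )
            recovered_times <- c(recovered_times, t[ci])
            expected <- t[ci] + prev_dur
            prev_d <- d
          }
        }
      }
      # any remaining unexplained gap is a stop
      marks <- sort(c(ev$peak_time[i], recovered_times, ev$peak_time[i + 1L]))
      gaps <- diff(marks)
      bad <- which(gaps > gap_factor * prev_dur)
      for (b in bad) {
        stops <- rbind(stops, c(marks[b], marks[b + 1L]))
      }
    }
  }
  if (length(new_rows)) {
    events <- rbind(events, do.call(rbind, new_rows))
    events <- events[order(events$peak_time), ]
    rownames(events) <- NULL
    class(events) <- c("step_events", "data.frame")
  }
  colnames(stops) <- c("start", "end")
  list(events = events, stops = stops)
}

#' Time foot strikes from the raw forward acceleration
#'
#' The phone is worn facing backward, so foot strike registers as the maximum
#' *negative* peak of the raw (unfiltered but regularized) forward linear
#' acceleration. Each detected step's foot-strike time is the time of the
#' minimum raw forward acceleration within `neighborhood` seconds of the
#' filtered-signal peak (default: half the locking period each side). Ties
#' resolve to the earlier sample; events are re-sorted by foot-strike time.
#'
#' @param events A `step_events` data frame.
#' @param raw_forward Raw regularized forward acceleration.
#' @param t Uniform time grid in seconds.
#' @param profile A `calib_profile`.
#' @param neighborhood Search half-width in seconds (default
#'   `locking_period / 2`).
#' @return The events with `foot_strike_time` filled, sorted by it.
#' @export
time_foot_strikes <- function(events, raw_forward, t, profile,
                              neighborhood = NULL) {
  if (nrow(events) == 0L) return(events)
  if (is.null(neighborhood)) neighborhood <- profile$locking_period / 2
  h <- max(1L, round(neighborhood * profile$rate))
  n <- length(raw_forward)
  for (i in seq_len(nrow(events))) {
    a <- max(1L, events$peak_idx[i] - h)
    b <- min(n, events$peak_idx[i] + h)
    fs <- a + which.min(raw_forward[a:b]) - 1L
    events$foot_strike_time[i] <- t[fs]
  }
  events <- events[order(events$foot_strike_time), ]
  rownames(events) <- NULL
  class(events) <- c("step_events", "data.frame")
  events
}
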