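#' Label steps left or right with the tangent method
#'
#' During a left step the trunk accelerates toward the right (and vice
#' versa), which the 1 Hz low-passed mediolateral acceleration captures as a
#' slow side-to-side oscillation at stride frequency. At each step, the
#' tangent line to that signal is taken at 0.25 of the step duration after
#' foot strike (slope from the central difference of the adjacent samples).
#' If the tangent's y-value exceeds the signal value at both one locking
#' period before and one locking period after the anchor (the signal curves
#' away below the tangent, i.e. the person is accelerating to the right) the
#' step is labelled right; values equal to or below the signal at either
#' point label the step left.
#'
#' Step duration is the time to the next foot strike within the same
#' walkway; the last step of a walkway reuses the previous duration.
#' A `side_margin` (the summed distance between tangent and signal at the two
#' comparison points) is stored to arbitrate alternation repair.
#'
#' @param events A `step_events` data frame with foot-strike times.
#' @param ml_f1 Mediolateral acceleration low-passed at 1 Hz.
#' @param t Uniform time grid in seconds.
#' @param profile A `calib_profile`.
#' @return The events with `side` and `side_margin` filled.
#' @export
classify_sides <- function(events, ml_f1, t, profile) {
  if (nrow(events) == 0L) return(events)
  n <- length(ml_f1)
  rate <- profile$rate
  k <- max(1L, round(profile$locking_period * rate))
  durs <- step_durations(events)
  for (i in seq_len(nrow(events))) {
    a_time <- events$foot_strike_time[i] + 0.25 * durs[i]
    a <- min(max(2L, round((a_time - t[1L]) * rate) + 1L), n - 1L)
    slope <- (ml_f1[a + 1L] - ml_f1[a - 1L]) / 2   # per sample
    b <- ml_f1[a]
    i_lo <- max(1L, a - k)
    i_hi <- min(n, a + k)
    y_lo <- b + slope * (i_lo - a)
    y_hi <- b + slope * (i_hi - a)
    right <- (y_lo > ml_f1[i_lo]) && (y_hi > ml_f1[i_hi])
    events$side[i] <- if (right) "right" else "left"
    events$side_margin[i] <-
      abs(y_lo - ml_f1[i_lo]) + abs(y_hi - ml_f1[i_hi])
  }
  events
}

# per-event step duration: time to the next foot strike within the same
# walkway; the last event of a walkway reuses the previous duration
step_durations <- function(events, fallback = 0.5) {
  n <- nrow(events)
  durs <- rep(NA_real_, n)
  for (w in unique(events$walkway_index)) {
    idx <- which(events$walkway_index == w)
    if (length(idx) >= 2L) {
      d <- diff(events$foot_strike_time[idx])
      durs[idx] <- c(d, d[length(d)])
    }
  }
  if (anyNA(durs)) {
    med <- stats::median(durs, na.rm = TRUE)
    durs[is.na(durs)] <- if (is.finite(med)) med else fallback
  }
  durs
}

#' Enforce left/right alternation within walkways
#'
#' Able-bodied steps strictly alternate sides within a straight walkway, so
#' the alternating sequence is used to fill steps the tangent method could
#' not label and to correct double counts (isolated same-side pairs). Of the
#' two possible alternating assignments for a run of steps, the one that
#' disagrees with the smallest total tangent margin is chosen — labels with a
#' small margin are flipped in preference to confident ones. Runs reset at
#' each walkway boundary and across stops.
#'
#' @param events A `step_events` data frame with `side` and `side_margin`.
#' @param stops Optional two-column matrix of stop intervals; alternation is
#'   not enforced across a stop.
#' @return The events with strictly alternating sides within each run.
#' @export
repair_sequence <- function(events, stops = NULL) {
  if (nrow(events) == 0L) return(events)
  run_id <- alternation_runs(events, stops)
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    sides <- events$side[idx]
    margins <- events$side_margin[idx]
    margins[is.na(margins) | is.na(sides)] <- 0
    events$side[idx] <- best_alternation(sides, margins)
  }
  events
}

# group events into runs within which alternation is enforced:
# per walkway, split where a stop interval separates consecutive strikes
alternation_runs <- function(events, stops = NULL) {
  n <- nrow(events)
  run_id <- integer(n)
  cur <- 0L
  for (w in unique(events$walkway_index)) {
    idx <- which(events$walkway_index == w)
    cur <- cur + 1L
    run_id[idx[1L]] <- cur
    if (length(idx) > 1L) {
      for (j in 2L:length(idx)) {
        t0 <- events$foot_strike_time[idx[j - 1L]]
        t1 <- events$foot_strike_time[idx[j]]
        straddles <- !is.null(stops) && nrow(stops) > 0L &&
          any(stops[, 1L] >= t0 & stops[, 2L] <= t1)
        if (straddles) cur <- cur + 1L
        run_id[idx[j]] <- cur
      }
    }
  }
  run_id
}

# pick the alternating side assignment minimising the summed margin of
# flipped labels (unknown labels carry zero margin)
best_alternation <- function(sides, margins) {
  n <- length(sides)
  start_l <- rep(c("left", "right"), length.out = n)
  start_r <- rep(c("right", "left"), length.out = n)
  cost <- function(assign) {
    sum(margins[!is.na(sides) & sides != assign])
  }
  if (cost(start_l) <= cost(start_r)) start_l else start_r
}
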