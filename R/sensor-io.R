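#' Construct a sensor trial
#'
#' A `sensor_trial` holds one walk test recording: per-sample timestamps,
#' tri-axial linear acceleration (gravity removed) and device azimuth, plus
#' the known walkway length the test was performed on.
#'
#' Axis convention: `acc_forward` is the direction of progression. The device
#' is worn facing backward at the mid lower back, so foot strikes register as
#' sharp NEGATIVE peaks in the raw forward channel; no sign flipping is done
#' at construction time — downstream code handles polarity explicitly.
#'
#' @param t Numeric vector of timestamps in seconds, monotone non-decreasing.
#' @param acc_forward,acc_vertical,acc_ml Numeric vectors, linear acceleration
#'   in m/s^2 along the forward (anteroposterior), vertical and mediolateral
#'   axes.
#' @param azimuth Numeric vector, device heading in degrees within `[0, 360)`.
#' @param walkway_length Walkway length in metres, `> 0`.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `sensor_trial`.
#' @export
sensor_trial <- function(t, acc_forward, acc_vertical, acc_ml, azimuth,
                         walkway_length, meta = list()) {
  n <- length(t)
  lens <- c(length(acc_forward), length(acc_vertical), length(acc_ml),
            length(azimuth))
  if (any(lens != n)) {
    stop("all channels must have the same length as `t`", call. = FALSE)
  }
  if (n < 2L) stop("a sensor trial needs at least 2 samples", call. = FALSE)
  if (any(diff(t) < 0)) {
    stop("`t` must be monotone non-decreasing", call. = FALSE)
  }
  if (!is.numeric(walkway_length) || length(walkway_length) != 1L ||
      !is.finite(walkway_length) || walkway_length <= 0) {
    stop("`walkway_length` must be a single positive number", call. = FALSE)
  }
  if (any(azimuth < 0 | azimuth >= 360)) {
    stop("`azimuth` values must lie in [0, 360)", call. = FALSE)
  }
  structure(
    list(
      t = as.numeric(t),
      acc_forward = as.numeric(acc_forward),
      acc_vertical = as.numeric(acc_vertical),
      acc_ml = as.numeric(acc_ml),
      azimuth = as.numeric(azimuth),
      walkway_length = as.numeric(walkway_length),
      meta = meta
    ),
    class = "sensor_trial"
  )
}

#' @export
print.sensor_trial <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1L]
  rate <- (length(x$t) - 1L) / max(dur, .Machine$double.eps)
  cat(sprintf(
    "<sensor_trial> %d samples, %.1f s, ~%.1f Hz, walkway %.2f m\n",
    length(x$t), dur, rate, x$walkway_length
  ))
  invisible(x)
}

#' Number of samples in a trial
#' @param trial A `sensor_trial`.
#' @return Integer sample count.
#' @export
n_samples <- function(trial) length(trial$t)

trial_channels <- c("time", "acc_forward", "acc_vertical", "acc_ml", "azimuth")

#' Read a sensor trial from a delimited text file
#'
#' Expects a comma-delimited file with a header naming the five channels
#' `time, acc_forward, acc_vertical, acc_ml, azimuth` (any column order,
#' extra columns ignored). Rows containing non-finite values are dropped with
#' a warning; duplicate timestamps are collapsed keeping the first row.
#'
#' @param path Path to the file.
#' @param walkway_length Walkway length in metres.
#' @param meta Optional metadata list attached to the trial.
#' @return A [sensor_trial()].
#' @export
read_trial <- function(path, walkway_length, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(trial_channels, names(df))
  if (length(missing)) {
    stop("trial file is missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[trial_channels]
  ok <- rowSums(!is.finite(as.matrix(df))) == 0L
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite values dropped", call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  dup <- duplicated(df$time)
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  if (nrow(df) < 2L) stop("fewer than 2 usable rows in ", path, call. = FALSE)
  sensor_trial(df$time, df$acc_forward, df$acc_vertical, df$acc_ml,
               df$azimuth, walkway_length, meta = meta)
}

#' Write a sensor trial to a delimited text file
#'
#' @param trial A [sensor_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  df <- data.frame(
    time = trial$t,
    acc_forward = trial$acc_forward,
    acc_vertical = trial$acc_vertical,
    acc_ml = trial$acc_ml,
    azimuth = trial$azimuth
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a trial onto a uniform time grid
#'
#' Smartphone sensors sample at a jittery rate (nominally ~50 Hz with a
#' standard deviation of several Hz). All downstream window arithmetic
#' (locking periods, sliding turn windows) assumes a constant sample spacing,
#' so trials are linearly interpolated onto a uniform grid spanning
#' `[t[1], t[n]]` before analysis. The azimuth channel is unwrapped (see
#' [correct_azimuth()]) before interpolation so values are never interpolated
#' across the 0/360 degree seam, then re-wrapped into `[0, 360)` for storage.
#'
#' @param trial A [sensor_trial()].
#' @param target_rate Target sampling rate in Hz, within `[20, 200]`.
#' @return A [sensor_trial()] on a uniform grid. The output has
#'   `floor((t_end - t0) * rate) + 1` samples.
#' @export
regularize <- function(trial, target_rate = 50) {
  stopifnot(inherits(trial, "sensor_trial"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate < 20 || target_rate > 200) {
    stop("`target_rate` must be a single value in [20, 200] Hz", call. = FALSE)
  }
  t <- trial$t
  keep <- c(TRUE, diff(t) > 0)
  t <- t[keep]
  t0 <- t[1L]
  t_end <- t[length(t)]
  grid <- t0 + seq.int(0L, floor((t_end - t0) * target_rate)) / target_rate
  interp <- function(y) stats::approx(t, y[keep], xout = grid, rule = 2)$y
  az_cont <- interp(correct_azimuth(trial$azimuth[keep]))
  sensor_trial(
    t = grid,
    acc_forward = interp(trial$acc_forward),
    acc_vertical = interp(trial$acc_vertical),
    acc_ml = interp(trial$acc_ml),
    azimuth = wrap360(az_cont),
    walkway_length = trial$walkway_length,
    meta = c(trial$meta, list(regularized_rate = target_rate))
  )
}

#' Read a ground-truth annotation file
#'
#' Annotation schema: a comma-delimited file with header
#' `event_type,start,end,label`. `foot_strike` rows use `start` as the strike
#' time and `label` as the side (`left`/`right`); `turn` and `stop` rows give
#' intervals; a single `distance` row gives the true distance in metres in
#' `start`.
#'
#' @param path Path to the annotation file.
#' @return A `ground_truth` object: list with `foot_strikes`, `sides`,
#'   `turn_intervals`, `stop_intervals` (two-column matrices), `true_distance`.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(event_type = "character",
                                       label = "character"))
  need <- c("event_type", "start", "end", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("annotation file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fs <- df[df$event_type == "foot_strike", , drop = FALSE]
  turns <- df[df$event_type == "turn", , drop = FALSE]
  stops <- df[df$event_type == "stop", , drop = FALSE]
  dist <- df[df$event_type == "distance", , drop = FALSE]
  ground_truth(
    foot_strikes = fs$start,
    sides = fs$label,
    turn_intervals = cbind(turns$start, turns$end),
    stop_intervals = cbind(stops$start, stops$end),
    true_distance = if (nrow(dist)) dist$start[1L] else NA_real_
  )
}

#' Construct a ground-truth annotation object
#'
#' @param foot_strikes Strictly increasing foot-strike times in seconds.
#' @param sides Character vector over `left`/`right`, aligned to
#'   `foot_strikes`.
#' @param turn_intervals,stop_intervals Two-column matrices of
#'   `(start, end)` intervals in seconds (possibly zero rows).
#' @param true_distance True distance walked in metres.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(foot_strikes, sides, turn_intervals = NULL,
                         stop_intervals = NULL, true_distance = NA_real_) {
  as_intervals <- function(x) {
    if (is.null(x) || length(x) == 0L) {
      return(matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "end"))))
    }
    m <- matrix(as.numeric(x), ncol = 2L)
    colnames(m) <- c("start", "end")
    m
  }
  foot_strikes <- as.numeric(foot_strikes)
  if (length(foot_strikes) > 1L && any(diff(foot_strikes) <= 0)) {
    stop("`foot_strikes` must be strictly increasing", call. = FALSE)
  }
  if (length(sides) != length(foot_strikes)) {
    stop("`sides` must align with `foot_strikes`", call. = FALSE)
  }
  ti <- as_intervals(turn_intervals)
  si <- as_intervals(stop_intervals)
  for (m in list(ti, si)) {
    if (nrow(m) && any(m[, 2L] <= m[, 1L])) {
      stop("interval ends must exceed starts", call. = FALSE)
    }
  }
  structure(
    list(foot_strikes = foot_strikes, sides = as.character(sides),
         turn_intervals = ti, stop_intervals = si,
         true_distance = as.numeric(true_distance)),
    class = "ground_truth"
  )
}

#' Write a ground-truth annotation file
#'
#' @param truth A [ground_truth()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- list(
    data.frame(event_type = "foot_strike", start = truth$foot_strikes,
               end = truth$foot_strikes, label = truth$sides),
    if (nrow(truth$turn_intervals)) {
      data.frame(event_type = "turn", start = truth$turn_intervals[, 1L],
                 end = truth$turn_intervals[, 2L], label = "")
    },
    if (nrow(truth$stop_intervals)) {
      data.frame(event_type = "stop", start = truth$stop_intervals[, 1L],
                 end = truth$stop_intervals[, 2L], label = "")
    },
    if (is.finite(truth$true_distance)) {
      data.frame(event_type = "distance", start = truth$true_distance,
                 end = truth$true_distance, label = "")
    }
  )
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write trial outcomes to a delimited file
#'
#' The outcome file has two blocks: one row per scalar outcome
#' (`outcome,value`), then a per-walkway block with columns
#' `walkway,steps,duration_s,cadence,mean_step_length`. Values round-trip
#' through [read_outcomes()] at 6 decimal places.
#'
#' @param outcomes A `trial_outcomes` object (see [compute_gait_outcomes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  sc <- outcomes$scalars
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("outcome,value", con)
  writeLines(sprintf("%s,%.6f", names(sc), sc), con)
  writeLines("", con)
  writeLines("walkway,steps,duration_s,cadence,mean_step_length", con)
  pw <- outcomes$per_walkway
  if (!is.null(pw) && nrow(pw)) {
    writeLines(sprintf("%d,%d,%.6f,%.6f,%.6f", pw$walkway, pw$steps,
                       pw$duration_s, pw$cadence, pw$mean_step_length), con)
  }
  invisible(path)
}

#' Read an outcome file written by [write_outcomes()]
#'
#' @param path Path to the outcome file.
#' @return A list with `scalars` (named numeric vector) and `per_walkway`
#'   (data frame).
#' @export
read_outcomes <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1L]
  sc_df <- utils::read.csv(text = lines[seq_len(blank - 1L)])
  scalars <- stats::setNames(as.numeric(sc_df$value), sc_df$outcome)
  pw <- utils::read.csv(text = lines[(blank + 1L):length(lines)])
  structure(list(scalars = scalars, per_walkway = pw),
            class = "trial_outcomes")
}
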