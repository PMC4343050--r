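#' Total distance walked from walkway decomposition
#'
#' The walk test is performed on a track of known length, so every completed
#' walkway contributes exactly `walkway_length` metres and only the final
#' partial walkway must be estimated: its step count times the mean step
#' length of a reference walkway. The reference is the last completed
#' walkway, unless it contains a stop, in which case the most recent earlier
#' stop-free walkway is used. If the mean step duration in the last walkway
#' is less than `slowdown_ratio` (default 0.9) of the reference's — the
#' person slowed by more than ~10% per step — the step length is first
#' multiplied by that duration ratio. Step-length error therefore never
#' compounds across completed walkways.
#'
#' @param segments A `walk_segments` tiling from [segment_trial()].
#' @param events A `step_events` data frame with foot-strike times.
#' @param walkway_length Walkway length in metres.
#' @param stops Two-column matrix of stop intervals (seconds), possibly
#'   zero rows.
#' @param slowdown_ratio Duration-ratio threshold below which the last
#'   walkway's step length is scaled (default 0.9).
#' @return A list: `total_distance`, `n_full_walkways`,
#'   `last_walkway_distance`, `reference_walkway` (index),
#'   `reference_step_length`, `duration_ratio`.
#' @export
compute_distance <- function(segments, events, walkway_length, stops = NULL,
                             slowdown_ratio = 0.9) {
  ws <- segments[segments$kind == "walkway", , drop = FALSE]
  counts <- step_counts(ws$index, events)
  last_i <- nrow(ws)
  full <- ws[-last_i, , drop = FALSE]
  full <- full[!full$degenerate, , drop = FALSE]
  n_full <- nrow(full)
  last_steps <- counts[[as.character(ws$index[last_i])]]
  if (n_full == 0L) {
    warning("no completed walkway before the final partial one; distance is ",
            "a coarse estimate", call. = FALSE)
    est <- last_steps * walkway_length / max(sum(unlist(counts)), 1L)
    return(list(total_distance = est, n_full_walkways = 0L,
                last_walkway_distance = est, reference_walkway = NA_integer_,
                reference_step_length = NA_real_, duration_ratio = NA_real_))
  }
  has_stop <- function(seg) {
    !is.null(stops) && nrow(stops) > 0L &&
      any(stops[, 1L] < seg$end & stops[, 2L] > seg$start)
  }
  ref <- NULL
  for (i in rev(seq_len(n_full))) {
    if (!has_stop(full[i, ]) && counts[[as.character(full$index[i])]] > 0L) {
      ref <- full[i, ]
      break
    }
  }
  if (is.null(ref)) ref <- full[n_full, ]  # every full walkway has a stop
  ref_count <- counts[[as.character(ref$index)]]
  ref_len <- walkway_length / max(ref_count, 1L)
  ratio <- duration_ratio(events, ws$index[last_i], ref$index, stops)
  step_len <- if (is.finite(ratio) && ratio < slowdown_ratio) {
    ref_len * ratio
  } else {
    ref_len
  }
  last_dist <- last_steps * step_len
  list(
    total_distance = n_full * walkway_length + last_dist,
    n_full_walkways = n_full,
    last_walkway_distance = last_dist,
    reference_walkway = ref$index,
    reference_step_length = ref_len,
    duration_ratio = ratio
  )
}

# named list: steps detected in each walkway index
step_counts <- function(indices, events) {
  out <- as.list(stats::setNames(integer(length(indices)),
                                 as.character(indices)))
  if (nrow(events)) {
    tab <- table(events$walkway_index)
    for (nm in names(tab)) if (nm %in% names(out)) out[[nm]] <- tab[[nm]]
  }
  out
}

# mean step durations (foot strike to foot strike) within a walkway,
# excluding the first step out of the turn and intervals spanning a stop
walkway_step_durations <- function(events, windex, stops = NULL) {
  ev <- events[events$walkway_index == windex, ]
  if (nrow(ev) < 3L) return(numeric(0))
  fstr <- ev$foot_strike_time
  d <- diff(fstr)
  keep <- rep(TRUE, length(d))
  keep[1L] <- FALSE  # first step out of a turn is atypical
  if (!is.null(stops) && nrow(stops) > 0L) {
    for (j in seq_along(d)) {
      if (any(stops[, 1L] >= fstr[j] & stops[, 2L] <= fstr[j + 1L])) {
        keep[j] <- FALSE
      }
    }
  }
  d[keep]
}

duration_ratio <- function(events, last_index, ref_index, stops) {
  d_last <- walkway_step_durations(events, last_index, stops)
  d_ref <- walkway_step_durations(events, ref_index, stops)
  if (!length(d_last) || !length(d_ref)) return(NA_real_)
  mean(d_last) / mean(d_ref)
}

pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Clinical gait outcomes for a trial
#'
#' Computes the outcome set reported after a walk test: total distance,
#' step counts, cadence (mean/SD across walkways and overall), left/right
#' step time, stride time, and a step-time symmetry index (mean left step
#' time / mean right step time; `symmetry_form = "asymmetry"` instead gives
#' `|L - R| / (0.5 (L + R))`). Step and stride times never span turns or
#' stops; turn steps are not counted; stop time is excluded from cadence;
#' degenerate walkway slivers are excluded from per-walkway statistics.
#' Sides with fewer than 2 steps report `NA`, not zero. SDs are population
#' SDs.
#'
#' @param events A `step_events` data frame, timed and sided.
#' @param segments A `walk_segments` tiling.
#' @param walkway_length Walkway length in metres.
#' @param stops Two-column matrix of stop intervals (seconds).
#' @param slowdown_ratio Passed to [compute_distance()].
#' @param symmetry_form `"ratio"` (default) or `"asymmetry"`.
#' @return A `trial_outcomes` object: `scalars` (named numeric vector),
#'   `per_walkway` (data frame: walkway, steps, duration_s, cadence,
#'   mean_step_length), `distance` (the [compute_distance()] breakdown),
#'   `stops`.
#' @export
compute_gait_outcomes <- function(events, segments, walkway_length,
                                  stops = NULL, slowdown_ratio = 0.9,
                                  symmetry_form = c("ratio", "asymmetry")) {
  symmetry_form <- match.arg(symmetry_form)
  dist <- compute_distance(segments, events, walkway_length, stops,
                           slowdown_ratio)
  ws <- segments[segments$kind == "walkway" & !segments$degenerate, ,
                 drop = FALSE]
  counts <- step_counts(ws$index, events)
  # per-walkway block
  pw <- data.frame(walkway = integer(0), steps = integer(0),
                   duration_s = numeric(0), cadence = numeric(0),
                   mean_step_length = numeric(0))
  for (i in seq_len(nrow(ws))) {
    seg <- ws[i, ]
    nst <- counts[[as.character(seg$index)]]
    stop_time <- overlap_time(stops, seg$start, seg$end)
    dur <- (seg$end - seg$start) - stop_time
    is_last <- i == nrow(ws) && seg$index ==
      max(segments$index[segments$kind == "walkway"], na.rm = TRUE)
    msl <- if (is_last) {
      if (nst > 0L) dist$last_walkway_distance / nst else NA_real_
    } else if (nst > 0L) walkway_length / nst else NA_real_
    pw <- rbind(pw, data.frame(
      walkway = seg$index, steps = as.integer(nst), duration_s = dur,
      cadence = if (dur > 0) nst / dur * 60 else NA_real_,
      mean_step_length = msl
    ))
  }
  # step/stride times within walkways, never across stops
  runs <- alternation_runs(events, stops)
  step_int <- list(left = numeric(0), right = numeric(0), all = numeric(0))
  stride <- numeric(0)
  for (r in unique(runs)) {
    ev <- events[runs == r, ]
    if (nrow(ev) < 2L) next
    d <- diff(ev$foot_strike_time)
    step_int$all <- c(step_int$all, d)
    ending <- ev$side[-1L]  # interval belongs to the foot that lands
    step_int$left <- c(step_int$left, d[ending == "left"])
    step_int$right <- c(step_int$right, d[ending == "right"])
    for (sd_ in c("left", "right")) {
      si <- which(ev$side == sd_)
      if (length(si) >= 2L) stride <- c(stride, diff(ev$foot_strike_time[si]))
    }
  }
  # a side with fewer than 2 steps has undefined timing, reported as NA
  side_stats <- function(x, n_steps) {
    if (n_steps < 2L || length(x) < 1L) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(x), sd = pop_sd(x))
  }
  lt <- side_stats(step_int$left, sum(events$side == "left", na.rm = TRUE))
  rt <- side_stats(step_int$right, sum(events$side == "right", na.rm = TRUE))
  st <- side_stats(stride, length(stride) + 1L)
  sym <- if (is.na(lt[["mean"]]) || is.na(rt[["mean"]])) {
    NA_real_
  } else if (symmetry_form == "ratio") {
    lt[["mean"]] / rt[["mean"]]
  } else {
    abs(lt[["mean"]] - rt[["mean"]]) / (0.5 * (lt[["mean"]] + rt[["mean"]]))
  }
  total_steps <- nrow(events)
  walk_time <- sum(pw$duration_s)
  scalars <- c(
    total_distance_m = dist$total_distance,
    n_full_walkways = as.numeric(dist$n_full_walkways),
    last_walkway_distance_m = dist$last_walkway_distance,
    total_steps = as.numeric(total_steps),
    cadence_mean = mean(pw$cadence, na.rm = TRUE),
    cadence_sd = pop_sd(pw$cadence[is.finite(pw$cadence)]),
    cadence_overall = if (walk_time > 0) total_steps / walk_time * 60
                      else NA_real_,
    step_time_mean_left = lt[["mean"]], step_time_sd_left = lt[["sd"]],
    step_time_mean_right = rt[["mean"]], step_time_sd_right = rt[["sd"]],
    stride_time_mean = st[["mean"]], stride_time_sd = st[["sd"]],
    symmetry_index = sym,
    n_stops = as.numeric(if (is.null(stops)) 0L else nrow(stops)),
    stop_time_s = overlap_time(stops, -Inf, Inf)
  )
  structure(
    list(scalars = scalars, per_walkway = pw, distance = dist, stops = stops),
    class = "trial_outcomes"
  )
}

# total time of stop intervals overlapping [a, b]
overlap_time <- function(stops, a, b) {
  if (is.null(stops) || nrow(stops) == 0L) return(0)
  sum(pmax(0, pmin(stops[, 2L], b) - pmax(stops[, 1L], a)))
}

#' @export
print.trial_outcomes <- function(x, ...) {
  sc <- x$scalars
  cat(sprintf(
    paste0("<trial_outcomes> distance %.2f m (%d full walkways + %.2f m), ",
           "%d steps, cadence %.1f steps/min, symmetry %.3f\n"),
    sc[["total_distance_m"]], as.integer(sc[["n_full_walkways"]]),
    sc[["last_walkway_distance_m"]], as.integer(sc[["total_steps"]]),
    sc[["cadence_mean"]], sc[["symmetry_index"]]
  ))
  invisible(x)
}
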