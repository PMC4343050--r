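#' Detect turns from the continuous azimuth signal
#'
#' A walk test is performed back and forth on a straight walkway, so the
#' heading alternates between two plateaus ~180 degrees apart with quick
#' reversals at the walkway ends. A turn is *triggered* wherever the azimuth
#' range (max - min) within a sliding window of `trigger_window` seconds
#' exceeds `trigger_angle` degrees. Each trigger is then *extended* to the
#' maximal contiguous run of samples whose centred `sd_window`-second frame
#' has an azimuth standard deviation above `sd_threshold` degrees, which
#' captures the full duration of the rotation at different turning speeds.
#' Overlapping triggers merge into one interval.
#'
#' @param azimuth_cont Continuous (wrap-corrected) azimuth in degrees, see
#'   [correct_azimuth()].
#' @param t Uniform time grid in seconds.
#' @param trigger_angle Azimuth range (degrees) that marks a turn within the
#'   trigger window. Default 100.
#' @param trigger_window Trigger window length in seconds. Default 3.
#' @param sd_threshold Per-frame azimuth standard deviation (degrees)
#'   defining the turn extent. Default 10.
#' @param sd_window Frame length in seconds for the extent criterion.
#'   Default 1.
#' @return A two-column matrix of `(start, end)` turn intervals in seconds,
#'   in time order (zero rows when no turn is found).
#' @export
detect_turns <- function(azimuth_cont, t, trigger_angle = 100,
                         trigger_window = 3, sd_threshold = 10,
                         sd_window = 1) {
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  n <- length(t)
  stopifnot(length(azimuth_cont) == n)
  rate <- (n - 1) / (t[n] - t[1L])
  empty <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  w <- min(max(2L, round(trigger_window * rate) + 1L), n)
  k <- min(max(2L, round(sd_window * rate) + 1L), n)

  # rolling range over the trigger window (left-aligned)
  rmax <- roll_max(azimuth_cont, w)
  rmin <- -roll_max(-azimuth_cont, w)
  trig <- (rmax - rmin) > trigger_angle
  if (!any(trig)) return(empty)

  # samples covered by any triggering window
  covered <- logical(n)
  ti <- which(trig)
  for (i in ti) covered[i:min(n, i + w - 1L)] <- TRUE

  # centred rolling SD (population) for the extent criterion
  sdv <- roll_sd_centered(azimuth_cont, k)
  sd_ok <- sdv > sd_threshold

  # maximal contiguous sd_ok runs that intersect a trigger region
  runs <- bool_runs(sd_ok)
  keep <- runs[apply(runs, 1L, function(r) any(covered[r[1L]:r[2L]])), ,
               drop = FALSE]
  if (nrow(keep) == 0L) {
    # degenerate: trigger without an SD run (near-instant rotation);
    # fall back to the covered trigger region itself
    keep <- bool_runs(covered)
  }
  # merge overlapping/adjacent intervals
  keep <- keep[order(keep[, 1L]), , drop = FALSE]
  merged <- keep[1L, , drop = FALSE]
  if (nrow(keep) > 1L) {
    for (i in 2L:nrow(keep)) {
      last <- nrow(merged)
      if (keep[i, 1L] <= merged[last, 2L] + 1L) {
        merged[last, 2L] <- max(merged[last, 2L], keep[i, 2L])
      } else {
        merged <- rbind(merged, keep[i, , drop = FALSE])
      }
    }
  }
  out <- cbind(start = t[merged[, 1L]], end = t[merged[, 2L]])
  out
}

# rolling max over windows of length k, left-aligned, length n - k + 1
roll_max <- function(x, k) {
  n <- length(x)
  m <- n - k + 1L
  out <- numeric(n)
  # monotonic deque algorithm, O(n)
  dq <- integer(0)
  res <- numeric(m)
  for (i in seq_len(n)) {
    while (length(dq) && x[dq[length(dq)]] <= x[i]) {
      dq <- dq[-length(dq)]
    }
    dq <- c(dq, i)
    if (dq[1L] <= i - k) dq <- dq[-1L]
    if (i >= k) res[i - k + 1L] <- x[dq[1L]]
  }
  c(res, rep(NA_real_, k - 1L))[seq_len(n)] -> out
  out[is.na(out)] <- -Inf  # windows that would overrun the end never trigger
  out
}

# centred rolling population SD over windows of length k
roll_sd_centered <- function(x, k) {
  n <- length(x)
  kern <- rep(1 / k, k)
  m1 <- stats::filter(x, kern, sides = 2L)
  m2 <- stats::filter(x^2, kern, sides = 2L)
  v <- pmax(as.numeric(m2 - m1^2), 0)
  v[is.na(v)] <- 0
  sqrt(v)
}

# index runs of TRUE values as a (start, end) matrix
bool_runs <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Tile a trial span into alternating walkway and turn segments
#'
#' @param turn_intervals Two-column matrix of sorted, non-overlapping turn
#'   intervals in seconds, inside `t_span`.
#' @param t_span Length-2 numeric, trial `(start, end)` in seconds.
#' @param min_walkway Walkways shorter than this (seconds) are flagged
#'   degenerate (trial started or ended mid-turn); they are kept in the
#'   tiling but excluded from step-length estimation.
#' @return A `walk_segments` data frame with columns `kind`
#'   (`walkway`/`turn`), `start`, `end`, `index` (walkway ordinal, `NA` for
#'   turns) and `degenerate`. Segments tile `t_span` exactly; the first and
#'   last segments are walkways.
#' @export
segment_trial <- function(turn_intervals, t_span, min_walkway = 0.5) {
  s0 <- t_span[1L]
  s1 <- t_span[2L]
  if (is.null(turn_intervals) || nrow(turn_intervals) == 0L) {
    seg <- data.frame(kind = "walkway", start = s0, end = s1, index = 1L,
                      degenerate = (s1 - s0) < min_walkway)
    class(seg) <- c("walk_segments", "data.frame")
    return(seg)
  }
  ti <- turn_intervals[order(turn_intervals[, 1L]), , drop = FALSE]
  if (any(ti[, 1L] < s0 - 1e-9) || any(ti[, 2L] > s1 + 1e-9)) {
    stop("turn interval outside the trial span", call. = FALSE)
  }
  if (nrow(ti) > 1L && any(ti[-1L, 1L] < ti[-nrow(ti), 2L])) {
    stop("turn intervals must be non-overlapping", call. = FALSE)
  }
  eps <- 1e-6
  # ensure a positive-length leading/trailing walkway exists
  if (ti[1L, 1L] <= s0) ti[1L, 1L] <- s0 + eps
  if (ti[nrow(ti), 2L] >= s1) ti[nrow(ti), 2L] <- s1 - eps
  kind <- character(0); start <- numeric(0); end <- numeric(0)
  cur <- s0
  for (i in seq_len(nrow(ti))) {
    kind <- c(kind, "walkway", "turn")
    start <- c(start, cur, ti[i, 1L])
    end <- c(end, ti[i, 1L], ti[i, 2L])
    cur <- ti[i, 2L]
  }
  kind <- c(kind, "walkway"); start <- c(start, cur); end <- c(end, s1)
  seg <- data.frame(kind = kind, start = start, end = end,
                    index = NA_integer_, degenerate = FALSE)
  is_w <- seg$kind == "walkway"
  seg$index[is_w] <- seq_len(sum(is_w))
  seg$degenerate[is_w] <- (seg$end[is_w] - seg$start[is_w]) < min_walkway
  class(seg) <- c("walk_segments", "data.frame")
  seg
}
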