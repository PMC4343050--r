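#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis pipeline, with the
#' device-validated defaults: 50 Hz resampling, 4 Hz / 1 Hz low-pass
#' cutoffs, 100 degrees per 3 s turn trigger with a 10 degree per 1 s
#' duration criterion, locking-period rule constants 0.7 s / 0.4 s / 0.6,
#' axis-selection ratio 1.4, shape-similarity ratios 0.35 (detection) and
#' 0.30 (recovery), missed-step gap factor 1.75, and last-walkway slowdown
#' ratio 0.9.
#'
#' @param target_rate Uniform resampling rate, Hz.
#' @param cutoff_step,cutoff_lr Low-pass cutoffs (Hz) for step detection and
#'   left/right labelling.
#' @param wrap_trigger Azimuth unwrap trigger, degrees (see
#'   [correct_azimuth()]).
#' @param turn_angle,turn_window,turn_sd,turn_sd_window Turn detection
#'   constants (see [detect_turns()]).
#' @param calib_seconds Self-calibration window, seconds.
#' @param axis_ratio Axis-selection reversal-count ratio.
#' @param shape_ratio,recover_ratio Shape-similarity acceptance ratios.
#' @param gap_factor Missed-step gap trigger multiple.
#' @param timing_tolerance Recovery timing tolerance (fraction of the
#'   previous inter-step interval).
#' @param boundary_fraction Fraction of the detection channel's boundary
#'   threshold that a candidate's peak prominence must exceed (the rule that
#'   admits a walkway's attenuated first/last steps).
#' @param slowdown_ratio Last-walkway step-duration ratio below which step
#'   length is scaled.
#' @param symmetry_form `"ratio"` or `"asymmetry"` symmetry index.
#' @return A `sixmwt_config` list.
#' @export
sixmwt_config <- function(target_rate = 50, cutoff_step = 4, cutoff_lr = 1,
                          wrap_trigger = 180, turn_angle = 100,
                          turn_window = 3, turn_sd = 10, turn_sd_window = 1,
                          calib_seconds = 5, axis_ratio = 1.4,
                          shape_ratio = 0.35, recover_ratio = 0.30,
                          gap_factor = 1.75, timing_tolerance = 0.25,
                          boundary_fraction = 0.65, slowdown_ratio = 0.9,
                          symmetry_form = "ratio") {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1L))
  if (any(vapply(cfg[num], function(v) v <= 0, logical(1L)))) {
    stop("all numeric configuration values must be positive", call. = FALSE)
  }
  structure(cfg, class = "sixmwt_config")
}

#' Run the full walk-test analysis pipeline
#'
#' Executes regularization, filtering, turn detection, segmentation,
#' self-calibration, step detection, missed-step recovery, foot-strike
#' timing, left/right labelling with alternation repair, and outcome
#' computation.
#'
#' @param trial A [sensor_trial()] (raw; it is regularized internally).
#' @param config A [sixmwt_config()].
#' @return A `sixmwt_result` list: `outcomes` (a `trial_outcomes`), `events`
#'   (a `step_events` data frame), `segments`, `turns`, `stops`, `profile`,
#'   `trial` (the regularized trial) and `filtered`.
#' @export
run_sixmwt <- function(trial, config = sixmwt_config()) {
  reg <- regularize(trial, config$target_rate)
  fs <- filter_trial(reg, cutoff_step = config$cutoff_step,
                     cutoff_lr = config$cutoff_lr)
  turns <- detect_turns(fs$azimuth_cont, fs$t,
                        trigger_angle = config$turn_angle,
                        trigger_window = config$turn_window,
                        sd_threshold = config$turn_sd,
                        sd_window = config$turn_sd_window)
  segments <- segment_trial(turns, c(fs$t[1L], fs$t[length(fs$t)]))
  profile <- calibrate_trial(fs, segments,
                             calib_seconds = config$calib_seconds,
                             ratio_threshold = config$axis_ratio)
  sig <- if (profile$primary_axis == "forward") fs$forward_f4
         else fs$vertical_f4
  other <- if (profile$primary_axis == "forward") fs$vertical_f4
           else fs$forward_f4
  events <- detect_steps(sig, fs$t, profile, segments,
                         shape_ratio = config$shape_ratio,
                         boundary_fraction = config$boundary_fraction)
  rec <- recover_missed_steps(events, sig, other, fs$t, profile,
                              gap_factor = config$gap_factor,
                              recover_ratio = config$recover_ratio,
                              timing_tolerance = config$timing_tolerance)
  events <- time_foot_strikes(rec$events, reg$acc_forward, fs$t, profile)
  events <- classify_sides(events, fs$ml_f1, fs$t, profile)
  events <- repair_sequence(events, rec$stops)
  outcomes <- compute_gait_outcomes(events, segments, reg$walkway_length,
                                    stops = rec$stops,
                                    slowdown_ratio = config$slowdown_ratio,
                                    symmetry_form = config$symmetry_form)
  structure(
    list(outcomes = outcomes, events = events, segments = segments,
         turns = turns, stops = rec$stops, profile = profile, trial = reg,
         filtered = fs, config = config),
    class = "sixmwt_result"
  )
}

#' @export
print.sixmwt_result <- function(x, ...) {
  cat(sprintf("<sixmwt_result> %d steps, %d turns, %d stop(s)\n",
              nrow(x$events), nrow(x$turns), nrow(x$stops)))
  print(x$profile)
  print(x$outcomes)
  invisible(x)
}

#' Generate, analyse and score a set of synthetic scenarios
#'
#' Runs [generate_trial()], [run_sixmwt()] and [evaluate_detection()] for
#' each scenario and returns one summary row per trial.
#'
#' @param scenarios A list of [gait_scenario()] objects (e.g.
#'   [default_scenarios()]).
#' @param config A [sixmwt_config()].
#' @param tolerance Foot-strike timing tolerance in seconds.
#' @return A data frame with one row per scenario: step counts, accuracy,
#'   timing error mean/SD, side agreement, turn count difference and
#'   distance errors. The per-trial evaluation lists are attached as the
#'   `evaluations` attribute.
#' @export
run_bench <- function(scenarios, config = sixmwt_config(),
                      tolerance = 0.07) {
  rows <- list()
  evals <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    g <- generate_trial(sc)
    res <- run_sixmwt(g$trial, config)
    ev <- evaluate_detection(res, g$truth, tolerance)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(
      scenario = sc$label,
      axis = res$profile$primary_axis,
      true_steps = ev$n_true,
      detected_steps = ev$n_detected,
      accuracy_pct = ev$count_accuracy_pct,
      within_tol_pct = ev$within_tolerance_pct,
      mean_abs_dt_s = ev$mean_abs_dt,
      sd_abs_dt_s = ev$sd_abs_dt,
      side_agreement_pct = ev$side_agreement_pct,
      turn_count_diff = ev$turn_count_diff,
      true_distance_m = g$truth$true_distance,
      calc_distance_m = res$outcomes$scalars[["total_distance_m"]],
      distance_error_m = ev$distance_error_m,
      distance_error_pct = ev$distance_error_pct
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "evaluations") <- evals
  out
}
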