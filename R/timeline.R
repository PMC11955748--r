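#' Trial event timeline
#'
#' Declarative description of the within-trial event structure shared by all
#' preprocessing and analysis stages. All windows are half-open intervals
#' `[start, end)` in trial-relative milliseconds, so that a window "from 16.5
#' to 17 s" contains the sample at 16500 ms but not the one at 17000 ms and
#' adjacent windows never double-count boundary samples.
#'
#' The default instance encodes a 23.2 s trial sampled at 120 Hz with a
#' 2 s anticipation phase (15--17 s), a 500 ms baseline window at its end
#' (16.5--17 s), a 1.2 s reveal phase, and a 5 s outcome phase (18.2--23.2 s)
#' whose grid has exactly 600 sample slots.
#'
#' @param trial_duration_ms Total trial duration in milliseconds.
#' @param anticipation_window_ms Half-open `[start, end)` interval (ms) of the
#'   anticipation phase.
#' @param baseline_window_ms Half-open interval (ms) whose mean pupil diameter
#'   anchors the percent-change baseline correction. Must lie within the
#'   anticipation window.
#' @param reveal_window_ms Half-open interval (ms) during which the outcome
#'   starts to be revealed (between anticipation and outcome phases).
#' @param outcome_window_ms Half-open interval (ms) of the outcome phase over
#'   which the pupil response is analysed.
#' @param sampling_hz Nominal sampling rate of the eye tracker in Hz.
#'
#' @return An object of class `trial_timeline`: a list with the fields above
#'   plus `n_trial_slots` and `n_outcome_slots` (nominal grid sizes) and
#'   `step_ms` (nominal sample spacing).
#' @examples
#' tl <- trial_timeline()
#' tl$n_outcome_slots # 600
#' @export
trial_timeline <- function(trial_duration_ms = 23200,
                           anticipation_window_ms = c(15000, 17000),
                           baseline_window_ms = c(16500, 17000),
                           reveal_window_ms = c(17000, 18200),
                           outcome_window_ms = c(18200, 23200),
                           sampling_hz = 120) {
  check_window <- function(w, name) {
    if (!is.numeric(w) || length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      stop(sprintf("'%s' must be a numeric [start, end) interval with start < end", name))
  }
  check_window(anticipation_window_ms, "anticipation_window_ms")
  check_window(baseline_window_ms, "baseline_window_ms")
  check_window(reveal_window_ms, "reveal_window_ms")
  check_window(outcome_window_ms, "outcome_window_ms")
  if (trial_duration_ms <= 0 || sampling_hz <= 0)
    stop("trial_duration_ms and sampling_hz must be positive")
  if (baseline_window_ms[1] < anticipation_window_ms[1] ||
      baseline_window_ms[2] > anticipation_window_ms[2])
    stop("baseline window must lie within the anticipation window")
  if (outcome_window_ms[2] > trial_duration_ms)
    stop("outcome window extends beyond the trial duration")

  step_ms <- 1000 / sampling_hz
  structure(list(
    trial_duration_ms = trial_duration_ms,
    anticipation_window_ms = anticipation_window_ms,
    baseline_window_ms = baseline_window_ms,
    reveal_window_ms = reveal_window_ms,
    outcome_window_ms = outcome_window_ms,
    sampling_hz = sampling_hz,
    step_ms = step_ms,
    n_trial_slots = floor(trial_duration_ms * sampling_hz / 1000),
    n_outcome_slots = round(diff(outcome_window_ms) * sampling_hz / 1000)
  ), class = "trial_timeline")
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat("Trial timeline:", x$trial_duration_ms, "ms at", x$sampling_hz, "Hz\n")
  cat("  anticipation [", x$anticipation_window_ms[1], ",",
      x$anticipation_window_ms[2], ") ms\n")
  cat("  baseline     [", x$baseline_window_ms[1], ",",
      x$baseline_window_ms[2], ") ms\n")
  cat("  reveal       [", x$reveal_window_ms[1], ",",
      x$reveal_window_ms[2], ") ms\n")
  cat("  outcome      [", x$outcome_window_ms[1], ",",
      x$outcome_window_ms[2], ") ms (", x$n_outcome_slots, "slots )\n")
  invisible(x)
}

#' Preprocessing filter parameters
#'
#' Bundles the tunable parameters of the preprocessing cascade. Defaults
#' reproduce the standard analysis settings: 90th-percentile
#' neighbour-difference artifact filter, linear interpolation of gaps of at
#' most eight samples, outlier removal beyond three (unscaled) median
#' absolute deviations, and inclusion of trials with at least 10% valid
#' samples in the outcome window.
#'
#' @param percentile_cutoff Percentile in (0, 100] of the per-trace
#'   neighbour-difference score distribution above which (strictly) samples
#'   are removed.
#' @param max_gap_samples Maximal length (in samples) of a missing run that is
#'   linearly interpolated; longer runs are left missing.
#' @param mad_k Multiplier of the median absolute deviation beyond which
#'   (strictly) baseline-corrected samples are removed.
#' @param mad_scaled If `TRUE`, the MAD is multiplied by the normal
#'   consistency constant 1.4826; the default is the unscaled MAD.
#' @param min_outcome_fraction Minimal fraction of valid outcome-window grid
#'   points for a trial to be included (boundary kept: exactly this fraction
#'   is included). The robustness variant uses 0.50.
#' @param baseline_window_ms Optional override of the timeline's baseline
#'   window, a half-open `[start, end)` interval in ms.
#' @param location_change_window_ms Half-open interval (ms) of the
#'   change-of-location scene used for the screen-looking inclusion check.
#' @param min_location_change_fraction Minimal fraction of samples with gaze
#'   on screen during `location_change_window_ms` for trial inclusion; set to
#'   0 to disable the check.
#'
#' @return An object of class `filter_params` (a named list).
#' @examples
#' filter_params()
#' filter_params(min_outcome_fraction = 0.5) # robustness variant
#' @export
filter_params <- function(percentile_cutoff = 90,
                          max_gap_samples = 8,
                          mad_k = 3,
                          mad_scaled = FALSE,
                          min_outcome_fraction = 0.10,
                          baseline_window_ms = NULL,
                          location_change_window_ms = c(9000, 13400),
                          min_location_change_fraction = 0.5) {
  if (percentile_cutoff <= 0 || percentile_cutoff > 100)
    stop("percentile_cutoff must be in (0, 100]")
  if (max_gap_samples < 0) stop("max_gap_samples must be non-negative")
  if (mad_k <= 0) stop("mad_k must be positive")
  if (min_outcome_fraction <= 0 || min_outcome_fraction > 1)
    stop("min_outcome_fraction must be in (0, 1]")
  if (!is.null(baseline_window_ms) &&
      (length(baseline_window_ms) != 2L || baseline_window_ms[1] >= baseline_window_ms[2]))
    stop("baseline_window_ms must be a [start, end) interval")
  structure(list(
    percentile_cutoff = percentile_cutoff,
    max_gap_samples = as.integer(max_gap_samples),
    mad_k = mad_k,
    mad_scaled = isTRUE(mad_scaled),
    min_outcome_fraction = min_outcome_fraction,
    baseline_window_ms = baseline_window_ms,
    location_change_window_ms = location_change_window_ms,
    min_location_change_fraction = min_location_change_fraction
  ), class = "filter_params")
}

#' Screen geometry
#'
#' @param width_px,height_px Screen size in pixels; defaults match a
#'   1280 x 1024 presentation screen.
#' @return A list with class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024) {
  if (width_px <= 0 || height_px <= 0) stop("screen dimensions must be positive")
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px)),
            class = "screen_geometry")
}

# internal: is t inside half-open [w[1], w[2]) ?
in_window <- function(t, w) t >= w[1] & t < w[2]
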