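#' Remove physically unrealistic samples
#'
#' Sets pupil values to missing where they cannot be real measurements:
#' per eye, pupil diameters below zero; and, for samples whose gaze point is
#' present but falls outside the screen, both eyes' pupil values. A pure,
#' vectorised transformation -- no rows are dropped.
#'
#' @param samples Sample data frame with canonical columns (see
#'   [read_samples()]).
#' @param screen A [screen_geometry()].
#' @return The sample data frame with offending pupil values set to `NA`.
#' @export
remove_invalid <- function(samples, screen = screen_geometry()) {
  samples$pupil_left_mm[!is.na(samples$pupil_left_mm) &
                        samples$pupil_left_mm < 0] <- NA_real_
  samples$pupil_right_mm[!is.na(samples$pupil_right_mm) &
                         samples$pupil_right_mm < 0] <- NA_real_
  off <- !is.na(samples$gaze_x_px) & !is.na(samples$gaze_y_px) &
    (samples$gaze_x_px < 0 | samples$gaze_x_px > screen$width_px |
     samples$gaze_y_px < 0 | samples$gaze_y_px > screen$height_px)
  samples$pupil_left_mm[off] <- NA_real_
  samples$pupil_right_mm[off] <- NA_real_
  samples
}

#' Neighbour-difference artifact scores
#'
#' For each interior sample, the average of the absolute differences from
#' its previous and next sample:
#' `score_i = (|x_i - x_{i-1}| + |x_{i+1} - x_i|) / 2`.
#' The score is missing wherever the sample itself or either neighbour is
#' missing, and always at both endpoints. Large scores mark sample-to-sample
#' jumps typical of partial blinks and tracking artifacts.
#'
#' @param x Numeric pupil series (may contain `NA`).
#' @return Numeric vector of scores, same length as `x`.
#' @export
neighbor_diff_scores <- function(x) {
  n <- length(x)
  scores <- rep(NA_real_, n)
  if (n < 3L) return(scores)
  i <- 2:(n - 1)
  scores[i] <- (abs(x[i] - x[i - 1L]) + abs(x[i + 1L] - x[i])) / 2
  scores
}

#' Percentile cutoff artifact filter
#'
#' Removes samples whose neighbour-difference score strictly exceeds the
#' given percentile of the non-missing score distribution of this trace.
#' Scores are computed once on the input; there is no iterative
#' re-filtering. With the strict inequality a constant trace (all scores 0,
#' threshold 0) passes untouched.
#'
#' @param x Numeric pupil series.
#' @param percentile_cutoff Percentile in (0, 100], default 90.
#' @param scores Optional externally supplied score distribution (used for
#'   pooled-percentile mode); defaults to the trace's own scores.
#' @return `x` with filtered samples set to `NA`. If fewer than two
#'   non-missing scores exist the trace is returned unchanged.
#' @export
percentile_filter <- function(x, percentile_cutoff = 90, scores = NULL) {
  sc <- neighbor_diff_scores(x)
  pool <- if (is.null(scores)) sc else scores
  pool <- pool[!is.na(pool)]
  if (length(pool) < 2L) return(x)
  threshold <- stats::quantile(pool, percentile_cutoff / 100, names = FALSE)
  x[!is.na(sc) & sc > threshold] <- NA_real_
  x
}

#' Linear interpolation of short missing runs
#'
#' Fills maximal runs of at most `max_gap` consecutive missing values by
#' linear interpolation between the flanking non-missing samples. Longer
#' runs and runs touching either end of the series (no anchor on one side)
#' are left missing. At 120 Hz the default of 8 samples corresponds to
#' roughly 70 ms, short enough to bridge tracking dropouts but not blinks.
#'
#' @param x Numeric series on a uniform sample grid.
#' @param max_gap Maximal run length (in samples) to interpolate.
#' @return `x` with short interior gaps filled.
#' @export
interpolate_gaps <- function(x, max_gap = 8) {
  n <- length(x)
  if (n < 3L || !anyNA(x) || all(is.na(x))) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next            # edge run: no anchor
    x0 <- x[s - 1L]; x1 <- x[e + 1L]
    if (is.na(x0) || is.na(x1)) next       # cannot happen for maximal runs
    x[s:e] <- x0 + (x1 - x0) * seq_len(r$lengths[k]) / (r$lengths[k] + 1)
  }
  x
}

#' Combine left- and right-eye traces into a cyclopean trace
#'
#' Pointwise mean where both eyes are present, the present eye's value where
#' only one is, missing where both are.
#'
#' @param left,right Numeric series on the same grid.
#' @return Combined numeric series.
#' @export
combine_eyes <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right traces have different lengths (grid mismatch)")
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Percent-change baseline correction and outcome-phase segmentation
#'
#' Computes the baseline `b` as the mean of the non-missing samples in the
#' baseline window, transforms every sample to relative change
#' `(x - b) / b`, and restricts the result to the outcome-window grid.
#' Relative change is unitless, so the transform is invariant under
#' rescaling of the raw trace.
#'
#' @param x Numeric pupil series on the nominal trial grid (length
#'   `timeline$n_trial_slots`).
#' @param timeline A [trial_timeline()].
#' @param baseline_window_ms Optional `[start, end)` override of the
#'   timeline's baseline window.
#' @return A list: `rel_change` (length `timeline$n_outcome_slots`),
#'   `grid_t_ms` (grid times relative to outcome onset), `baseline_mm`
#'   (`NA` if no valid baseline sample or non-positive baseline), `n_valid`.
#' @export
baseline_correct <- function(x, timeline = trial_timeline(),
                             baseline_window_ms = NULL) {
  if (length(x) != timeline$n_trial_slots)
    stop("trace length ", length(x), " does not match the nominal trial grid (",
         timeline$n_trial_slots, " slots)")
  bw <- if (is.null(baseline_window_ms)) timeline$baseline_window_ms else baseline_window_ms
  t_grid <- (seq_along(x) - 1) * timeline$step_ms
  base_vals <- x[in_window(t_grid, bw)]
  base_vals <- base_vals[!is.na(base_vals)]
  out_idx <- which(in_window(t_grid, timeline$outcome_window_ms))
  grid_t_ms <- t_grid[out_idx] - timeline$outcome_window_ms[1]
  if (length(base_vals) == 0L || mean(base_vals) <= 0) {
    rel <- rep(NA_real_, length(out_idx))
    return(list(rel_change = rel, grid_t_ms = grid_t_ms,
                baseline_mm = NA_real_, n_valid = 0L))
  }
  b <- mean(base_vals)
  rel <- (x[out_idx] - b) / b
  list(rel_change = rel, grid_t_ms = grid_t_ms, baseline_mm = b,
       n_valid = sum(!is.na(rel)))
}

#' Median-absolute-deviation outlier exclusion
#'
#' Removes, in a single pass, points farther than `k` median absolute
#' deviations from the median of the non-missing values. The MAD is unscaled
#' by default (`median(|x - median|)`, no normal-consistency constant); the
#' strict inequality means that when the MAD is zero only points that differ
#' from the median at all are removed.
#'
#' @param x Numeric series (typically the baseline-corrected outcome trace).
#' @param k Positive MAD multiplier, default 3.
#' @param scaled If `TRUE`, multiply the MAD by 1.4826.
#' @return `x` with outlying points set to `NA`. Series with fewer than two
#'   non-missing points are returned unchanged.
#' @export
mad_exclude <- function(x, k = 3, scaled = FALSE) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) return(x)
  med <- stats::median(x[ok])
  mad_val <- stats::median(abs(x[ok] - med))
  if (scaled) mad_val <- mad_val * 1.4826
  x[ok & abs(x - med) > k * mad_val] <- NA_real_
  x
}

#' Trial inclusion by outcome-window coverage
#'
#' A trial is included if the fraction of valid outcome-window grid points
#' is at least `min_outcome_fraction`; "less than 10% excluded" is read
#' strictly, so a trial at exactly the threshold (e.g. 60 of 600) is kept.
#'
#' @param n_valid Number of non-missing outcome-window grid points.
#' @param n_slots Total number of outcome-window grid points (default 600).
#' @param min_outcome_fraction Inclusion threshold, default 0.10.
#' @return Logical scalar.
#' @export
include_trial <- function(n_valid, n_slots = 600, min_outcome_fraction = 0.10) {
  n_valid / n_slots >= min_outcome_fraction
}

#' Subject inclusion by condition coverage
#'
#' A subject enters a given analysis only with at least one included trial in
#' every condition cell the analysis requires.
#'
#' @param inclusion A per-trial inclusion report (data frame with columns
#'   `subject_id`, `included`, and the condition columns referenced by
#'   `required_cells`).
#' @param required_cells A list of named character vectors, one per required
#'   cell, e.g. `list(c(belief = "FB", outcome = "congruent"), ...)`.
#' @return A data frame with one row per subject: `subject_id`, `included`,
#'   and one logical column per required cell.
#' @export
include_subject <- function(inclusion, required_cells) {
  subjects <- unique(inclusion$subject_id)
  cell_name <- function(cell) paste(cell, collapse = "_")
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (cell in required_cells) {
    has <- vapply(subjects, function(s) {
      rows <- inclusion$subject_id == s & inclusion$included
      for (col in names(cell)) rows <- rows & inclusion[[col]] == cell[[col]]
      any(rows)
    }, logical(1))
    out[[cell_name(cell)]] <- has
  }
  out$included <- Reduce(`&`, out[setdiff(names(out), "subject_id")])
  out
}

#' Snap samples to the nominal sampling grid
#'
#' Hardware timestamps jitter; downstream gap counting is defined in
#' samples, so each recorded sample is assigned to the nearest slot of the
#' nominal grid (slot width `1000 / sampling_hz` ms). When several samples
#' compete for a slot the first wins; empty slots are missing.
#'
#' @param samples Sample data frame with canonical columns.
#' @param timeline A [trial_timeline()].
#' @return A list of full-length (`timeline$n_trial_slots`) vectors:
#'   `pupil_left`, `pupil_right`, `gaze_x`, `gaze_y`, `t_ms` (nominal grid
#'   times), with validity flags already applied to the pupil series.
#' @export
snap_to_grid <- function(samples, timeline = trial_timeline()) {
  n <- timeline$n_trial_slots
  slot <- round(samples$t_ms / timeline$step_ms) + 1L
  keep <- !is.na(slot) & slot >= 1L & slot <= n & !duplicated(slot)
  slot <- slot[keep]
  blank <- rep(NA_real_, n)
  pl <- pr <- gx <- gy <- blank
  pl[slot] <- ifelse(samples$valid_left[keep], samples$pupil_left_mm[keep], NA_real_)
  pr[slot] <- ifelse(samples$valid_right[keep], samples$pupil_right_mm[keep], NA_real_)
  gx[slot] <- samples$gaze_x_px[keep]
  gy[slot] <- samples$gaze_y_px[keep]
  list(pupil_left = pl, pupil_right = pr, gaze_x = gx, gaze_y = gy,
       t_ms = (seq_len(n) - 1) * timeline$step_ms)
}

#' Preprocess a single trial
#'
#' Runs the full cascade in fixed order: validity/grid snapping, removal of
#' unrealistic values, per-eye percentile filtering and gap interpolation,
#' binocular averaging, a second filter and interpolation pass on the
#' averaged trace, percent-change baseline correction with outcome-phase
#' segmentation, MAD outlier exclusion, and the inclusion rules.
#'
#' @param trial A trial as produced by [segment_trials()] or
#'   [generate_trial()].
#' @param params A [filter_params()].
#' @return A list of class `pupil_trace`: `meta`, `grid_t_ms`, `rel_change`
#'   (length 600 on the default timeline), `baseline_mm`, `n_valid`, and
#'   `report` -- a one-row inclusion report with `included`, `reason`
#'   (`ok`, `low_outcome_coverage`, `no_baseline`,
#'   `low_location_change_looking`) and `fraction_valid`.
#' @export
preprocess_trial <- function(trial, params = filter_params()) {
  timeline <- trial$timeline
  screen <- if (!is.null(trial$screen)) trial$screen else screen_geometry()
  g <- snap_to_grid(trial$samples, timeline)

  sm <- data.frame(pupil_left_mm = g$pupil_left, pupil_right_mm = g$pupil_right,
                   gaze_x_px = g$gaze_x, gaze_y_px = g$gaze_y)
  sm <- remove_invalid(sm, screen)

  left <- interpolate_gaps(percentile_filter(sm$pupil_left_mm,
                                             params$percentile_cutoff),
                           params$max_gap_samples)
  right <- interpolate_gaps(percentile_filter(sm$pupil_right_mm,
                                              params$percentile_cutoff),
                            params$max_gap_samples)
  both <- combine_eyes(left, right)
  both <- interpolate_gaps(percentile_filter(both, params$percentile_cutoff),
                           params$max_gap_samples)

  bc <- baseline_correct(both, timeline, params$baseline_window_ms)
  rel <- mad_exclude(bc$rel_change, params$mad_k, params$mad_scaled)
  n_valid <- sum(!is.na(rel))
  n_slots <- length(rel)

  # screen-looking check over the change-of-location window (automated
  # counterpart of the manual-coding inclusion rule)
  looking_ok <- TRUE
  if (params$min_location_change_fraction > 0) {
    lw <- in_window(g$t_ms, params$location_change_window_ms)
    if (any(lw)) {
      on_screen <- !is.na(g$gaze_x[lw]) & !is.na(g$gaze_y[lw]) &
        g$gaze_x[lw] >= 0 & g$gaze_x[lw] <= screen$width_px &
        g$gaze_y[lw] >= 0 & g$gaze_y[lw] <= screen$height_px
      looking_ok <- mean(on_screen) >= params$min_location_change_fraction
    }
  }

  reason <- if (!looking_ok) "low_location_change_looking"
    else if (is.na(bc$baseline_mm)) "no_baseline"
    else if (!include_trial(n_valid, n_slots, params$min_outcome_fraction))
      "low_outcome_coverage"
    else "ok"

  report <- cbind(trial$meta,
                  data.frame(included = reason == "ok", reason = reason,
                             fraction_valid = n_valid / n_slots,
                             stringsAsFactors = FALSE))
  structure(list(meta = trial$meta, grid_t_ms = bc$grid_t_ms,
                 rel_change = rel, baseline_mm = bc$baseline_mm,
                 n_valid = n_valid, report = report),
            class = "pupil_trace")
}

#' Preprocess a set of trials
#'
#' Applies [preprocess_trial()] to every trial and assembles the results
#' into a trace matrix plus per-trial metadata and the inclusion report.
#'
#' @param trials A list of trials.
#' @param params A [filter_params()].
#' @return A list of class `pupil_traces`: `rel` (matrix, included trials x
#'   grid points), `meta` (data frame, one row per included trial, with
#'   `baseline_mm` and `n_valid`), `grid_t_ms`, `inclusion` (report for all
#'   trials, included or not), `params`.
#' @export
preprocess_dataset <- function(trials, params = filter_params()) {
  traces <- lapply(trials, preprocess_trial, params = params)
  inclusion <- do.call(rbind, lapply(traces, `[[`, "report"))
  rownames(inclusion) <- NULL
  keep <- which(inclusion$included)
  grid_t_ms <- if (length(traces) > 0L) traces[[1L]]$grid_t_ms else numeric(0)
  rel <- if (length(keep) > 0L)
    do.call(rbind, lapply(traces[keep], `[[`, "rel_change"))
  else matrix(numeric(0), nrow = 0, ncol = length(grid_t_ms))
  meta <- if (length(keep) > 0L) {
    m <- do.call(rbind, lapply(traces[keep], `[[`, "meta"))
    m$baseline_mm <- vapply(traces[keep], `[[`, numeric(1), "baseline_mm")
    m$n_valid <- vapply(traces[keep], `[[`, integer(1), "n_valid")
    rownames(m) <- NULL
    m
  } else NULL
  structure(list(rel = rel, meta = meta, grid_t_ms = grid_t_ms,
                 inclusion = inclusion, params = params),
            class = "pupil_traces")
}

#' @export
print.pupil_traces <- function(x, ...) {
  cat("Preprocessed pupil traces:", nrow(x$rel), "included /",
      nrow(x$inclusion), "trials,", length(x$grid_t_ms), "grid points\n")
  invisible(x)
}

#' Multiverse robustness runner
#'
#' Re-runs preprocessing and the downstream contrast (time course plus
#' window-averaged Bayes factor) under every combination of filter-parameter
#' variants, so the stability of a result against preprocessing choices can
#' be inspected directly. Variants that fail are recorded as failed rows and
#' the run continues.
#'
#' @param trials List of trials.
#' @param grid A data frame of parameter variants; columns must be arguments
#'   of [filter_params()] (e.g. from `expand.grid(percentile_cutoff =
#'   c(90, 95), min_outcome_fraction = c(0.10, 0.50))`).
#' @param contrast,subset Passed to [per_timepoint_bf()] /
#'   [averaged_outcome_bf()].
#' @param method Bayes-factor method for the contrasts.
#' @return A data frame with one row per variant: the variant's parameters,
#'   `n_included`, `avg_bf10`, `n_windows`, `window_ms` (total evidence-window
#'   duration), and `error` (`NA` on success).
#' @export
multiverse_run <- function(trials, grid,
                           contrast = list(factor = "outcome",
                                           levels = c("congruent", "incongruent")),
                           subset = list(belief = "FB", block = "ObjectMemory"),
                           method = "bic_lmm") {
  if (is.null(grid) || nrow(grid) == 0L) stop("variant grid is empty")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    variant <- as.list(grid[i, , drop = FALSE])
    res <- tryCatch({
      params <- do.call(filter_params, variant)
      traces <- preprocess_dataset(trials, params)
      tc <- per_timepoint_bf(traces, contrast = contrast, subset = subset,
                             method = method)
      avg <- averaged_outcome_bf(traces, contrast = contrast, subset = subset,
                                 method = method)
      data.frame(variant = i, grid[i, , drop = FALSE],
                 n_included = sum(traces$inclusion$included),
                 avg_bf10 = avg$bf10, n_windows = nrow(tc$windows),
                 window_ms = if (nrow(tc$windows) > 0)
                   sum(tc$windows$end_ms - tc$windows$start_ms) else 0,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(variant = i, grid[i, , drop = FALSE], n_included = NA_integer_,
                 avg_bf10 = NA_real_, n_windows = NA_integer_,
                 window_ms = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
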