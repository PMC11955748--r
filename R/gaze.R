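#' Area-of-interest geometry
#'
#' Builds the named AOI rectangles for a trial given which side holds the
#' reality-congruent location. Rectangles are `c(xmin, xmax, ymin, ymax)` in
#' screen pixels; the default geometry places the two hiding locations in
#' the lower left and lower right of a 1280 x 1024 screen.
#'
#' @param congruent_side `"left"` or `"right"`.
#' @param left_rect,right_rect Rectangles of the two hiding locations.
#' @param screen A [screen_geometry()]; rectangles must lie within it.
#' @return A list with elements `congruent_location` and
#'   `incongruent_location`.
#' @export
aoi_set <- function(congruent_side,
                    left_rect = c(200, 480, 600, 840),
                    right_rect = c(800, 1080, 600, 840),
                    screen = screen_geometry()) {
  congruent_side <- match.arg(congruent_side, c("left", "right"))
  for (r in list(left_rect, right_rect)) {
    if (length(r) != 4L || r[1] >= r[2] || r[3] >= r[4])
      stop("AOI rectangles must be c(xmin, xmax, ymin, ymax) with min < max")
    if (r[1] < 0 || r[2] > screen$width_px || r[3] < 0 || r[4] > screen$height_px)
      stop("AOI rectangle extends beyond the screen")
  }
  if (congruent_side == "left")
    list(congruent_location = left_rect, incongruent_location = right_rect)
  else
    list(congruent_location = right_rect, incongruent_location = left_rect)
}

point_in_rect <- function(x, y, rect) {
  !is.na(x) & !is.na(y) &
    x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

#' Sliding-window velocity fixation detection
#'
#' Classifies gaze samples with an Olsson-style sliding-window velocity
#' filter (the algorithm behind the classic Tobii fixation filter): for each
#' sample the detector compares the average gaze position of the preceding
#' and following `window` samples; samples whose windowed displacement
#' exceeds the velocity threshold are saccadic. Maximal runs of
#' non-saccadic samples become candidate fixations; consecutive fixations
#' whose centroids lie closer than `distance_threshold` are merged, and
#' fixations shorter than `min_duration_ms` are discarded.
#'
#' @param gaze_x,gaze_y Gaze coordinates (px) on the nominal sampling grid
#'   (`NA` where missing).
#' @param t_ms Sample times (ms), same length.
#' @param velocity_threshold Velocity threshold, default 35. Interpreted in
#'   pixels per window (`velocity_mode = "px_per_window"`, the original
#'   filter's convention) or pixels per second (`"px_per_s"`).
#' @param distance_threshold Centroid merge distance in pixels, default 35.
#' @param window Sliding-window half-width in samples, default 5.
#' @param min_duration_ms Minimal fixation duration, default 60 ms.
#' @param velocity_mode Unit convention for `velocity_threshold`.
#' @param sampling_hz Sampling rate, used only in `"px_per_s"` mode.
#' @return A data frame of fixations: `start_ms`, `end_ms` (half-open),
#'   `x`, `y` (centroid), `duration_ms`. Empty for all-missing gaze.
#' @export
detect_fixations <- function(gaze_x, gaze_y, t_ms,
                             velocity_threshold = 35,
                             distance_threshold = 35,
                             window = 5,
                             min_duration_ms = 60,
                             velocity_mode = c("px_per_window", "px_per_s"),
                             sampling_hz = 120) {
  velocity_mode <- match.arg(velocity_mode)
  if (velocity_threshold <= 0 || distance_threshold <= 0)
    stop("thresholds must be positive")
  n <- length(gaze_x)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      x = numeric(0), y = numeric(0), duration_ms = numeric(0))
  valid <- !is.na(gaze_x) & !is.na(gaze_y)
  if (!any(valid) || n < 2 * window + 1) return(empty)

  thr_px <- if (velocity_mode == "px_per_window") velocity_threshold
    else velocity_threshold * window / sampling_hz
  step_ms <- if (n >= 2) stats::median(diff(t_ms)) else 1000 / sampling_hz

  # windowed displacement: distance between the mean positions of the
  # preceding and following `window` samples (valid samples only),
  # computed for all samples at once from prefix sums
  px <- cumsum(c(0, ifelse(valid, gaze_x, 0)))
  py <- cumsum(c(0, ifelse(valid, gaze_y, 0)))
  pc <- cumsum(c(0, as.numeric(valid)))
  range_mean <- function(pref, lo, hi) {  # mean over samples lo..hi (1-based)
    s <- pref[pmin(hi, n) + 1L] - pref[pmax(lo, 1L)]
    s
  }
  i <- seq_len(n)
  b_lo <- i - window; b_hi <- i - 1L
  a_lo <- i; a_hi <- i + window - 1L
  b_cnt <- range_mean(pc, b_lo, b_hi); a_cnt <- range_mean(pc, a_lo, a_hi)
  b_cnt[1L] <- 0
  bx <- range_mean(px, b_lo, b_hi) / b_cnt
  by <- range_mean(py, b_lo, b_hi) / b_cnt
  ax <- range_mean(px, a_lo, a_hi) / a_cnt
  ay <- range_mean(py, a_lo, a_hi) / a_cnt
  vel <- sqrt((ax - bx)^2 + (ay - by)^2)
  # samples without motion evidence on one side (edges, isolated data)
  # carry no saccade signal and stay classifiable as fixation
  is_fix <- valid & (b_cnt == 0 | a_cnt == 0 | !is.na(vel) & vel <= thr_px)

  r <- rle(is_fix)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  fixes <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    idx <- idx[valid[idx]]
    if (length(idx) == 0L) next
    fixes[[length(fixes) + 1L]] <- list(
      idx = idx,
      start_ms = t_ms[min(idx)], end_ms = t_ms[max(idx)] + step_ms,
      x = mean(gaze_x[idx]), y = mean(gaze_y[idx]))
  }
  if (length(fixes) == 0L) return(empty)

  # merge consecutive fixations with nearby centroids
  merged <- list(fixes[[1L]])
  for (f in fixes[-1L]) {
    last <- merged[[length(merged)]]
    if (sqrt((f$x - last$x)^2 + (f$y - last$y)^2) < distance_threshold) {
      idx <- c(last$idx, f$idx)
      merged[[length(merged)]] <- list(
        idx = idx, start_ms = last$start_ms, end_ms = f$end_ms,
        x = mean(gaze_x[idx]), y = mean(gaze_y[idx]))
    } else merged[[length(merged) + 1L]] <- f
  }
  out <- do.call(rbind, lapply(merged, function(f)
    data.frame(start_ms = f$start_ms, end_ms = f$end_ms, x = f$x, y = f$y,
               duration_ms = f$end_ms - f$start_ms)))
  out <- out[out$duration_ms >= min_duration_ms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anticipatory-looking scores from fixations
#'
#' Scores the anticipation-phase looking behaviour of one trial: per-AOI
#' looking time is the summed fixation duration clipped to the analysis
#' window (fixations assigned to AOIs by centroid), the differential looking
#' score is
#' `DLS = (t_congruent - t_incongruent) / (t_congruent + t_incongruent)`,
#' and the first gaze is the AOI of the earliest in-window fixation that
#' lands in an AOI.
#'
#' @param fixations Fixation data frame from [detect_fixations()].
#' @param aois AOI set from [aoi_set()].
#' @param window Half-open analysis window in trial-relative ms, default
#'   `[15000, 17000)`.
#' @param denominator `"aoi_total"` (default; DLS denominator is total AOI
#'   looking) or `"window_total"` (denominator is the window length).
#' @return A list: `dls` (`NA` when the denominator is zero), `first_gaze`
#'   (`"congruent"`, `"incongruent"`, or `"none"`), `t_congruent_ms`,
#'   `t_incongruent_ms`.
#' @export
anticipatory_scores <- function(fixations, aois, window = c(15000, 17000),
                                denominator = c("aoi_total", "window_total")) {
  denominator <- match.arg(denominator)
  none <- list(dls = NA_real_, first_gaze = "none",
               t_congruent_ms = 0, t_incongruent_ms = 0)
  if (is.null(fixations) || nrow(fixations) == 0L) return(none)
  clip_start <- pmax(fixations$start_ms, window[1])
  clip_end <- pmin(fixations$end_ms, window[2])
  dur <- clip_end - clip_start
  keep <- dur > 0
  if (!any(keep)) return(none)
  fx <- fixations[keep, , drop = FALSE]
  dur <- dur[keep]; clip_start <- clip_start[keep]
  in_c <- point_in_rect(fx$x, fx$y, aois$congruent_location)
  in_i <- !in_c & point_in_rect(fx$x, fx$y, aois$incongruent_location)
  t_c <- sum(dur[in_c]); t_i <- sum(dur[in_i])
  denom <- if (denominator == "aoi_total") t_c + t_i else diff(window)
  dls <- if (denom > 0 && (t_c + t_i) > 0) (t_c - t_i) / denom else NA_real_
  aoi_hit <- in_c | in_i
  first_gaze <- if (!any(aoi_hit)) "none" else {
    first <- which(aoi_hit)[which.min(clip_start[aoi_hit])]
    if (in_c[first]) "congruent" else "incongruent"
  }
  list(dls = dls, first_gaze = first_gaze,
       t_congruent_ms = t_c, t_incongruent_ms = t_i)
}

#' Trial-level anticipatory-looking scores for a dataset
#'
#' Convenience wrapper: detects fixations and computes [anticipatory_scores()]
#' for every trial, resolving each trial's AOI mapping from its
#' `congruent_side`.
#'
#' @param trials List of trials (see [segment_trials()]).
#' @param window Analysis window in ms.
#' @param ... Passed to [detect_fixations()].
#' @return A data frame with one row per trial: trial metadata plus `dls`,
#'   `first_gaze`, `t_congruent_ms`, `t_incongruent_ms`.
#' @export
score_anticipatory_looking <- function(trials, window = c(15000, 17000), ...) {
  rows <- lapply(trials, function(trial) {
    g <- snap_to_grid(trial$samples, trial$timeline)
    fx <- detect_fixations(g$gaze_x, g$gaze_y, g$t_ms,
                           sampling_hz = trial$timeline$sampling_hz, ...)
    aois <- aoi_set(trial$meta$congruent_side)
    sc <- anticipatory_scores(fx, aois, window)
    cbind(trial$meta, as.data.frame(sc, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate first-gaze outcomes per subject
#'
#' Majority vote of each subject's trial-level first gazes ("none" trials
#' ignored; exact ties dropped), yielding the success/trial counts for a
#' group-level binomial test of first gaze toward the congruent location.
#'
#' @param scores Data frame from [score_anticipatory_looking()] (typically
#'   already filtered to one condition cell).
#' @return A list: `k` subjects whose majority first gaze was congruent, `n`
#'   subjects with a majority.
#' @export
aggregate_first_gaze <- function(scores) {
  per_subject <- tapply(scores$first_gaze, scores$subject_id, function(fg) {
    fg <- fg[fg != "none"]
    if (length(fg) == 0L) return(NA)
    n_c <- sum(fg == "congruent"); n_i <- sum(fg == "incongruent")
    if (n_c == n_i) NA else n_c > n_i
  })
  per_subject <- per_subject[!is.na(per_subject)]
  list(k = sum(unlist(per_subject)), n = length(per_subject))
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two categorical label sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal label distributions. When both raters assign a single identical
#' label throughout (`p_e = 1`), kappa is defined as 1.
#'
#' @param labels_a,labels_b Equal-length categorical sequences.
#' @return Numeric scalar in `[-1, 1]`.
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1L)
    stop("label sequences must have equal length >= 1")
  levels_all <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = levels_all)
  b <- factor(as.character(labels_b), levels = levels_all)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}
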