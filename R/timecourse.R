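subset_traces <- function(traces, subset) {
  keep <- rep(TRUE, nrow(traces$meta))
  for (col in names(subset)) {
    if (is.null(traces$meta[[col]]))
      stop("subset refers to unknown metadata column: ", col)
    keep <- keep & traces$meta[[col]] %in% subset[[col]]
  }
  keep
}

# Per-timepoint BIC-LMM engine: the exact profiled-ML random-intercept fit
# (see R/lmm.R), with the design matrix rebuilt from the timepoint's
# missingness pattern. Falls back to NA on numerical failure.
lmm_point_bf <- function(values, is_l1, subject) {
  ok <- !is.na(values)
  y <- values[ok]
  X_alt <- cbind(1, as.numeric(is_l1[ok]))
  X_null <- X_alt[, 1L, drop = FALSE]
  tryCatch(ri_bic_bf(y, X_alt, X_null, subject[ok]),
           error = function(e) NA_real_)
}

#' Per-timepoint Bayes factor contrast along the outcome-phase grid
#'
#' For every grid point from `analysis_start_ms` onward, contrasts the two
#' condition levels on the trials with a valid value at that point --- by
#' default with the BIC-approximated mixed model (condition fixed effect,
#' subject random intercept), alternatively with a subject-aggregated JZS
#' t test --- and detects evidence windows: maximal runs of consecutive
#' timepoints whose BF10 reaches the threshold with a constant direction.
#' Timepoints where either condition has fewer than `min_subjects` subjects
#' with data are skipped (BF missing) rather than imputed. No multiplicity
#' correction is applied across timepoints; windows are descriptive.
#'
#' @param traces A `pupil_traces` object from [preprocess_dataset()].
#' @param contrast A list: `factor` (metadata column) and `levels`
#'   (its two levels, first minus second defines the direction sign).
#' @param subset Named list restricting trials, e.g.
#'   `list(belief = "FB", block = "ObjectMemory", age_group = "9mo")`.
#' @param method `"bic_lmm"` (default) or `"jzs"`.
#' @param analysis_start_ms First outcome-phase time (ms) entering the
#'   analysis, default 1000.
#' @param bf_threshold Evidence-window threshold on BF10, default 3.
#' @param min_run Minimal window length in grid points, default 1.
#' @param min_subjects Minimal subjects per condition per timepoint.
#' @return An object of class `bf_timecourse`: `series` (data frame `t_ms`,
#'   `bf10`, `direction`, `n1`, `n2`), `windows` (see [detect_windows()]),
#'   plus the settings. `direction` is +1 when the first contrast level has
#'   the larger mean.
#' @export
per_timepoint_bf <- function(traces, contrast = list(factor = "outcome",
                                                     levels = c("congruent", "incongruent")),
                             subset = list(),
                             method = c("bic_lmm", "jzs"),
                             analysis_start_ms = 1000,
                             bf_threshold = 3, min_run = 1,
                             min_subjects = 2) {
  method <- match.arg(method)
  keep <- subset_traces(traces, subset)
  meta <- traces$meta[keep, , drop = FALSE]
  rel <- traces$rel[keep, , drop = FALSE]
  cond <- meta[[contrast$factor]]
  if (!all(contrast$levels %in% unique(cond)))
    stop("contrast level(s) absent from the data: ",
         paste(setdiff(contrast$levels, unique(cond)), collapse = ", "))
  sel <- cond %in% contrast$levels
  meta <- meta[sel, , drop = FALSE]; rel <- rel[sel, , drop = FALSE]
  cond <- factor(meta[[contrast$factor]], levels = contrast$levels)
  subj <- meta$subject_id

  t_ms <- traces$grid_t_ms
  eval_idx <- which(t_ms >= analysis_start_ms)
  if (length(eval_idx) == 0L) stop("no grid points at or after analysis_start_ms")

  bf10 <- rep(NA_real_, length(t_ms))
  direction <- rep(NA_real_, length(t_ms))
  n1 <- n2 <- rep(NA_integer_, length(t_ms))
  is_l1 <- cond == contrast$levels[1L]
  for (j in eval_idx) {
    v <- rel[, j]
    ok <- !is.na(v)
    s1 <- length(unique(subj[ok & is_l1]))
    s2 <- length(unique(subj[ok & !is_l1]))
    n1[j] <- s1; n2[j] <- s2
    if (s1 < min_subjects || s2 < min_subjects) next
    m1 <- mean(v[ok & is_l1]); m2 <- mean(v[ok & !is_l1])
    direction[j] <- sign(m1 - m2)
    bf10[j] <- if (method == "bic_lmm") lmm_point_bf(v, is_l1, subj)
      else {
        agg <- tapply(v[ok], list(as.character(subj[ok]), cond[ok]), mean)
        complete <- stats::complete.cases(agg)
        if (sum(complete) < min_subjects) NA_real_
        else tryCatch(jzs_ttest_bf(agg[complete, 1L], agg[complete, 2L],
                                   paired = TRUE)$bf10,
                      error = function(e) NA_real_)
      }
  }
  if (all(is.na(bf10))) stop("no evaluable timepoints for this contrast")
  series <- data.frame(t_ms = t_ms, bf10 = bf10, direction = direction,
                       n1 = n1, n2 = n2)
  windows <- detect_windows(bf10, t_ms, direction, threshold = bf_threshold,
                            min_run = min_run)
  structure(list(series = series, windows = windows, contrast = contrast,
                 subset = subset, method = method,
                 analysis_start_ms = analysis_start_ms,
                 bf_threshold = bf_threshold,
                 note = "no multiplicity correction across timepoints"),
            class = "bf_timecourse")
}

#' @export
print.bf_timecourse <- function(x, ...) {
  cat("BF time course (", x$method, "): ",
      sum(!is.na(x$series$bf10)), " evaluable timepoints, ",
      nrow(x$windows), " evidence window(s)\n", sep = "")
  if (nrow(x$windows) > 0) print(x$windows)
  invisible(x)
}

#' Detect evidence windows in a Bayes factor series
#'
#' Maximal runs of consecutive grid points with `bf10 >= threshold` and
#' constant direction, at least `min_run` points long, reported with
#' half-open millisecond bounds (`end_ms` is the grid step past the last
#' suprathreshold point). Missing BF values and direction changes break
#' runs; no bridging over sub-threshold points.
#'
#' @param bf10 Numeric BF series on a uniform grid.
#' @param t_ms Grid times in ms.
#' @param direction Direction sign per point (+1/-1), same length.
#' @param threshold BF10 threshold, default 3.
#' @param min_run Minimal run length in grid points, default 1.
#' @return Data frame: `start_ms`, `end_ms`, `direction`, `max_bf10`,
#'   `n_points`.
#' @export
detect_windows <- function(bf10, t_ms, direction = rep(1, length(bf10)),
                           threshold = 3, min_run = 1) {
  stopifnot(length(bf10) == length(t_ms), length(direction) == length(bf10))
  step <- if (length(t_ms) >= 2) stats::median(diff(t_ms)) else 0
  above <- !is.na(bf10) & bf10 >= threshold & !is.na(direction)
  # run id changes when above-status or direction changes
  dir_key <- ifelse(above, direction, NA_real_)
  run_id <- cumsum(c(TRUE, above[-1L] != above[-length(above)] |
                       (above[-1L] & above[-length(above)] &
                          dir_key[-1L] != dir_key[-length(dir_key)])))
  out <- list()
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (!above[idx[1L]] || length(idx) < min_run) next
    out[[length(out) + 1L]] <- data.frame(
      start_ms = t_ms[idx[1L]], end_ms = t_ms[idx[length(idx)]] + step,
      direction = direction[idx[1L]], max_bf10 = max(bf10[idx]),
      n_points = length(idx))
  }
  if (length(out) == 0L)
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      direction = numeric(0), max_bf10 = numeric(0),
                      n_points = integer(0)))
  do.call(rbind, out)
}

#' Window-averaged outcome-phase Bayes factor contrast
#'
#' Averages each trial's valid relative-change values over the whole
#' outcome window and contrasts the two condition levels on those per-trial
#' means, by the BIC-approximated mixed model (default) or the
#' subject-aggregated JZS t test.
#'
#' @inheritParams per_timepoint_bf
#' @return A `bf_result`; its `direction` field is +1 when the first
#'   contrast level has the larger mean.
#' @export
averaged_outcome_bf <- function(traces, contrast = list(factor = "outcome",
                                                        levels = c("congruent", "incongruent")),
                                subset = list(),
                                method = c("bic_lmm", "jzs")) {
  method <- match.arg(method)
  keep <- subset_traces(traces, subset)
  meta <- traces$meta[keep, , drop = FALSE]
  rel <- traces$rel[keep, , drop = FALSE]
  cond <- meta[[contrast$factor]]
  sel <- cond %in% contrast$levels
  if (!all(contrast$levels %in% unique(cond)))
    stop("contrast level(s) absent from the data: ",
         paste(setdiff(contrast$levels, unique(cond)), collapse = ", "))
  meta <- meta[sel, , drop = FALSE]; rel <- rel[sel, , drop = FALSE]
  cond <- factor(meta[[contrast$factor]], levels = contrast$levels)
  trial_means <- rowMeans(rel, na.rm = TRUE)
  if (method == "bic_lmm") {
    out <- bic_lmm_bf(trial_means, cond, meta$subject_id)
  } else {
    agg <- tapply(trial_means, list(as.character(meta$subject_id), cond), mean)
    complete <- stats::complete.cases(agg)
    out <- jzs_ttest_bf(agg[complete, 1L], agg[complete, 2L], paired = TRUE)
    out$direction <- sign(mean(agg[complete, 1L] - agg[complete, 2L]))
  }
  out
}

#' Plot a Bayes factor time course
#'
#' Condition means with standard-error ribbons over the outcome-phase grid,
#' with detected evidence windows shaded. Requires ggplot2.
#'
#' @param traces A `pupil_traces` object.
#' @param timecourse A `bf_timecourse` from [per_timepoint_bf()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(traces, timecourse) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  keep <- subset_traces(traces, timecourse$subset)
  meta <- traces$meta[keep, , drop = FALSE]
  rel <- traces$rel[keep, , drop = FALSE]
  cond <- meta[[timecourse$contrast$factor]]
  rows <- lapply(timecourse$contrast$levels, function(lev) {
    m <- rel[cond == lev, , drop = FALSE]
    data.frame(t_ms = traces$grid_t_ms,
               mean = colMeans(m, na.rm = TRUE),
               se = apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) /
                            sqrt(sum(!is.na(v)))),
               condition = lev)
  })
  df <- do.call(rbind, rows)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$mean,
                                        colour = .data$condition,
                                        fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from outcome onset (ms)",
                  y = "Relative pupil change") +
    ggplot2::theme_minimal()
  if (nrow(timecourse$windows) > 0)
    p <- p + ggplot2::annotate("rect",
                               xmin = timecourse$windows$start_ms,
                               xmax = timecourse$windows$end_ms,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  p
}
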