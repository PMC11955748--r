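# Independent, deliberately plain reference implementations used as oracles.
# Each is written as a direct loop over the definition, separate from the
# vectorised package code it checks.

ref_neighbor_scores <- function(x) {
  n <- length(x)
  s <- rep(NA_real_, n)
  if (n < 3) return(s)
  for (i in 2:(n - 1)) {
    if (!is.na(x[i - 1]) && !is.na(x[i]) && !is.na(x[i + 1]))
      s[i] <- (abs(x[i] - x[i - 1]) + abs(x[i + 1] - x[i])) / 2
  }
  s
}

ref_percentile_filter <- function(x, p = 90) {
  s <- ref_neighbor_scores(x)
  sv <- s[!is.na(s)]
  if (length(sv) < 2) return(x)
  thr <- stats::quantile(sv, p / 100, names = FALSE)
  for (i in seq_along(x)) {
    if (!is.na(s[i]) && s[i] > thr) x[i] <- NA_real_
  }
  x
}

ref_interpolate_gaps <- function(x, max_gap = 8) {
  n <- length(x)
  i <- 1
  while (i <= n) {
    if (is.na(x[i])) {
      j <- i
      while (j <= n && is.na(x[j])) j <- j + 1
      gap_len <- j - i
      if (i > 1 && j <= n && gap_len <= max_gap) {
        left <- x[i - 1]; right <- x[j]
        for (k in seq_len(gap_len))
          x[i + k - 1] <- left + (right - left) * k / (gap_len + 1)
      }
      i <- j
    } else i <- i + 1
  }
  x
}

ref_mad_exclude <- function(x, k = 3) {
  v <- x[!is.na(x)]
  if (length(v) < 2) return(x)
  med <- stats::median(v)
  mad_val <- stats::median(abs(v - med))
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && abs(x[i] - med) > k * mad_val) x[i] <- NA_real_
  }
  x
}

ref_combine_eyes <- function(l, r) {
  out <- rep(NA_real_, length(l))
  for (i in seq_along(l)) {
    if (!is.na(l[i]) && !is.na(r[i])) out[i] <- (l[i] + r[i]) / 2
    else if (!is.na(l[i])) out[i] <- l[i]
    else if (!is.na(r[i])) out[i] <- r[i]
  }
  out
}

# Straight-line reference of the whole per-trial cascade, operating on
# grid-aligned left/right pupil vectors (no gaze, validity all TRUE).
ref_cascade <- function(pl, pr, timeline, params = filter_params()) {
  pl[!is.na(pl) & pl < 0] <- NA_real_
  pr[!is.na(pr) & pr < 0] <- NA_real_
  pl <- ref_interpolate_gaps(ref_percentile_filter(pl, params$percentile_cutoff),
                             params$max_gap_samples)
  pr <- ref_interpolate_gaps(ref_percentile_filter(pr, params$percentile_cutoff),
                             params$max_gap_samples)
  both <- ref_combine_eyes(pl, pr)
  both <- ref_interpolate_gaps(ref_percentile_filter(both, params$percentile_cutoff),
                               params$max_gap_samples)
  t_grid <- (seq_along(both) - 1) * timeline$step_ms
  bw <- timeline$baseline_window_ms
  base <- both[t_grid >= bw[1] & t_grid < bw[2]]
  base <- base[!is.na(base)]
  ow <- timeline$outcome_window_ms
  out_idx <- which(t_grid >= ow[1] & t_grid < ow[2])
  if (length(base) == 0 || mean(base) <= 0)
    return(rep(NA_real_, length(out_idx)))
  b <- mean(base)
  rel <- (both[out_idx] - b) / b
  ref_mad_exclude(rel, params$mad_k)
}

# Independent JZS oracle: marginal likelihood of t under a noncentral-t
# with the Cauchy prior on the standardized effect, integrated over delta
# (a different formulation than the package's g-prior integral).
jzs_oracle <- function(t, n1, n2 = NULL, r = sqrt(2) / 2) {
  if (is.null(n2)) { N <- n1; df <- n1 - 1 }
  else { N <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2 }
  num <- stats::integrate(function(d)
    suppressWarnings(stats::dt(t, df, ncp = d * sqrt(N))) *
      stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-10)$value
  num / stats::dt(t, df)
}

# Brute-force run-length scan for evidence windows.
ref_windows <- function(bf, t_ms, direction, threshold = 3) {
  step <- stats::median(diff(t_ms))
  out <- NULL
  i <- 1; n <- length(bf)
  while (i <= n) {
    if (!is.na(bf[i]) && bf[i] >= threshold && !is.na(direction[i])) {
      j <- i
      while (j + 1 <= n && !is.na(bf[j + 1]) && bf[j + 1] >= threshold &&
             !is.na(direction[j + 1]) && direction[j + 1] == direction[i])
        j <- j + 1
      out <- rbind(out, data.frame(start_ms = t_ms[i], end_ms = t_ms[j] + step,
                                   direction = direction[i],
                                   max_bf10 = max(bf[i:j]),
                                   n_points = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      direction = numeric(0), max_bf10 = numeric(0),
                      n_points = integer(0))
  out
}

# Small timeline for fast cascade tests: 1 s trial at 120 Hz, 60-slot
# outcome grid.
mini_timeline <- function() {
  trial_timeline(trial_duration_ms = 1000,
                 anticipation_window_ms = c(200, 500),
                 baseline_window_ms = c(300, 500),
                 reveal_window_ms = c(500, 500 + 1),
                 outcome_window_ms = c(500, 1000),
                 sampling_hz = 120)
}

# Random pupil trace with planted artifacts and missing runs.
random_trace <- function(n, base = 4, noise = 0.02,
                         p_spike = 0.05, p_gap = 0.1, max_gap_len = 12) {
  x <- base + stats::rnorm(n, 0, noise)
  spikes <- which(stats::runif(n) < p_spike)
  x[spikes] <- x[spikes] + sample(c(-1, 1), length(spikes), TRUE) *
    stats::runif(length(spikes), 0.3, 1)
  i <- 1
  while (i <= n) {
    if (stats::runif(1) < p_gap) {
      len <- sample(seq_len(max_gap_len), 1)
      x[i:min(n, i + len - 1)] <- NA_real_
      i <- i + len
    }
    i <- i + 1
  }
  x
}

# Build a minimal in-memory trial from grid-aligned eye vectors.
make_trial <- function(pl, pr, timeline, meta = NULL,
                       gaze_x = NULL, gaze_y = NULL) {
  n <- timeline$n_trial_slots
  stopifnot(length(pl) == n, length(pr) == n)
  if (is.null(meta))
    meta <- data.frame(subject_id = "s001", age_group = "9mo",
                       block = "ObjectMemory", belief = "FB",
                       outcome = "congruent", congruent_side = "left",
                       trial_index = 1, stringsAsFactors = FALSE)
  if (is.null(gaze_x)) gaze_x <- rep(640, n)
  if (is.null(gaze_y)) gaze_y <- rep(512, n)
  samples <- data.frame(t_ms = (seq_len(n) - 1) * timeline$step_ms,
                        pupil_left_mm = pl, pupil_right_mm = pr,
                        valid_left = TRUE, valid_right = TRUE,
                        gaze_x_px = gaze_x, gaze_y_px = gaze_y)
  structure(list(meta = meta, samples = samples, timeline = timeline,
                 screen = screen_geometry()),
            class = "pupil_trial")
}
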