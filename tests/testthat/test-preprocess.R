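test_that("remove_invalid handles negative pupils and off-screen gaze", {
  s <- data.frame(pupil_left_mm = c(-1, 3, 3), pupil_right_mm = c(3.2, 3.2, 3.2),
                  gaze_x_px = c(600, -5, 600), gaze_y_px = c(500, 300, 500))
  out <- remove_invalid(s, screen_geometry())
  expect_true(is.na(out$pupil_left_mm[1]))
  expect_equal(out$pupil_right_mm[1], 3.2)          # other eye untouched
  expect_true(is.na(out$pupil_left_mm[2]) && is.na(out$pupil_right_mm[2]))
  expect_equal(out[3, ], s[3, ], ignore_attr = TRUE) # valid row unchanged
})

test_that("neighbour-difference scores follow the hand-computed definition", {
  expect_equal(neighbor_diff_scores(c(1, 2, 4)), c(NA, 1.5, NA))
  expect_equal(neighbor_diff_scores(rep(5, 10))[2:9], rep(0, 8))
  x <- c(1, 2, NA, 4, 5)
  expect_true(all(is.na(neighbor_diff_scores(x)[2:4])))
  expect_true(all(is.na(neighbor_diff_scores(c(1, 2)))))
})

test_that("percentile filter removes spikes, spares constants, caps removals", {
  set.seed(3)
  x <- 4 + rnorm(20, 0, 0.01)
  x[10] <- x[10] + 1                     # spike 100x noise
  out <- percentile_filter(x, 90)
  expect_true(is.na(out[10]))
  expect_lt(sum(is.na(out)), 4)
  expect_equal(percentile_filter(rep(2, 30)), rep(2, 30))  # strict inequality
  # removal count bounded by the percentile definition (plus ties)
  for (i in 1:20) {
    y <- random_trace(50)
    filtered <- percentile_filter(y, 90)
    n_scored <- sum(!is.na(neighbor_diff_scores(y)))
    expect_lte(sum(is.na(filtered)) - sum(is.na(y)), ceiling(0.10 * n_scored) + 1)
  }
})

test_that("gap interpolation fills runs of at most eight samples", {
  x <- c(1, rep(NA, 8), 10)
  expect_equal(interpolate_gaps(x), 1:10)
  y <- c(1, rep(NA, 9), 11)
  expect_equal(interpolate_gaps(y), y)              # 9-gap left missing
  lead <- c(NA, NA, 3, 4)
  expect_equal(interpolate_gaps(lead), lead)        # no left anchor
  trail <- c(3, 4, NA)
  expect_equal(interpolate_gaps(trail), trail)
})

test_that("binocular combination averages, falls back, propagates missing", {
  expect_equal(combine_eyes(3.0, 3.2), 3.1)
  expect_equal(combine_eyes(c(3, NA, NA), c(NA, 3.2, NA)), c(3, 3.2, NA))
  expect_error(combine_eyes(1:3, 1:4), "grid mismatch")
})

test_that("baseline correction yields percent change and flags degenerate baselines", {
  tl <- mini_timeline()
  x <- rep(4, tl$n_trial_slots)
  bc <- baseline_correct(x, tl)
  expect_equal(bc$rel_change, rep(0, tl$n_outcome_slots))
  expect_equal(bc$baseline_mm, 4)
  x2 <- x
  x2[seq_len(tl$n_trial_slots) > 60] <- 4.2          # outcome slots at 4.2
  bc2 <- baseline_correct(x2, tl)
  expect_equal(unique(bc2$rel_change), 0.05)         # (4.2 - 4) / 4
  x3 <- x
  t_grid <- (seq_along(x3) - 1) * tl$step_ms
  x3[t_grid >= 300 & t_grid < 500] <- NA             # empty baseline window
  bc3 <- baseline_correct(x3, tl)
  expect_true(is.na(bc3$baseline_mm))
  expect_true(all(is.na(bc3$rel_change)))
  # scale invariance: percent change is unitless
  set.seed(5)
  x4 <- 4 + rnorm(tl$n_trial_slots, 0, 0.05)
  expect_equal(baseline_correct(x4 * 7.3, tl)$rel_change,
               baseline_correct(x4, tl)$rel_change, tolerance = 1e-12)
})

test_that("MAD exclusion is unscaled, strict, and single-pass", {
  expect_equal(mad_exclude(c(0, 0, 0, 0, 1)), c(0, 0, 0, 0, NA))
  set.seed(9)
  x <- rnorm(100, 0, 0.01)
  x_clipped <- pmin(pmax(x, -0.015), 0.015)          # nothing beyond 3 MAD
  expect_equal(mad_exclude(x_clipped), x_clipped)
  # single pass is not idempotent in general: a second pass may remove more
  y <- c(rep(0, 10), 0.5, 1:5)
  once <- mad_exclude(y)
  twice <- mad_exclude(once)
  expect_gte(sum(is.na(twice)), sum(is.na(once)))
})

test_that("trial inclusion keeps the exact 10% boundary", {
  expect_true(include_trial(60, 600, 0.10))
  expect_false(include_trial(59, 600, 0.10))
  expect_true(include_trial(600, 600, 0.50))
})

test_that("subject inclusion requires one trial per relevant condition cell", {
  incl <- data.frame(
    subject_id = c("a", "a", "b", "b", "c"),
    belief = c("FB", "FB", "FB", "FB", "TB"),
    outcome = c("congruent", "incongruent", "congruent", "congruent", "congruent"),
    included = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cells <- list(c(belief = "FB", outcome = "congruent"),
                c(belief = "FB", outcome = "incongruent"))
  rep <- include_subject(incl, cells)
  expect_true(rep$included[rep$subject_id == "a"])
  expect_false(rep$included[rep$subject_id == "b"])   # FB-incongruent absent
  expect_false(rep$included[rep$subject_id == "c"])   # no included trial at all
})

test_that("operators match brute-force references on random traces", {
  set.seed(101)
  for (i in 1:60) {
    x <- random_trace(sample(10:50, 1))
    expect_equal(neighbor_diff_scores(x), ref_neighbor_scores(x))
    expect_equal(percentile_filter(x, 90), ref_percentile_filter(x, 90))
    expect_equal(interpolate_gaps(x, 8), ref_interpolate_gaps(x, 8))
    expect_equal(mad_exclude(x, 3), ref_mad_exclude(x, 3))
  }
})

test_that("all operators except interpolation are missingness-monotone", {
  set.seed(77)
  for (i in 1:25) {
    x <- random_trace(40)
    na_in <- is.na(x)
    expect_true(all(is.na(percentile_filter(x, 90))[na_in]))
    expect_true(all(is.na(mad_exclude(x, 3))[na_in]))
    l <- random_trace(40); r <- random_trace(40)
    expect_true(all(is.na(combine_eyes(l, r))[is.na(l) & is.na(r)]))
    # interpolation is the only value-creating operator
    filled <- interpolate_gaps(x, 8)
    expect_true(all(!is.na(filled[!na_in])))
  }
})

test_that("the full cascade matches the straight-line reference", {
  tl <- mini_timeline()
  set.seed(202)
  for (i in 1:25) {
    pl <- random_trace(tl$n_trial_slots)
    pr <- random_trace(tl$n_trial_slots)
    trial <- make_trial(pl, pr, tl)
    got <- preprocess_trial(trial)
    expect_equal(got$rel_change, ref_cascade(pl, pr, tl), tolerance = 1e-12)
  }
})

test_that("a noise-free planted dilation is recovered exactly up to MAD exclusion", {
  cfg <- synthetic_config(noise_sd = 0, blink_rate_per_s = 0, missing_rate = 0,
                          effect_map = list("ObjectMemory:FB:congruent" =
                            list(amplitude = 0.02, onset_ms = 2200,
                                 offset_ms = 2900)))
  meta <- data.frame(subject_id = "s001", age_group = "9mo",
                     block = "ObjectMemory", belief = "FB",
                     outcome = "congruent", congruent_side = "left",
                     trial_index = 1)
  trial <- generate_trial(4, meta, cfg, seed = 1)
  g <- snap_to_grid(trial$samples, trial$timeline)
  both <- combine_eyes(interpolate_gaps(percentile_filter(g$pupil_left)),
                       interpolate_gaps(percentile_filter(g$pupil_right)))
  both <- interpolate_gaps(percentile_filter(both))
  bc <- baseline_correct(both, trial$timeline)
  on_effect <- bc$grid_t_ms >= 2200 + 50 & bc$grid_t_ms < 2900 - 50
  expect_equal(unique(round(bc$rel_change[on_effect], 10)), 0.02)
  # degenerate MAD on a noise-free trace: MAD = 0, so the strict rule removes
  # every point that differs from the (null) median, i.e. the plateau itself
  trace <- preprocess_trial(trial)
  expect_true(all(is.na(trace$rel_change[on_effect])))
  expect_true(trace$report$included)   # the null majority still counts as valid
})

test_that("an all-missing trial is excluded for low coverage", {
  tl <- mini_timeline()
  trial <- make_trial(rep(NA_real_, tl$n_trial_slots),
                      rep(NA_real_, tl$n_trial_slots), tl)
  trace <- preprocess_trial(trial)
  expect_false(trace$report$included)
  expect_true(trace$report$reason %in% c("no_baseline", "low_outcome_coverage"))
})

test_that("multiverse runner produces one row per variant and tolerates failures", {
  cfg <- synthetic_preset("paper_like_9mo", n_subjects = 6, seed = 3)
  cfg$blocks <- "ObjectMemory"
  trials <- generate_experiment(cfg)$trials
  grid <- expand.grid(percentile_cutoff = c(90, 95),
                      min_outcome_fraction = c(0.10, 0.50))
  res <- multiverse_run(trials, grid, method = "jzs")
  expect_equal(nrow(res), 4L)
  expect_true(all(is.na(res$error)))
  expect_error(multiverse_run(trials, grid[0, , drop = FALSE]), "empty")
})
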