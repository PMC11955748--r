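# scripted noise-free scanpath on the 120 Hz grid
scanpath <- function(segments, hz = 120, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(vapply(segments, function(s) s$window[2],
                                          numeric(1)))
  t_ms <- seq(0, t_end - 1, by = 1000 / hz)
  gx <- gy <- rep(NA_real_, length(t_ms))
  for (s in segments) {
    idx <- t_ms >= s$window[1] & t_ms < s$window[2]
    gx[idx] <- s$x; gy[idx] <- s$y
  }
  list(gx = gx, gy = gy, t_ms = t_ms)
}

test_that("a static gaze yields exactly one fixation at its location", {
  sp <- scanpath(list(list(window = c(0, 500), x = 640, y = 512)))
  fx <- detect_fixations(sp$gx, sp$gy, sp$t_ms)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$x, 640)
  expect_equal(fx$y, 512)
  expect_gte(fx$duration_ms, 400)
})

test_that("well-separated dwells are recovered in count and order", {
  sp <- scanpath(list(list(window = c(0, 500), x = 300, y = 500),
                      list(window = c(500, 525), x = 450, y = 500),
                      list(window = c(525, 1000), x = 600, y = 500)))
  fx <- detect_fixations(sp$gx, sp$gy, sp$t_ms)
  expect_equal(nrow(fx), 2L)
  expect_lt(abs(fx$x[1] - 300), 25)
  expect_lt(abs(fx$x[2] - 600), 25)
  expect_true(fx$start_ms[1] < fx$start_ms[2])
})

test_that("dwells closer than the distance threshold merge into one fixation", {
  sp <- scanpath(list(list(window = c(0, 500), x = 500, y = 500),
                      list(window = c(500, 1000), x = 520, y = 500)))
  fx <- detect_fixations(sp$gx, sp$gy, sp$t_ms)
  expect_equal(nrow(fx), 1L)
  expect_lt(abs(fx$x - 510), 15)
})

test_that("all-missing gaze gives an empty fixation list", {
  fx <- detect_fixations(rep(NA_real_, 100), rep(NA_real_, 100),
                         seq(0, by = 1000 / 120, length.out = 100))
  expect_equal(nrow(fx), 0L)
})

test_that("differential looking scores match constructed dwell plans", {
  aois <- aoi_set("left")
  c_xy <- c(340, 720); i_xy <- c(940, 720)
  # all 2000 ms on the congruent AOI
  full <- data.frame(start_ms = 15000, end_ms = 17000,
                     x = c_xy[1], y = c_xy[2], duration_ms = 2000)
  sc <- anticipatory_scores(full, aois)
  expect_equal(sc$dls, 1)
  expect_equal(sc$first_gaze, "congruent")
  # 600 ms congruent, 400 ms incongruent -> (600 - 400) / 1000
  mix <- data.frame(start_ms = c(15000, 15700),
                    end_ms = c(15600, 16100),
                    x = c(c_xy[1], i_xy[1]), y = c(c_xy[2], i_xy[2]),
                    duration_ms = c(600, 400))
  sc2 <- anticipatory_scores(mix, aois)
  expect_equal(sc2$dls, 0.2)
  expect_equal(sc2$t_congruent_ms, 600)
  expect_equal(sc2$t_incongruent_ms, 400)
  # outside both AOIs
  off <- data.frame(start_ms = 15000, end_ms = 16000, x = 640, y = 100,
                    duration_ms = 1000)
  sc3 <- anticipatory_scores(off, aois)
  expect_true(is.na(sc3$dls))
  expect_equal(sc3$first_gaze, "none")
})

test_that("looking times never exceed the window and label swap negates DLS", {
  set.seed(21)
  for (i in 1:20) {
    n_fix <- sample(1:6, 1)
    fx <- data.frame(start_ms = sort(runif(n_fix, 14000, 17500)))
    fx$end_ms <- fx$start_ms + runif(n_fix, 50, 800)
    fx$x <- runif(n_fix, 0, 1280); fx$y <- runif(n_fix, 0, 1024)
    fx$duration_ms <- fx$end_ms - fx$start_ms
    left <- anticipatory_scores(fx, aoi_set("left"))
    right <- anticipatory_scores(fx, aoi_set("right"))
    expect_lte(left$t_congruent_ms + left$t_incongruent_ms, 2000)
    if (!is.na(left$dls)) {
      expect_true(left$dls >= -1 && left$dls <= 1)
      expect_equal(left$dls, -right$dls)
    }
  }
})

test_that("Cohen's kappa matches the contingency-table closed form", {
  expect_equal(cohen_kappa(c("x", "y", "x"), c("x", "y", "x")), 1)
  # a = (1,1,0,0), b = (1,0,1,0): p_o = 0.5, p_e = 0.5 -> kappa = 0
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  # hand-computed asymmetric 2x2: a=(1,1,1,0), b=(1,1,0,0)
  # p_o = 3/4, p_e = (3*2 + 1*2)/16 = 1/2 -> kappa = 1/2
  expect_equal(cohen_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.5)
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5)), 1)  # p_e = 1 edge
  set.seed(31)
  a <- sample(0:1, 1e4, TRUE); b <- sample(0:1, 1e4, TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)   # independent raters -> ~0
  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})

test_that("trial-level scoring resolves AOIs by congruent side", {
  cfg <- synthetic_config(n_subjects = 2, blocks = "ObjectMemory",
                          noise_sd = 0.005, blink_rate_per_s = 0,
                          missing_rate = 0, seed = 5)
  trials <- generate_experiment(cfg)$trials
  scores <- score_anticipatory_looking(trials)
  # the default gaze script dwells on the congruent location all anticipation
  expect_true(all(scores$dls == 1))
  expect_true(all(scores$first_gaze == "congruent"))
  agg <- aggregate_first_gaze(scores)
  expect_equal(agg$k, agg$n)
})
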