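test_that("JZS t Bayes factor agrees with the noncentral-t quadrature oracle", {
  for (t in c(0, 0.5, 1, 2, 2.5, 3, 4)) {
    for (n in c(5, 10, 20, 30, 50, 100)) {
      expect_equal(jzs_bf_from_t(t, n)$bf10, jzs_oracle(t, n),
                   tolerance = 1e-6, label = sprintf("t=%g n=%d", t, n))
    }
    expect_equal(jzs_bf_from_t(t, 15, 18)$bf10, jzs_oracle(t, 15, 18),
                 tolerance = 1e-6)
  }
})

test_that("JZS BF favours the null at t = 0 and increases in |t|", {
  expect_lt(jzs_bf_from_t(0, 20)$bf10, 1)
  grid <- seq(0, 5, by = 0.5)
  bfs <- vapply(grid, function(t) jzs_bf_from_t(t, 25)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("jzs_ttest_bf handles one-sample, paired, two-sample and degenerate input", {
  set.seed(41)
  x <- rnorm(30, 0.8); y <- rnorm(30)
  one <- jzs_ttest_bf(x)
  expect_equal(one$bf10, exp(one$log_bf10))
  t_ref <- unname(t.test(x)$statistic)
  expect_equal(one$t, t_ref, tolerance = 1e-12)
  paired <- jzs_ttest_bf(x, y, paired = TRUE)
  expect_equal(paired$bf10, jzs_ttest_bf(x - y)$bf10, tolerance = 1e-12)
  two <- jzs_ttest_bf(x, y)
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)
  expect_equal(two$t, t2, tolerance = 1e-12)
  # label swap flips t but not the two-sided BF
  expect_equal(jzs_ttest_bf(y, x)$bf10, two$bf10, tolerance = 1e-10)
  expect_error(jzs_ttest_bf(rep(1, 10)), "zero variance")
})

test_that("BIC mixed-model BF matches lme4 and detects planted effects", {
  set.seed(51)
  max_gap <- 0
  for (i in 1:10) {
    ns <- sample(8:20, 1)
    subj <- rep(seq_len(ns), each = 2)
    cond <- rep(c("a", "b"), ns)
    y <- 0.4 * (cond == "a") + rnorm(ns, sd = 0.8)[subj] + rnorm(2 * ns)
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
    f1 <- lme4::lmer(y ~ cond + (1 | subj), REML = FALSE, control = ctrl)
    f0 <- lme4::lmer(y ~ 1 + (1 | subj), REML = FALSE, control = ctrl)
    ref <- exp((BIC(f0) - BIC(f1)) / 2)
    got <- bic_lmm_bf(y, cond, subj)
    expect_equal(got$bf10, ref, tolerance = 1e-6)
    max_gap <- max(max_gap, abs(log(got$bf10 / ref)))
  }
  expect_lt(max_gap, 1e-6)
  expect_error(bic_lmm_bf(rnorm(4), c("a", "b", "a", "b"), c(1, 1, 1, 1)),
               "subjects")
})

test_that("mixed-model BF favours null under permutation and effect when planted", {
  set.seed(61)
  null_bfs <- effect_bfs <- numeric(40)
  for (i in 1:40) {
    ns <- 30
    subj <- rep(seq_len(ns), each = 2)
    u <- rnorm(ns)
    cond <- rep(c("a", "b"), ns)
    null_bfs[i] <- bic_lmm_bf(u[subj] + rnorm(2 * ns), sample(cond), subj)$bf10
    y <- (cond == "a") * 1.0 + u[subj] + rnorm(2 * ns)  # 1 within-subject SD
    effect_bfs[i] <- bic_lmm_bf(y, cond, subj)$bf10
  }
  expect_lt(median(null_bfs), 1)
  # the BIC (unit-information) approximation is conservative: a 1-SD fixed
  # effect at 30 subjects clears BF 3 in most but not quite all runs
  expect_gte(mean(effect_bfs > 3), 0.8)
  expect_gt(median(effect_bfs), 10)
})

test_that("interaction BF separates additive from crossover generative models", {
  set.seed(71)
  add_bfs <- cross_bfs <- numeric(30)
  for (i in 1:30) {
    ns <- 30
    subj <- rep(seq_len(ns), each = 4)
    o <- rep(c("cong", "incong"), 2 * ns)
    b <- rep(rep(c("TB", "FB"), each = 2), ns)
    u <- rnorm(ns)[subj]
    add <- 0.5 * (o == "cong") + 0.3 * (b == "FB") + u + rnorm(4 * ns)
    add_bfs[i] <- interaction_bf(add, o, b, subj)$bf10
    crossover <- ifelse(b == "FB", 0.5, -0.5) * ((o == "cong") - 0.5) * 2 +
      u + rnorm(4 * ns)
    cross_bfs[i] <- interaction_bf(crossover, o, b, subj)$bf10
  }
  expect_lt(median(add_bfs), 1)
  expect_gte(mean(cross_bfs > 3), 0.9)
  # relabeling belief levels leaves the interaction BF unchanged
  set.seed(72)
  ns <- 20; subj <- rep(seq_len(ns), each = 4)
  o <- rep(c("cong", "incong"), 2 * ns)
  b <- rep(rep(c("TB", "FB"), each = 2), ns)
  y <- rnorm(4 * ns)
  b_swapped <- ifelse(b == "TB", "FB", "TB")
  expect_equal(interaction_bf(y, o, b, subj)$bf10,
               interaction_bf(y, o, b_swapped, subj)$bf10, tolerance = 1e-8)
  expect_error(interaction_bf(y[o == "cong"], o[o == "cong"],
                              b[o == "cong"], subj[o == "cong"]),
               "empty cell")
})

test_that("signed-rank statistic is exact and its BF tracks the effect", {
  # hand computation: |x| ranks of (1, -2, 3, 0.5, -0.1) are (3, 4, 5, 2, 1);
  # the positive entries carry ranks 3, 5, 2 -> W = 10
  x0 <- c(1, -2, 3, 0.5, -0.1)
  expect_equal(signed_rank_bf(x0)$W, 10)
  expect_equal(signed_rank_bf(x0)$W,
               unname(suppressWarnings(wilcox.test(x0)$statistic)))
  x <- c(0.2, 0.5, 1.1, 2.0, 0.7)
  expect_equal(signed_rank_bf(x)$W, 5 * 6 / 2)        # all positive: maximal
  wref <- unname(suppressWarnings(wilcox.test(x)$statistic))
  expect_equal(signed_rank_bf(x)$W, wref)
  set.seed(81)
  sym <- rnorm(200)
  sr <- signed_rank_bf(sym)
  expect_lt(abs(sr$W - 200 * 201 / 4) / (200 * 201 / 4), 0.15)
  expect_lt(sr$bf10, 1)
  shifted <- rnorm(50, 0.8)
  expect_gt(signed_rank_bf(shifted)$bf10, 3)
  expect_error(signed_rank_bf(rep(0, 10)), "zero")
  expect_error(signed_rank_bf(c(1, 2, -1)), "at least 5")
})

test_that("binomial BF equals its Beta-function closed form", {
  expect_equal(binomial_bf(1, 1)$bf10, 1)
  expect_equal(binomial_bf(10, 10)$bf10, 2^10 / 11, tolerance = 1e-12)
  expect_equal(binomial_bf(3, 12, p0 = 0.25)$bf10,
               beta(4, 10) / (0.25^3 * 0.75^9), tolerance = 1e-12)
  for (n in c(10, 40, 100))
    expect_lt(binomial_bf(n / 2, n)$bf10, 1)
  expect_error(binomial_bf(5, 3), "between 0 and n")
})

test_that("evidence classification reproduces the category scheme with reciprocity", {
  expect_equal(classify_bf(15.74), "strong_for")
  expect_equal(classify_bf(4.54), "moderate_for")
  expect_equal(classify_bf(1), "anecdotal_for")
  expect_equal(classify_bf(0.14), "moderate_against")
  expect_equal(classify_bf(44.18), "very_strong_for")
  expect_equal(classify_bf(291.21), "extreme_for")
  expect_equal(classify_bf(0.02), "very_strong_against")
  # reciprocal symmetry: classify(1/b) mirrors classify(b)
  for (b in c(1.5, 3.5, 12, 40, 200)) {
    lab <- strsplit(classify_bf(b), "_(?=for)", perl = TRUE)[[1]]
    rec <- strsplit(classify_bf(1 / b), "_(?=against)", perl = TRUE)[[1]]
    expect_equal(lab[1], rec[1])
  }
  expect_error(classify_bf(-1), "positive")
})
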