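#' Specification of a Bayesian sequential sampling design
#'
#' Data collection continues until the Bayes factor crosses an upper or
#' lower evidence threshold, after a minimum sample size, up to a maximum.
#' Defaults follow the common design: minimum 25 participants per group,
#' symmetric thresholds at 3 and 1/3, a look after every added participant.
#'
#' @param min_n_per_group Minimum sample size before the first look.
#' @param max_n Maximum sample size (forced stop).
#' @param bf_upper Upper stopping threshold (evidence for the effect).
#' @param bf_lower Lower stopping threshold; must equal `1 / bf_upper`.
#' @param step Participants added between looks.
#' @param effect_size True standardized effect size of the generative model
#'   (subject scores drawn from `N(effect_size, 1)`).
#' @return A list of class `sequential_spec`.
#' @export
sequential_spec <- function(min_n_per_group = 25, max_n = 100,
                            bf_upper = 3, bf_lower = 1 / bf_upper,
                            step = 1, effect_size = 0) {
  if (max_n < min_n_per_group)
    stop("max_n must be at least min_n_per_group")
  if (abs(bf_lower - 1 / bf_upper) > 1e-12)
    stop("bf_lower must equal 1 / bf_upper")
  if (step < 1) stop("step must be at least 1")
  structure(list(min_n_per_group = as.integer(min_n_per_group),
                 max_n = as.integer(max_n), bf_upper = bf_upper,
                 bf_lower = bf_lower, step = as.integer(step),
                 effect_size = effect_size),
            class = "sequential_spec")
}

#' Simulate a Bayesian sequential design
#'
#' For each replicate, draws subject-level scores from the generative model
#' `N(effect_size, 1)`, recomputes the Bayes factor at every look from the
#' minimum sample size onward, and records the first threshold crossing
#' (`support_h1` at `bf >= bf_upper`, `support_h0` at `bf <= bf_lower`) or
#' `max_n_reached`. With the default one-sample JZS test the cumulative
#' t statistics are computed incrementally, so 500-replicate runs are cheap.
#'
#' @param spec A [sequential_spec()].
#' @param n_replicates Number of simulated experiments.
#' @param bf_method Either `NULL` (default one-sample JZS t test on the
#'   scores) or a function `f(x) -> bf10` applied to the accumulated sample
#'   at each look.
#' @param seed Integer seed; identical spec + seed reproduce the replicate
#'   table exactly.
#' @return A list of class `sequential_sim`: `replicates` (data frame
#'   `replicate`, `stop_n`, `decision`, `bf_final`), `summary` (decision
#'   proportions and stopping-N quantiles), `spec`, `seed`.
#' @export
simulate_sequential <- function(spec, n_replicates = 500, bf_method = NULL,
                                seed = 1) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  set.seed(seed)
  looks <- seq(spec$min_n_per_group, spec$max_n, by = spec$step)
  if (looks[length(looks)] != spec$max_n) looks <- c(looks, spec$max_n)
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    x <- stats::rnorm(spec$max_n, mean = spec$effect_size, sd = 1)
    stop_n <- spec$max_n
    decision <- "max_n_reached"
    bf_final <- NA_real_
    if (is.null(bf_method)) {
      cs <- cumsum(x); cs2 <- cumsum(x^2)
      for (n in looks) {
        m <- cs[n] / n
        v <- (cs2[n] - n * m^2) / (n - 1)
        if (v <= 0) next
        t_stat <- m / sqrt(v / n)
        bf <- jzs_bf_from_t(t_stat, n)$bf10
        bf_final <- bf
        if (bf >= spec$bf_upper) { stop_n <- n; decision <- "support_h1"; break }
        if (bf <= spec$bf_lower) { stop_n <- n; decision <- "support_h0"; break }
      }
    } else {
      for (n in looks) {
        bf <- bf_method(x[seq_len(n)])
        bf_final <- bf
        if (bf >= spec$bf_upper) { stop_n <- n; decision <- "support_h1"; break }
        if (bf <= spec$bf_lower) { stop_n <- n; decision <- "support_h0"; break }
      }
    }
    rows[[rep_i]] <- data.frame(replicate = rep_i, stop_n = stop_n,
                                decision = decision, bf_final = bf_final,
                                stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, rows)
  decisions <- c("support_h1", "support_h0", "max_n_reached")
  props <- vapply(decisions, function(d) mean(replicates$decision == d),
                  numeric(1))
  summary <- list(
    proportions = props,
    stop_n_quantiles = stats::quantile(replicates$stop_n,
                                       c(0.25, 0.5, 0.75, 0.9)),
    median_stop_n = stats::median(replicates$stop_n))
  structure(list(replicates = replicates, summary = summary, spec = spec,
                 seed = seed),
            class = "sequential_sim")
}

#' @export
print.sequential_sim <- function(x, ...) {
  cat("Sequential design simulation (", nrow(x$replicates), " replicates, ",
      "effect size ", x$spec$effect_size, ")\n", sep = "")
  print(round(x$summary$proportions, 3))
  cat("median stopping N:", x$summary$median_stop_n, "\n")
  invisible(x)
}
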