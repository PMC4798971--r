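test_that("log-odds map is antisymmetric, monotone in the balance, and 0 at 0", {
  m <- s1_map()
  tt <- c(0.1, 0.5, 1, 2)
  expect_equal(log_odds(m, tt, 0), rep(0, 4))
  d <- seq(-3, 3, by = 0.1)
  for (t1 in tt) {
    lo <- log_odds(m, t1, d)
    expect_true(all(diff(lo) > 0))                       # strictly increasing
    expect_equal(lo, -rev(log_odds(m, t1, rev(-d))))     # antisymmetry
  }
})

test_that("degenerate coherence sets give the expected limiting beliefs", {
  p <- s1_params()
  # only 0% coherence: the stimulus carries no information
  m0 <- build_belief_map(p, coherences = c(0, 0), tabulate = FALSE)
  expect_equal(log_odds(m0, c(0.2, 1), c(1.5, -2)), c(0, 0))
  # a single strong pair, large balance at short elapsed time: near-certain
  m1 <- build_belief_map(p, coherences = c(-0.512, 0.512), tabulate = FALSE)
  expect_gt(log_odds(m1, 0.05, 2), 5)
})

test_that("map inversion returns the balance at the target log-odds", {
  m <- s1_map()
  t <- c(0.05, 0.3, 1.2, 4)
  for (lo in c(-1, 0, 0.5, 2)) {
    d <- invert_log_odds(m, t, lo)
    expect_equal(log_odds(m, t, d), rep(lo, length(t)), tolerance = 1e-8)
  }
})

test_that("log-odds convert to the printed probability thresholds", {
  expect_equal(round(probability_equivalent(0.89), 2), 0.71)
  expect_equal(round(probability_equivalent(1.26), 2), 0.78)
  expect_equal(probability_equivalent(0), 0.5)
})

test_that("payoff indifference gives the optimal criterion", {
  expect_equal(round(optimal_criterion(), 2), 0.69)
  expect_equal(probability_equivalent(optimal_criterion()), 2 / 3)
  # symmetric-magnitude high-risk payoffs push the indifference to 1/2
  expect_equal(optimal_criterion(rbind(high = c(3, -3), low = c(1, -1))), 0)
  expect_error(optimal_criterion(rbind(high = c(1, -1), low = c(1, -1))),
               "degenerate")
})

test_that("initial predictions are coherent probabilities with RT structure", {
  p <- s1_params(); m <- s1_map(); crit <- s1_crit()
  tg <- coarse_tgrid()
  prev_ph_err <- -1
  for (co in c(0, 0.032, 0.064, 0.256)) {
    ip <- initial_outcome_probs(p, crit, m, co, tg)
    expect_equal(sum(ip$probs), 1, tolerance = 1e-6)
    expect_equal(ip$mean_rt, ip$mean_dt + p$tnd_mean)
    pc <- ip$probs[["correct_high"]] + ip$probs[["correct_low"]]
    if (co == 0) expect_equal(pc, 0.5, tolerance = 1e-12)
    # confidence-accuracy coupling
    p_corr_high <- ip$probs[["correct_high"]] /
      (ip$probs[["correct_high"]] + ip$probs[["error_high"]])
    p_corr_low <- ip$probs[["correct_low"]] /
      (ip$probs[["correct_low"]] + ip$probs[["error_low"]])
    expect_gte(p_corr_high, p_corr_low - 1e-12)
    # errors at stronger nonzero motion are reported with high confidence
    # more often (at 0% the "error" designation is a coin flip, so that
    # point reflects the overall high rate and is not part of the trend)
    if (co > 0) {
      ph_err <- ip$probs[["error_high"]] /
        (ip$probs[["error_high"]] + ip$probs[["error_low"]])
      expect_gt(ph_err, prev_ph_err)
      prev_ph_err <- ph_err
    }
  }
})

test_that("criterion limits drive the high-confidence rate to 0 and 1", {
  p <- s1_params(); m <- s1_map()
  tg <- coarse_tgrid()
  hi <- function(theta) {
    ip <- initial_outcome_probs(p, confidence_criterion(theta), m, 0.064, tg)
    ip$probs[["correct_high"]] + ip$probs[["error_high"]]
  }
  expect_lt(hi(15), 1e-6)
  expect_gt(hi(1e-8), 1 - 1e-6)
})

test_that("high-confidence saturates on correct trials at the strongest motion", {
  ip <- initial_outcome_probs(s1_params(), s1_crit(), s1_map(), 0.512,
                              coarse_tgrid())
  expect_gt(ip$probs[["correct_high"]] /
              (ip$probs[["correct_high"]] + ip$probs[["correct_low"]]), 0.9)
})

test_that("off-design coherences are refused", {
  expect_error(initial_outcome_probs(s1_params(), s1_crit(), s1_map(), 0.1),
               "refusing")
})

test_that("alternative confidence rules implement their stated partitions", {
  p <- s1_params()
  tg <- coarse_tgrid()
  # balance threshold 0: every absorbed trial is high by construction
  a1 <- alternative_confidence_rule("balance", 0, p, 0.064, tg)
  expect_equal(a1$probs[["correct_high"]] + a1$probs[["error_high"]], 1,
               tolerance = 1e-9)
  # time threshold beyond the grid: all high
  a2 <- alternative_confidence_rule("time", 10, p, 0.064, tg)
  expect_equal(a2$probs[["correct_high"]] + a2$probs[["error_high"]], 1,
               tolerance = 1e-9)
  expect_error(alternative_confidence_rule("wiggle", 1, p, 0.064, tg))
})

test_that("the joint rule beats a time-only read-out on model-generated data", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  tg <- coarse_tgrid()
  tr <- s1_trials()
  bc <- tabulate_behavior(tr)
  mnll <- function(pred_fn) {
    tot <- 0
    for (i in seq_along(bc$per)) {
      pr <- pmax(pred_fn(bc$coherences[i]), 1e-10)
      tot <- tot - sum(bc$per[[i]]$n4 * log(pr))
    }
    tot
  }
  nll_main <- mnll(function(u)
    initial_outcome_probs(p, crit, m, u, tg)$probs)
  # give the time-only rule its best threshold on a grid
  nll_time <- min(vapply(c(0.3, 0.5, 0.7, 0.9, 1.2, 1.6), function(thr)
    mnll(function(u)
      alternative_confidence_rule("time", thr, p, u, tg)$probs),
    numeric(1)))
  expect_lt(nll_main, nll_time)
})

test_that("belief maps round-trip through the delimited grid format", {
  p <- s1_params()
  m <- build_belief_map(p, t_grid = seq(0.05, 1, by = 0.05),
                        delta_grid = seq(-2, 2, by = 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_belief_map(m, f)
  m2 <- read_belief_map(f)
  expect_equal(m2$params$kappa, p$kappa)
  expect_equal(m2$coherences, m$coherences)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$logodds, m$logodds, tolerance = 1e-10)
  expect_equal(log_odds(m2, 0.4, 0.7), log_odds(m, 0.4, 0.7))
})
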