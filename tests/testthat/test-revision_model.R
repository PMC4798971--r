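test_that("zone thresholds follow the shifted-criterion arithmetic", {
  crit <- s1_crit(); rev <- s1_rev()
  expect_equal(unname(final_zone_thresholds(crit, rev, "low")),
               c(1.66, -0.24, -0.53), tolerance = 1e-12)
  expect_equal(unname(final_zone_thresholds(crit, rev, "high")),
               c(0.12, -0.24, -0.53), tolerance = 1e-12)
  # no hysteresis: the final rule equals the initial rule
  rev0 <- revision_params(0.3)
  expect_equal(unname(final_zone_thresholds(crit, rev0, "high")),
               c(0.89, 0, -0.89))
  # non-ordered thresholds are rejected
  bad <- revision_params(0.3, d1 = 2, d2 = 0.5, d3 = 0)
  expect_error(final_zone_thresholds(crit, bad, "high"), "decreasing")
})

test_that("a zero-length, unshifted post-initiation stage changes nothing", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  ot <- outcome_table(p, crit, revision_params(0), m,
                      coherences = c(0, 0.128),
                      time_grid = coarse_tgrid())
  for (tb in ot$tables) {
    expect_equal(sum(tb$joint), 1, tolerance = 1e-6)
    expect_equal(sum(tb$joint) - sum(diag(tb$joint)), 0, tolerance = 1e-12)
    expect_equal(tb$rate_change_decision, 0)
    expect_equal(tb$rate_change_confidence, 0)
  }
})

test_that("propagation with t_pip = 0 returns the initial log-odds exactly", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  ppi <- propagate_post_initiation(p, m, 0.064, crit, 0,
                                   time_grid = coarse_tgrid())
  a <- ppi$atoms$right
  expect_equal(a$post_mean, a$delta)
  expect_equal(ppi$post_sd, 0)
})

test_that("outcome tables are proper distributions with error-revision asymmetry", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  ot <- outcome_table(p, crit, s1_rev(), m,
                      coherences = c(0.032, 0.128, 0.512),
                      time_grid = coarse_tgrid())
  for (tb in ot$tables) {
    expect_equal(sum(tb$joint), 1, tolerance = 1e-6)
    expect_true(all(tb$joint >= -1e-15))
    # drift opposes an erroneous choice: errors get revised more often
    expect_gt(tb$p_change_decision[["given_error"]],
              tb$p_change_decision[["given_correct"]])
    # confidence vacillates more than the direction decision
    expect_gt(tb$rate_change_confidence, tb$rate_change_decision)
  }
})

test_that("hysteresis suppresses changes relative to unshifted thresholds", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  tg <- coarse_tgrid()
  base <- outcome_table(p, crit, revision_params(0.395), m,
                        coherences = c(0.064), time_grid = tg)$tables[[1]]
  hyst <- outcome_table(p, crit,
                        revision_params(0.395, d1 = 0.6, d2 = 0.4), m,
                        coherences = c(0.064), time_grid = tg)$tables[[1]]
  expect_lte(hyst$rate_change_decision, base$rate_change_decision + 1e-12)
  expect_lte(hyst$rate_change_confidence,
             base$rate_change_confidence + 1e-12)
})

test_that("raising the low-to-high barrier weakly reduces low-to-high changes", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  tg <- coarse_tgrid()
  p_l2h <- vapply(c(0, 0.3, 0.6, 0.85), function(d1) {
    tb <- outcome_table(p, crit, revision_params(0.395, d1 = d1), m,
                        coherences = c(0.064), time_grid = tg)$tables[[1]]
    j <- tb$joint
    (j["correct_low", "correct_high"] + j["correct_low", "error_high"] +
       j["error_low", "correct_high"] + j["error_low", "error_high"]) /
      sum(j[c("correct_low", "error_low"), ])
  }, numeric(1))
  expect_true(all(diff(p_l2h) <= 1e-10))
})

test_that("t_pip above the mean non-decision time is rejected", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  expect_error(outcome_table(p, crit, revision_params(0.6), m,
                             coherences = 0.064), "non-decision")
})

test_that("post-initiation balance distribution matches the simulated continuation", {
  p <- s1_params(); crit <- s1_crit()
  rev <- s1_rev()
  m <- s1_map()
  co <- 0.064
  tr <- fixture("ks_trials_064",
                simulate_trials(p, crit, rev,
                                session_design(n_per = 50000,
                                               coherences = co),
                                seed = 31, map = m))
  ppi <- propagate_post_initiation(p, m, co, crit, rev$t_pip,
                                   time_grid = seq(1e-3, 5, by = 1e-3))
  for (w in c("right", "left")) {
    a <- ppi$atoms[[w]]
    wts <- a$w / sum(a$w)
    emp <- tr$delta_post[tr$init_dir == w]
    qs <- seq(-3, 4, by = 0.05)
    Fana <- vapply(qs, function(q)
      sum(wts * pnorm(q, a$post_mean, ppi$post_sd)), numeric(1))
    Femp <- ecdf(emp)(qs)
    expect_lt(max(abs(Fana - Femp)), 0.01)
  }
})

test_that("outcome tables export in tidy form", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  ot <- outcome_table(p, crit, s1_rev(), m, coherences = c(0.128),
                      time_grid = coarse_tgrid())
  df <- as.data.frame(ot)
  expect_named(df, c("coherence", "initial_cat", "final_cat",
                     "probability"))
  expect_equal(nrow(df), 16)
  expect_equal(sum(df$probability), 1, tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_outcome_table(ot, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$probability, df$probability, tolerance = 1e-12)
})
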