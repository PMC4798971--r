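test_that("fast-guess exclusion is strict at the cutoff", {
  d <- data.frame(rt = c(0.10, 0.149, 0.150, 0.80))
  expect_message(out <- exclude_trials(d), "2 trial")
  expect_equal(out$rt, c(0.150, 0.80))
  empty <- data.frame(rt = numeric(0))
  expect_identical(nrow(exclude_trials(empty)), 0L)
  slow <- data.frame(rt = c(0.2, 0.5))
  expect_equal(exclude_trials(slow)$rt, slow$rt)
  expect_equal(attr(exclude_trials(slow), "n_excluded"), 0L)
})

test_that("change detection reads areas against the 0.1 cm^2 criterion", {
  geo <- reach_geometry()
  # straight reach to the right/high target: no change on either axis
  straight <- data.frame(t = seq(0, 0.7, by = 1e-3))
  straight$x <- 8.5 * straight$t / 0.7
  straight$y <- 8.5 * straight$t / 0.7
  cl <- detect_change(straight, geo)
  expect_false(cl$change_decision || cl$change_confidence)
  expect_equal(unname(cl$final), c("right", "high"))
  expect_equal(unname(cl$initial), c("right", "high"))

  # constructed excursion: 0.1 cm into the left half from the edge of the
  # home region (y ~ 1) up to y = 3, i.e. ~0.2 cm^2 of opposite-side area,
  # before veering to the right/high target
  n1 <- 200
  exc <- data.frame(
    t = seq(0, 0.8, length.out = n1 + 300),
    x = c(rep(-0.1, n1), seq(-0.1, 8.5, length.out = 300)),
    y = c(seq(0, 3, length.out = n1), seq(3, 8.5, length.out = 300)))
  cl2 <- detect_change(exc, geo)
  expect_equal(cl2$opposite_areas[["decision"]], 0.2, tolerance = 0.05)
  expect_true(cl2$change_decision)
  expect_equal(unname(cl2$initial), c("left", "high"))

  sitting <- data.frame(t = 1:5 / 1000, x = rep(0.1, 5), y = rep(0, 5))
  expect_error(detect_change(sitting, geo), "never leaves")
})

test_that("confidence logistic recovers generating coefficients", {
  set.seed(14)
  n <- 10000
  acoh <- sample(c(0, 0.032, 0.064, 0.128, 0.256, 0.512), n, TRUE)
  ph <- plogis(-0.5 + 8 * acoh)
  d <- data.frame(coherence = acoh,
                  init_conf = ifelse(runif(n) < ph, "high", "low"))
  fit <- logistic_confidence(d)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$coefficients[["b0"]] + 0.5), 2 * se[1])
  expect_lt(abs(fit$coefficients[["b1"]] - 8), 2 * se[2])
  # shuffled labels: no slope
  d$init_conf <- sample(d$init_conf)
  fit0 <- logistic_confidence(d)
  se0 <- summary(fit0$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit0$coefficients[["b1"]]), 3 * se0[2])
  expect_error(logistic_confidence(data.frame(coherence = 1:3,
                                              init_conf = "high")),
               "both confidence levels")
})

test_that("high confidence comes with steeper choice sensitivity on model data", {
  tr <- s1_trials()
  fit <- logistic_choice_with_confidence(tr)
  expect_gt(fit$coefficients[["b3"]], 0)
  expect_lt(fit$p_value, 0.01)
  # a single confidence level reduces to the plain logistic
  tr1 <- tr; tr1$init_conf <- "high"
  plain <- logistic_choice_with_confidence(tr1)
  expect_true(is.na(plain$coefficients[["b3"]]))
  ref <- glm(I(init_dir == "right") ~ coherence, binomial(), data = tr1)
  expect_equal(plain$coefficients[["b1"]], unname(coef(ref)[2]),
               tolerance = 1e-8)
  # mirror antisymmetry of the stimulus axis
  tr2 <- tr
  tr2$coherence <- -tr2$coherence
  tr2$init_dir <- ifelse(tr$init_dir == "right", "left", "right")
  fit2 <- logistic_choice_with_confidence(tr2)
  expect_equal(abs(fit2$coefficients[["b1"]]),
               abs(fit$coefficients[["b1"]]), tolerance = 1e-6)
})

test_that("odds ratios follow their defining arithmetic and invariances", {
  mk <- function(hc, lc, he, le, final_same = TRUE) {
    d <- data.frame(
      coherence = 0.064,
      correct_init = rep(c(TRUE, TRUE, FALSE, FALSE), c(hc, lc, he, le)),
      init_conf = rep(c("high", "low", "high", "low"), c(hc, lc, he, le)))
    d$final_conf <- d$init_conf
    d
  }
  r <- odds_ratio_analysis(mk(90, 10, 50, 50), n_boot = 50, seed = 2)
  expect_equal(r$table$or_initial, 9)
  # no changes of confidence: final OR equals initial OR exactly
  expect_equal(r$table$or_final, r$table$or_initial)
  # multiplying all cells by a constant leaves the OR unchanged
  r3 <- odds_ratio_analysis(mk(270, 30, 150, 150), n_boot = 50, seed = 2)
  expect_equal(r3$table$or_initial, 9)
  # CIs contain the point estimate
  expect_lte(r$table$or_initial_lo, r$table$or_initial)
  expect_gte(r$table$or_initial_hi, r$table$or_initial)
  # a point without errors cannot define an OR and is excluded
  d <- mk(90, 10, 0, 0)
  r0 <- odds_ratio_analysis(d, n_boot = 20, seed = 2)
  expect_equal(r0$n_excluded_points, 1L)
})

test_that("bootstrap intervals tighten roughly as 1/sqrt(n)", {
  p <- s1_params(); crit <- s1_crit(); rev <- s1_rev()
  tr <- s1_trials()
  s <- tr[abs(tr$coherence) == 0.064, ]
  big <- odds_ratio_analysis(s, n_boot = 300, seed = 4)
  small <- odds_ratio_analysis(s[seq_len(nrow(s) %/% 4), ],
                               n_boot = 300, seed = 4)
  w_big <- big$table$or_initial_hi - big$table$or_initial_lo
  w_small <- small$table$or_initial_hi - small$table$or_initial_lo
  expect_lt(w_big, w_small)
})

test_that("points accounting applies the payoff matrix to the final choice", {
  d <- data.frame(correct_init = c(TRUE, FALSE, FALSE, TRUE),
                  init_conf = c("high", "high", "high", "low"),
                  correct_final = c(TRUE, FALSE, FALSE, TRUE),
                  final_conf = c("high", "low", "high", "low"))
  pa <- points_accounting(d)
  expect_equal(pa$points, c(2, -1, -3, 1))
  # high-risk error revised to low-risk error: benefit +2; the unchanged
  # trials do not enter the denominator
  expect_equal(pa$n_changes, 1)
  expect_equal(pa$change_benefit, 2)
  nochange <- points_accounting(d[c(1, 3, 4), ])
  expect_true(is.na(nochange$change_benefit))
})

test_that("changing one's mind pays on model-generated behavior", {
  tr <- s1_trials()
  pa <- points_accounting(tr)
  expect_gt(pa$change_benefit, 0)
})
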