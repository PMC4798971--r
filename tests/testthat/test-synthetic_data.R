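test_that("simulation is bit-reproducible under a fixed seed", {
  p <- s1_params(); crit <- s1_crit(); rev <- s1_rev()
  des <- session_design(n_per = 30)
  a <- simulate_trials(p, crit, rev, des, seed = 5)
  b <- simulate_trials(p, crit, rev, des, seed = 5)
  cc <- simulate_trials(p, crit, rev, des, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$rt, cc$rt))
})

test_that("trial records satisfy their accounting identities", {
  tr <- s1_trials()
  expect_equal(tr$rt, tr$dt_dec + tr$tnd)
  expect_equal(tr$correct_init, tr$init_dir == tr$direction)
  expect_equal(tr$change_decision, tr$init_dir != tr$final_dir)
  expect_equal(tr$change_confidence, tr$init_conf != tr$final_conf)
  expect_true(all(tr$init_conf[tr$lo_init >= 0.89] == "high"))
  expect_true(all(abs(tr$coherence[tr$direction == "left"] <= 0)))
})

test_that("a very sensitive observer is fast and nearly perfect on strong motion", {
  p <- race_params(kappa = 60, bound = 0.74, tnd_mean = 0.4)
  tr <- simulate_trials(p, s1_crit(), revision_params(0),
                        session_design(n_per = 400, coherences = 0.512),
                        seed = 2)
  expect_gt(mean(tr$correct_init), 0.999)
  expect_lt(mean(tr$dt_dec), 0.1)
})

test_that("simulated category frequencies converge to the analytic predictions", {
  p <- s1_params(); crit <- s1_crit(); m <- s1_map()
  tg <- coarse_tgrid()
  tr <- s1_trials()
  for (co in c(0.064, 0.256)) {
    s <- tr[tr$coherence == co, ]
    ip <- initial_outcome_probs(p, crit, m, co, tg)
    emp <- c(mean(s$correct_init & s$init_conf == "high"),
             mean(s$correct_init & s$init_conf == "low"),
             mean(!s$correct_init & s$init_conf == "high"),
             mean(!s$correct_init & s$init_conf == "low"))
    se <- sqrt(ip$probs * (1 - ip$probs) / nrow(s))
    expect_true(all(abs(emp - ip$probs) < 3 * pmax(se, 1e-3)))
  }
})

test_that("unabsorbed trials are censored, counted and excluded", {
  p <- race_params(kappa = 1, bound = 1.2, tnd_mean = 0.4)
  expect_message(
    tr <- simulate_trials(p, s1_crit(), revision_params(0),
                          session_design(n_per = 60, coherences = 0),
                          seed = 3, t_max = 1),
    "censored")
  expect_gt(attr(tr, "n_censored"), 0)
  expect_true(all(tr$dt_dec <= 1))
})

test_that("overall change-of-mind rates sit in the single-digit percent range", {
  tr <- s1_trials()
  rate <- mean(tr$change_decision | tr$change_confidence)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.2)
})

test_that("trajectories respect their construction and close the loop with detection", {
  geo <- reach_geometry()
  tr <- s1_trials()
  tr <- tr[seq_len(min(nrow(tr), 1000)), ]
  paths <- synthesize_trajectories(tr, geo, seed = 12)
  ok <- 0L
  for (i in seq_along(paths)) {
    cl <- detect_change(paths[[i]], geo)
    hit <- identical(unname(cl$final), c(tr$final_dir[i], tr$final_conf[i])) &&
      identical(unname(cl$initial), c(tr$init_dir[i], tr$init_conf[i]))
    ok <- ok + hit
  }
  expect_gte(ok / length(paths), 0.99)
  # change-of-both trajectories cross both dividing lines
  both <- which(tr$change_decision & tr$change_confidence)
  if (length(both)) {
    pth <- paths[[both[1]]]
    expect_true(min(pth$x) < 0 && max(pth$x) > 0)
    expect_true(min(pth$y) < 0 && max(pth$y) > 0)
  }
})

test_that("dot movies implement the displacement rule and frame bookkeeping", {
  mv <- generate_dot_movie(1, "right", n_frames = 30, seed = 8)
  nd <- attr(mv, "n_dots")
  # dot count per frame = density x aperture area x frame time
  expect_equal(nd, round(12.5 * pi * 2.5^2 / 75))
  expect_true(all(vapply(mv, nrow, integer(1)) == nd))
  # full coherence: each dot moves by exactly the coherent step (or wraps)
  step <- 5 * 3 / 75
  for (f in 4:6) {
    dx <- mv[[f]][, 1] - mv[[f - 3]][, 1]
    dy <- mv[[f]][, 2] - mv[[f - 3]][, 2]
    expect_true(all(abs(dy) < 1e-12))
    wrapped <- abs(dx - step) > 1e-12
    expect_true(all(abs(dx[!wrapped] - step) < 1e-12))
  }
})

test_that("mirrored pairs cancel their net motion energy", {
  cfg <- motion_filter_config()
  mv <- generate_dot_movie(0.512, "right", n_frames = 45, seed = 13)
  e1 <- motion_energy(mv, cfg)
  e2 <- motion_energy(mirror_movie(mv), cfg)
  expect_equal(e1$energy + e2$energy, rep(0, nrow(e1)), tolerance = 1e-9)
})

test_that("zero-coherence movies carry no mean directional signal", {
  cfg <- motion_filter_config()
  means <- vapply(1:60, function(s)
    mean(motion_energy(generate_dot_movie(0, "right", n_frames = 30,
                                          seed = s), cfg)$energy),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-12)
})

test_that("trial tables round-trip through delimited text", {
  tr <- s1_trials()[1:20, ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tr, f)
  back <- read_trial_table(f)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  expect_equal(back$final_conf, tr$final_conf)
})
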