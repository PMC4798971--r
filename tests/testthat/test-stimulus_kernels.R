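test_that("net energy carries the sign of the motion direction", {
  cfg <- motion_filter_config()
  er <- motion_energy(generate_dot_movie(1, "right", n_frames = 45,
                                         seed = 3), cfg)
  el <- motion_energy(generate_dot_movie(1, "left", n_frames = 45,
                                         seed = 3), cfg)
  expect_gt(mean(er$energy), 0)
  expect_lt(mean(el$energy), 0)
  expect_error(motion_energy(structure(list(), class = "dot_movie")),
               "empty")
})

test_that("mirroring a movie negates its energy trace", {
  cfg <- motion_filter_config()
  mv <- generate_dot_movie(0.064, "right", n_frames = 60, seed = 21)
  e <- motion_energy(mv, cfg)
  em <- motion_energy(mirror_movie(mv), cfg)
  expect_equal(em$energy, -e$energy, tolerance = 1e-9)
})

test_that("the impulse response is causal, transient and rightward-positive", {
  ir <- filter_impulse_response()
  expect_equal(max(ir$energy), 1)
  expect_gt(ir$t[which.max(ir$energy)], 0.02)
  expect_lt(max(abs(ir$energy[ir$t > 0.35])), 0.05)
})

test_that("residuals are mean-zero per condition and restricted to weak motion", {
  cfg <- motion_filter_config()
  info <- expand.grid(rep = 1:4,
                      coherence = c(-0.064, -0.032, 0.032, 0.064, 0.512))
  traces <- lapply(seq_len(nrow(info)), function(i)
    motion_energy(generate_dot_movie(abs(info$coherence[i]),
                                     if (info$coherence[i] >= 0) "right"
                                     else "left",
                                     n_frames = 30, seed = 100 + i), cfg))
  res <- energy_residuals(traces, info)
  expect_true(all(abs(res$info$coherence) <= 0.064))   # 51.2% dropped
  for (co in unique(res$info$coherence)) {
    sel <- res$info$coherence == co
    expect_equal(colMeans(res$residuals[sel, , drop = FALSE]),
                 rep(0, ncol(res$residuals)), tolerance = 1e-9)
    # removing the condition mean cannot inflate the variance
    raw <- do.call(rbind, lapply(traces[info$coherence == co],
                                 function(x) x$energy))
    expect_lte(mean(res$residuals[sel, ]^2), mean(scale(raw, scale = FALSE)^2) + 1e-9)
  }
})

closed_loop_fixture <- function() {
  fixture("closed_loop", {
    cfg <- motion_filter_config()
    p <- s1_params()
    crit <- s1_crit()
    cohs <- rep(c(-0.064, -0.032, 0, 0.032, 0.064), each = 90)
    movies <- lapply(seq_along(cohs), function(i)
      generate_dot_movie(abs(cohs[i]),
                         if (cohs[i] >= 0) "right" else "left",
                         n_frames = 150, seed = 2000 + i))
    traces <- lapply(movies, motion_energy, cfg = cfg)
    energies <- lapply(traces, function(x) x$energy)
    tr <- simulate_trials_from_energy(energies, cohs, p, crit, seed = 77)
    # movement alignment needs the trace to cover the whole viewing time
    tr <- tr[tr$rt <= length(energies[[1]]) / 75, ]
    list(cfg = cfg, traces = traces[tr$trial], trials = tr)
  })
}

test_that("choice kernels from a closed-loop simulation show the early-weighting signature", {
  cl <- closed_loop_fixture()
  res <- energy_residuals(cl$traces, cl$trials)
  km <- psychophysical_kernels(res, "choice", "movement", min_trials = 5)
  r <- km[km$group == "right", ]
  l <- km[km$group == "left", ]
  # with mean RT ~0.9 s and mean non-decision time ~0.46 s, the evidence
  # that drove the decision sits roughly 0.9 to 0.45 s before movement
  early_r <- mean(r$mean[r$t >= -0.85 & r$t < -0.35], na.rm = TRUE)
  late_r <- mean(r$mean[r$t > -0.1], na.rm = TRUE)
  early_l <- mean(l$mean[l$t >= -0.85 & l$t < -0.35], na.rm = TRUE)
  expect_gt(early_r, 0)    # rightward choices follow rightward fluctuations
  expect_lt(early_l, 0)
  expect_lt(late_r, early_r)   # influence decays toward movement onset
  # confidence kernels share the sign of the choice kernel
  kc <- psychophysical_kernels(res, "confidence", "movement",
                               min_trials = 5)
  rh <- kc[kc$group == "right_high", ]
  rl <- kc[kc$group == "right_low", ]
  if (nrow(rh) && nrow(rl)) {
    dif <- mean(rh$mean[rh$t >= -0.85 & rh$t < -0.3], na.rm = TRUE) -
      mean(rl$mean[rl$t >= -0.85 & rl$t < -0.3], na.rm = TRUE)
    expect_gt(dif, 0)
  }
})

test_that("shuffled grouping labels flatten the kernels", {
  cl <- closed_loop_fixture()
  res <- energy_residuals(cl$traces, cl$trials)
  set.seed(99)
  res$info$init_dir <- sample(res$info$init_dir)
  km <- psychophysical_kernels(res, "choice", "onset", min_trials = 5)
  for (g in unique(km$group)) {
    k <- km[km$group == g, ]
    expect_lt(abs(mean(k$mean / pmax(k$sem, 1e-12), na.rm = TRUE)), 1)
  }
})

test_that("non-decision parameters are recovered from synthetic kernels", {
  ir <- filter_impulse_response()
  dt <- 1 / 75
  t <- seq(-1.5, 0.2, by = dt)
  make_kernel <- function(mu, sig, alpha = 1, noise = 0) {
    step <- pnorm(-mu, t, sig)
    conv <- stats::convolve(step, rev(ir$energy),
                            type = "open")[seq_along(t)]
    y <- alpha * conv / sum(ir$energy)
    set.seed(1)
    data.frame(t = t, mean = y + rnorm(length(t), 0, noise))
  }
  fit <- fit_nondecision_from_kernel(make_kernel(0.40, 0.06, noise = 0.005),
                                     ir)
  expect_lt(abs(fit$mu_tnd - 0.40) / 0.40, 0.1)
  expect_lt(abs(fit$sigma_tnd - 0.06) / 0.06, 0.1)
  # recovery holds across a grid of generating values
  for (mu in c(0.3, 0.5)) {
    f <- fit_nondecision_from_kernel(make_kernel(mu, 0.08, noise = 0.005),
                                     ir)
    expect_lt(abs(f$mu_tnd - mu) / mu, 0.1)
  }
  # sigma -> 0: the fitted curve is a step smoothed only by the filter
  f0 <- fit_nondecision_from_kernel(make_kernel(0.4, 1e-6), ir)
  expect_lt(f0$sigma_tnd, 0.02)
  expect_lt(f0$rss, 1e-4)
  # flat kernel: not identifiable
  flat <- data.frame(t = t, mean = rep(0, length(t)))
  expect_false(fit_nondecision_from_kernel(flat, ir)$identifiable)
})

test_that("late evidence cannot influence the initial choice", {
  cl <- closed_loop_fixture()
  # correlate residual energy with choice in the window after the bound
  # crossing: the correlation must vanish
  res <- energy_residuals(cl$traces, cl$trials)
  E <- res$residuals
  info <- res$info
  dt <- res$t[2] - res$t[1]
  post <- rep(NA_real_, nrow(E))
  for (i in seq_len(nrow(E))) {
    k <- round(info$dt_dec[i] / dt) + 2
    if (k < ncol(E) - 3) post[i] <- mean(E[i, k:ncol(E)])
  }
  ok <- is.finite(post)
  r <- cor(post[ok], as.integer(info$init_dir[ok] == "right"))
  expect_lt(abs(r), 2.5 / sqrt(sum(ok)) + 0.05)
})
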