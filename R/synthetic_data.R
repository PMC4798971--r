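# Synthetic generators: Euler-Maruyama trial simulation (the Monte-Carlo
# counterpart of the analytic machinery), reach trajectories with
# mid-flight re-plans, and random-dot movies.

#' Session design for the motion discrimination task
#'
#' @param n_per Trials per signed coherence.
#' @param coherences Signed coherence set (see [coherence_set()]).
#' @param foreperiod_range,foreperiod_mean Truncated-exponential foreperiod
#'   (s) between trial start and motion onset.
#' @param block_order Block ordering of the two target layouts within a
#'   session (`"A"` = high-risk targets on top).
#' @param double_pass Whether stimuli are generated in mirrored pairs shown
#'   twice (controls stimulus-driven variability).
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_per = 100L, coherences = coherence_set(),
                           foreperiod_range = c(0.5, 2.0),
                           foreperiod_mean = 0.82,
                           block_order = c("A", "B", "B", "A"),
                           double_pass = TRUE) {
  stopifnot(n_per >= 1)
  structure(list(n_per = as.integer(n_per), coherences = coherences,
                 foreperiod_range = foreperiod_range,
                 foreperiod_mean = foreperiod_mean,
                 block_order = block_order, double_pass = double_pass),
            class = "session_design")
}

# truncated exponential draw on [lo, hi] with target mean (rate solved
# numerically once)
.rtruncexp <- function(n, lo, hi, mean) {
  f <- function(r) {
    # mean of exponential(rate r) truncated to [0, hi - lo], shifted by lo
    w <- hi - lo
    lo + 1 / r - w * exp(-r * w) / (1 - exp(-r * w)) - mean
  }
  r <- stats::uniroot(f, c(1e-3, 100))$root
  u <- stats::runif(n)
  lo + (-log(1 - u * (1 - exp(-r * (hi - lo))))) / r
}

#' Simulate trials from the full race + revision model
#'
#' Euler-Maruyama realization of the two correlated accumulators with
#' absorption detection, belief-map lookup at the decision, free
#' continuation of the evidence balance for `t_pip`, and final zone
#' classification. The post-initiation continuation is sampled from the
#' exact free Gaussian transition (distributionally identical to stepping
#' the unbounded pair).
#'
#' @param params A [race_params()] object.
#' @param crit A [confidence_criterion()].
#' @param rev A [revision_params()] (use `revision_params(0)` for an
#'   initial-decision-only simulation).
#' @param design A [session_design()].
#' @param seed Integer seed; the simulation is bit-reproducible.
#' @param dt Euler step (s), <= 1 ms.
#' @param t_max Censoring cap on decision time (s); unabsorbed trials are
#'   recorded as censored and excluded, with the count reported as an
#'   attribute and a message.
#' @param map Optional precomputed [build_belief_map()] (built from
#'   `params` and the design's coherence set otherwise).
#' @return A data frame of class `trial_table`, one row per (non-censored)
#'   trial: signed `coherence`, true/designated `direction`, decision time
#'   `dt_dec`, non-decision time `tnd`, `rt`, balance of evidence at the
#'   decision (`delta_dec`) and after continuation (`delta_post`), mapped
#'   log-odds (`lo_init`, `lo_final`), initial and final direction and
#'   confidence, correctness flags, and `points` earned on the final
#'   choice (`points_initial` is the counterfactual had the initial choice
#'   stood). Attribute `n_censored` counts excluded trials.
#' @export
simulate_trials <- function(params, crit, rev, design = session_design(),
                            seed = 1L, dt = 5e-4, t_max = 5,
                            map = NULL) {
  stopifnot(dt > 0, dt <= 1e-3)
  if (rev$t_pip > params$tnd_mean)
    stop("t_pip must not exceed the mean non-decision time", call. = FALSE)
  set.seed(seed)
  if (is.null(map)) {  # belief prior is over the symmetric experimental set
    cs <- design$coherences
    sym <- tryCatch({build_belief_map(params, cs, tabulate = FALSE)},
                    error = function(e) NULL)
    map <- if (!is.null(sym)) sym else
      build_belief_map(params, c(cs, -cs), tabulate = FALSE)
  }
  co <- rep(design$coherences, each = design$n_per)
  n <- length(co)
  ord <- sample.int(n)   # interleave conditions as in a session
  co <- co[ord]
  direction <- ifelse(co > 0, "right", ifelse(co < 0, "left",
                      sample(c("right", "left"), n, replace = TRUE)))
  rho <- params$corr; B <- params$bound
  mu1 <- params$kappa * co * dt
  sd_step <- sqrt(dt)
  x1 <- numeric(n); x2 <- numeric(n)
  t_dec <- rep(NA_real_, n); winner <- character(n)
  loser_state <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  nsteps <- ceiling(t_max / dt)
  for (s in seq_len(nsteps)) {
    idx <- which(active)
    if (!length(idx)) break
    p1 <- x1[idx]; p2 <- x2[idx]
    z1 <- stats::rnorm(length(idx))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(length(idx))
    n1 <- p1 + mu1[idx] + sd_step * z1
    n2 <- p2 - mu1[idx] + sd_step * z2
    x1[idx] <- n1; x2[idx] <- n2
    # Brownian-bridge probability of an intra-step bound excursion removes
    # the O(sqrt(dt)) bias of end-of-step crossing checks
    pc1 <- ifelse(n1 >= B, 1, exp(-2 * pmax(B - p1, 0) * pmax(B - n1, 0) / dt))
    pc2 <- ifelse(n2 >= B, 1, exp(-2 * pmax(B - p2, 0) * pmax(B - n2, 0) / dt))
    c1 <- stats::runif(length(idx)) < pc1
    c2 <- stats::runif(length(idx)) < pc2
    anyc <- c1 | c2
    if (any(anyc)) {
      hit <- idx[anyc]
      # if both cross within one step, credit the more probable crossing
      w_right <- ifelse(c1[anyc] & c2[anyc], pc1[anyc] >= pc2[anyc], c1[anyc])
      t_dec[hit] <- s * dt
      winner[hit] <- ifelse(w_right, "right", "left")
      loser_state[hit] <- pmin(ifelse(w_right, n2[anyc], n1[anyc]), B)
      active[hit] <- FALSE
    }
  }
  censored <- is.na(t_dec)
  n_cens <- sum(censored)
  keep <- which(!censored)
  co <- co[keep]; direction <- direction[keep]; t_dec <- t_dec[keep]
  winner <- winner[keep]; loser_state <- loser_state[keep]
  m <- length(keep)
  delta_dec <- B - loser_state
  lo_init <- log_odds(map, t_dec, delta_dec)
  init_conf <- ifelse(lo_init >= crit$theta, "high", "low")
  # free continuation of the oriented balance for t_pip
  orient <- ifelse(winner == "right", 1, -1)
  if (rev$t_pip > 0) {
    delta_post <- delta_dec + orient * 2 * params$kappa * co * rev$t_pip +
      sqrt(2 * (1 - rho) * rev$t_pip) * stats::rnorm(m)
    lo_final <- log_odds(map, t_dec + rev$t_pip, delta_post)
  } else {
    delta_post <- delta_dec
    lo_final <- lo_init
  }
  zone <- character(m)
  for (conf in c("high", "low")) {
    thr <- final_zone_thresholds(crit, rev, conf)
    sel <- init_conf == conf
    zone[sel] <- ifelse(lo_final[sel] >= thr[1], "same_high",
                 ifelse(lo_final[sel] >= thr[2], "same_low",
                 ifelse(lo_final[sel] >= thr[3], "opp_low", "opp_high")))
  }
  flip <- substr(zone, 1, 3) == "opp"
  final_dir <- ifelse(flip,
                      ifelse(winner == "right", "left", "right"), winner)
  final_conf <- ifelse(zone %in% c("same_high", "opp_high"), "high", "low")
  tnd <- pmax(stats::rnorm(m, params$tnd_mean, params$tnd_sd), 0)
  correct_init <- winner == direction
  correct_final <- final_dir == direction
  pay <- function(correct, conf)
    ifelse(conf == "high", ifelse(correct, 2, -3), ifelse(correct, 1, -1))
  out <- data.frame(
    trial = seq_len(m),
    coherence = co,
    direction = direction,
    foreperiod = .rtruncexp(m, design$foreperiod_range[1],
                            design$foreperiod_range[2],
                            design$foreperiod_mean),
    dt_dec = t_dec,
    tnd = tnd,
    rt = t_dec + tnd,
    delta_dec = delta_dec,
    delta_post = delta_post,
    lo_init = lo_init,
    lo_final = lo_final,
    init_dir = winner,
    init_conf = init_conf,
    final_dir = final_dir,
    final_conf = final_conf,
    correct_init = correct_init,
    correct_final = correct_final,
    change_decision = winner != final_dir,
    change_confidence = init_conf != final_conf,
    points = pay(correct_final, final_conf),
    points_initial = pay(correct_init, init_conf),
    seed = rep(seed, m))
  if (n_cens > 0)
    message(sprintf("%d trial(s) unabsorbed at %.1f s recorded as censored and excluded",
                    n_cens, t_max))
  attr(out, "n_censored") <- n_cens
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Geometry of the reaching workspace
#'
#' @param half_width Half of the target-square side (cm): targets sit at
#'   the corners of a square of twice this side length centred on home.
#' @param target_radius Target radius (cm).
#' @param home_radius Movement-initiation radius around home (cm).
#' @param rate Sampling rate (Hz).
#' @param layout `"A"` (high-confidence targets on top) or `"B"`.
#' @return An object of class `reach_geometry` with a `targets` data frame
#'   (direction, confidence, x, y).
#' @export
reach_geometry <- function(half_width = 8.5, target_radius = 1.5,
                           home_radius = 1, rate = 1000,
                           layout = c("A", "B")) {
  layout <- match.arg(layout)
  ysign <- if (layout == "A") 1 else -1
  targets <- data.frame(
    direction = c("right", "right", "left", "left"),
    confidence = c("high", "low", "high", "low"),
    x = c(half_width, half_width, -half_width, -half_width),
    y = ysign * c(half_width, -half_width, half_width, -half_width))
  structure(list(half_width = half_width, target_radius = target_radius,
                 home_radius = home_radius, rate = rate, layout = layout,
                 targets = targets),
            class = "reach_geometry")
}

.minjerk <- function(from, to, n) {
  s <- seq(0, 1, length.out = n)
  g <- 10 * s^3 - 15 * s^4 + 6 * s^5
  cbind(from[1] + (to[1] - from[1]) * g, from[2] + (to[2] - from[2]) * g)
}

#' Synthesize reach trajectories for a trial table
#'
#' Minimum-jerk paths from home to the initial target sampled at the
#' geometry's rate; on change-of-mind trials the movement re-plans toward
#' the final target at a time drawn uniformly from the middle 60% of the
#' movement. Smooth low-amplitude noise is added.
#'
#' @param trials A `trial_table` (or data frame with `init_dir`,
#'   `init_conf`, `final_dir`, `final_conf`).
#' @param geometry A [reach_geometry()].
#' @param seed Integer seed.
#' @param movement_duration Range (s) of movement durations, drawn
#'   uniformly.
#' @param noise_sd Amplitude (cm) of the smoothed positional noise.
#' @return A list of per-trial data frames `(t, x, y)` (seconds, cm).
#' @export
synthesize_trajectories <- function(trials, geometry = reach_geometry(),
                                    seed = 1L,
                                    movement_duration = c(0.55, 0.85),
                                    noise_sd = 0.03) {
  set.seed(seed)
  tg <- geometry$targets
  locate <- function(dir, conf) {
    i <- which(tg$direction == dir & tg$confidence == conf)
    c(tg$x[i], tg$y[i])
  }
  lapply(seq_len(nrow(trials)), function(i) {
    dur <- stats::runif(1, movement_duration[1], movement_duration[2])
    n <- max(10L, round(dur * geometry$rate))
    a <- locate(trials$init_dir[i], trials$init_conf[i])
    b <- locate(trials$final_dir[i], trials$final_conf[i])
    if (all(a == b)) {
      path <- .minjerk(c(0, 0), a, n)
    } else {
      frac <- stats::runif(1, 0.2, 0.8)
      n1 <- max(5L, round(n * frac))
      seg1 <- .minjerk(c(0, 0), a, n)[seq_len(n1), , drop = FALSE]
      seg2 <- .minjerk(seg1[n1, ], b, n - n1 + round(0.4 * n))
      path <- rbind(seg1, seg2[-1, , drop = FALSE])
    }
    np <- nrow(path)
    smooth_noise <- function() {
      e <- stats::rnorm(np, 0, noise_sd)
      stats::filter(e, rep(1 / 25, 25), circular = TRUE)
    }
    path[, 1] <- path[, 1] + as.numeric(smooth_noise())
    path[, 2] <- path[, 2] + as.numeric(smooth_noise())
    data.frame(t = (seq_len(np) - 1) / geometry$rate,
               x = path[, 1], y = path[, 2])
  })
}

#' Generate a random-dot motion movie
#'
#' Dots are shown for one frame and re-drawn in three interleaved sets:
#' the set shown on frame f reappears on frame f + 3 (40 ms later at
#' 75 Hz), at which point each of its dots is either displaced coherently
#' in the motion direction (probability = coherence) or replaced at a
#' random position. Dot count per frame equals density x aperture area x
#' frame duration. The coherent displacement equals speed x 3-frame
#' interval.
#'
#' @param coherence Coherence in `[0, 1]` (probability of coherent
#'   displacement).
#' @param direction `"right"` or `"left"`.
#' @param n_frames Number of frames.
#' @param aperture Aperture diameter (deg).
#' @param density Dot density (dots deg^-2 s^-1).
#' @param speed Motion speed (deg/s).
#' @param frame_rate Display frame rate (Hz).
#' @param seed Integer seed.
#' @return An object of class `dot_movie`: list of per-frame two-column
#'   matrices of dot coordinates (deg, centred on the aperture), with the
#'   generation settings as attributes.
#' @export
generate_dot_movie <- function(coherence, direction = c("right", "left"),
                               n_frames = 75L, aperture = 5, density = 12.5,
                               speed = 5, frame_rate = 75, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(coherence >= 0, coherence <= 1)
  set.seed(seed)
  radius <- aperture / 2
  area <- pi * radius^2
  n_dots <- max(1L, round(density * area / frame_rate))
  step <- speed * 3 / frame_rate * if (direction == "right") 1 else -1
  draw <- function(k) {
    # uniform in the circular aperture
    r <- radius * sqrt(stats::runif(k)); a <- stats::runif(k, 0, 2 * pi)
    cbind(x = r * cos(a), y = r * sin(a))
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f <= 3) {
      frames[[f]] <- draw(n_dots)
    } else {
      prev <- frames[[f - 3]]
      coh <- stats::runif(nrow(prev)) < coherence
      pts <- prev
      pts[coh, 1] <- pts[coh, 1] + step
      # coherently displaced dots leaving the aperture wrap to the
      # opposite side; non-coherent dots are replaced at random
      out <- sqrt(pts[, 1]^2 + pts[, 2]^2) > radius
      pts[coh & out, 1] <- pts[coh & out, 1] - sign(step) * 2 *
        sqrt(pmax(radius^2 - pts[coh & out, 2]^2, 0))
      if (any(!coh)) pts[!coh, ] <- draw(sum(!coh))
      frames[[f]] <- pts
    }
  }
  structure(frames, class = "dot_movie", coherence = coherence,
            direction = direction, aperture = aperture, density = density,
            speed = speed, frame_rate = frame_rate, n_dots = n_dots,
            seed = seed)
}

#' Horizontally mirror a dot movie
#'
#' Produces the mirrored partner of a movie about the vertical midline of
#' the aperture, as used by the double-pass procedure to cancel net
#' motion-energy bias across the stimulus set.
#'
#' @param movie A [generate_dot_movie()] object.
#' @return A `dot_movie` with negated x coordinates and flipped direction
#'   label.
#' @export
mirror_movie <- function(movie) {
  out <- lapply(unclass(movie), function(fr) {
    fr[, 1] <- -fr[, 1]; fr
  })
  attributes(out) <- attributes(movie)
  attr(out, "direction") <- if (attr(movie, "direction") == "right")
    "left" else "right"
  attr(out, "mirrored") <- TRUE
  out
}

#' Simulate choices driven by a movie's own motion energy
#'
#' Closed-loop generator for psychophysical-kernel analyses: the momentary
#' evidence feeding the two accumulators is the (standardized) net motion
#' energy of the trial's own dot movie plus independent accumulator noise,
#' so stimulus fluctuations causally drive choice and confidence up to the
#' moment the bound is reached.
#'
#' @param energies List of net motion-energy traces (one per trial, at the
#'   movie frame rate; see [motion_energy()]).
#' @param coherences Signed coherence per trial (used only for labelling).
#' @param params A [race_params()] object; `kappa` scales the standardized
#'   energy into drift.
#' @param crit A [confidence_criterion()].
#' @param map Optional [build_belief_map()].
#' @param gain Drift per unit standardized energy (1/s).
#' @param frame_rate Movie frame rate (Hz).
#' @param seed Integer seed.
#' @return A `trial_table`-like data frame with `rt`, `dt_dec`, initial
#'   choice and confidence columns (no revision stage).
#' @export
simulate_trials_from_energy <- function(energies, coherences, params, crit,
                                        map = NULL, gain = 2.5,
                                        frame_rate = 75, seed = 1L) {
  stopifnot(length(energies) == length(coherences))
  set.seed(seed)
  if (is.null(map))
    map <- build_belief_map(params, coherence_set(), tabulate = FALSE)
  dt <- 1 / frame_rate
  B <- params$bound; rho <- params$corr
  n <- length(energies)
  res <- vector("list", n)
  # standardize energies jointly so gain has a stable meaning
  esd <- stats::sd(unlist(energies))
  for (i in seq_len(n)) {
    e <- energies[[i]] / esd
    nf <- length(e)
    z1 <- stats::rnorm(nf); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(nf)
    x1 <- cumsum(gain * e * dt + sqrt(dt) * z1)
    x2 <- cumsum(-gain * e * dt + sqrt(dt) * z2)
    hit <- which(x1 >= B | x2 >= B)
    if (!length(hit)) {
      res[[i]] <- NULL
      next
    }
    h <- hit[1]
    w <- if (x1[h] - B >= x2[h] - B) "right" else "left"
    loser <- if (w == "right") x2[h] else x1[h]
    t_dec <- h * dt
    lo <- log_odds(map, t_dec, B - loser)
    res[[i]] <- data.frame(
      trial = i, coherence = coherences[i],
      direction = ifelse(coherences[i] >= 0, "right", "left"),
      dt_dec = t_dec,
      tnd = pmax(stats::rnorm(1, params$tnd_mean, params$tnd_sd), 0),
      init_dir = w,
      init_conf = ifelse(lo >= crit$theta, "high", "low"),
      lo_init = lo)
  }
  out <- do.call(rbind, res)
  out$rt <- out$dt_dec + out$tnd
  attr(out, "n_unabsorbed") <- n - length(unique(out$trial))
  out
}
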