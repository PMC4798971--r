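# Motion-energy filtering and psychophysical kernels.
#
# Dot movies are projected onto a one-dimensional spatial axis (the motion
# axis; the filters are direction-selective in x and the energy is summed
# over space anyway) and convolved with an opponent pair of quadrature
# space-time filters. The preferred displacement of the filters matches
# the coherent dot step (speed x 3-frame interval).

#' Motion-energy filter configuration
#'
#' Opponent-energy model: spatial even/odd (Gabor) quadrature pair crossed
#' with fast/slow biphasic temporal filters, combined into rightward- and
#' leftward-selective space-time filters whose squared quadrature outputs
#' are differenced and summed over space.
#'
#' @param spatial_freq Spatial frequency of the Gabor carrier (cyc/deg).
#' @param spatial_sd Gaussian envelope SD (deg).
#' @param k Temporal rate constant (1/s).
#' @param n_fast,n_slow Orders of the two biphasic temporal filters.
#' @param dx Spatial grid step (deg).
#' @param frame_rate Movie frame rate (Hz).
#' @param t_support Temporal filter support (s).
#' @param x_halfwidth Half-width of the spatial analysis window (deg).
#' @return A list of class `filter_config`.
#' @export
motion_filter_config <- function(spatial_freq = 1.1, spatial_sd = 0.35,
                                 k = 60, n_fast = 3, n_slow = 5,
                                 dx = 0.05, frame_rate = 75,
                                 t_support = 0.3, x_halfwidth = 2.5) {
  structure(list(spatial_freq = spatial_freq, spatial_sd = spatial_sd,
                 k = k, n_fast = n_fast, n_slow = n_slow, dx = dx,
                 frame_rate = frame_rate, t_support = t_support,
                 x_halfwidth = x_halfwidth),
            class = "filter_config")
}

# spatial quadrature pair and temporal pair on their grids
.me_filters <- function(cfg) {
  xs <- seq(-4 * cfg$spatial_sd, 4 * cfg$spatial_sd, by = cfg$dx)
  env <- exp(-xs^2 / (2 * cfg$spatial_sd^2))
  f_even <- env * cos(2 * pi * cfg$spatial_freq * xs)
  f_odd <- env * sin(2 * pi * cfg$spatial_freq * xs)
  ts <- seq(0, cfg$t_support, by = 1 / cfg$frame_rate)
  gt <- function(n) {
    v <- (cfg$k * ts)^n * exp(-cfg$k * ts) *
      (1 / factorial(n) - (cfg$k * ts)^2 / factorial(n + 2))
    v
  }
  list(xs = xs, ts = ts, f_even = f_even, f_odd = f_odd,
       g_fast = gt(cfg$n_fast), g_slow = gt(cfg$n_slow))
}

# separable convolution of a space-time stimulus S (nx x nt) with spatial
# kernel fx and causal temporal kernel gt
.conv_st <- function(S, fx, gt) {
  nx <- nrow(S); nt <- ncol(S)
  # spatial: centered convolution via stats::filter on each column
  Sp <- apply(S, 2, function(col)
    stats::filter(col, rev(fx), sides = 2))
  Sp[is.na(Sp)] <- 0
  # temporal: causal FIR
  out <- matrix(0, nx, nt)
  for (j in seq_along(gt)) {
    if (gt[j] == 0) next
    cols <- j:nt
    out[, cols] <- out[, cols] + gt[j] * Sp[, cols - j + 1, drop = FALSE]
  }
  out
}

#' Net motion energy of a dot movie
#'
#' Renders the movie onto a space-time grid (dot x positions, summed over
#' y), applies the opponent quadrature filters and sums over space,
#' yielding the net rightward-minus-leftward energy per frame.
#'
#' @param movie A [generate_dot_movie()] object.
#' @param cfg A [motion_filter_config()].
#' @return An object of class `energy_trace`: data frame with `t` (s,
#'   aligned to stimulus onset) and `energy` (arbitrary units), with the
#'   movie's metadata attached as attributes.
#' @export
motion_energy <- function(movie, cfg = motion_filter_config()) {
  if (!length(movie)) stop("empty movie", call. = FALSE)
  flt <- .me_filters(cfg)
  xg <- seq(-cfg$x_halfwidth, cfg$x_halfwidth, by = cfg$dx)
  nt <- length(movie)
  S <- matrix(0, length(xg), nt)
  for (f in seq_len(nt)) {
    fr <- movie[[f]]
    if (!nrow(fr)) next
    ix <- round((fr[, 1] + cfg$x_halfwidth) / cfg$dx) + 1
    ix <- ix[ix >= 1 & ix <= length(xg)]
    for (i in ix) S[i, f] <- S[i, f] + 1
  }
  a <- .conv_st(S, flt$f_even, flt$g_fast)
  b <- .conv_st(S, flt$f_odd, flt$g_slow)
  cc <- .conv_st(S, flt$f_odd, flt$g_fast)
  d <- .conv_st(S, flt$f_even, flt$g_slow)
  e_right <- (a - b)^2 + (cc + d)^2
  e_left <- (a + b)^2 + (cc - d)^2
  net <- colSums(e_right - e_left)
  structure(data.frame(t = (seq_len(nt) - 1) / cfg$frame_rate,
                       energy = net),
            class = c("energy_trace", "data.frame"),
            coherence = attr(movie, "coherence"),
            direction = attr(movie, "direction"),
            frame_rate = cfg$frame_rate)
}

#' Impulse response of the motion-energy filter
#'
#' Net energy response to a two-stroke rightward motion impulse at t = 0:
#' a dot shown at the origin and re-shown one coherent step to the right
#' three frames later.
#'
#' @param cfg A [motion_filter_config()].
#' @param speed Dot speed (deg/s) defining the two-stroke displacement.
#' @param n_frames Length of the returned response (frames).
#' @return Data frame with `t` (s) and `energy` (the impulse response
#'   `IR(t)`), normalized to unit peak.
#' @export
filter_impulse_response <- function(cfg = motion_filter_config(),
                                    speed = 5, n_frames = 45L) {
  step <- speed * 3 / cfg$frame_rate
  frames <- rep(list(matrix(numeric(0), 0, 2)), n_frames)
  frames[[1]] <- cbind(-step / 2, 0)
  frames[[4]] <- cbind(step / 2, 0)
  movie <- structure(frames, class = "dot_movie", coherence = 1,
                     direction = "right", frame_rate = cfg$frame_rate)
  ir <- motion_energy(movie, cfg)
  ir$energy <- ir$energy / max(abs(ir$energy))
  ir
}

#' Motion-energy residuals
#'
#' Removes from each trial's energy trace the mean trace of all trials
#' sharing its (coherence, direction) condition, and restricts the set to
#' weak motion (|coherence| at or below the cutoff), where fluctuations
#' have the strongest leverage on choice.
#'
#' @param traces List of `energy_trace` objects (equal length, aligned to
#'   stimulus onset).
#' @param info Data frame with one row per trace: `coherence` (signed) and
#'   any conditioning columns to carry along (e.g. choices, `rt`).
#' @param max_coherence Inclusion cutoff on |coherence| (default 0.064).
#' @param min_per_condition Conditions with fewer trials are dropped with
#'   a warning.
#' @return List with `residuals` (matrix, trials x frames), `t` (s), and
#'   `info` (rows matching the retained trials).
#' @export
energy_residuals <- function(traces, info, max_coherence = 0.064,
                             min_per_condition = 2L) {
  stopifnot(length(traces) == nrow(info))
  keep <- abs(info$coherence) <= max_coherence
  tr <- traces[keep]; info <- info[keep, , drop = FALSE]
  E <- do.call(rbind, lapply(tr, function(x) x$energy))
  cond <- interaction(info$coherence, sign(info$coherence) >= 0,
                      drop = TRUE)
  ok <- rep(TRUE, nrow(E))
  for (lv in levels(cond)) {
    sel <- cond == lv
    if (sum(sel) < min_per_condition) {
      warning(sprintf("condition %s has fewer than %d trials; excluded",
                      lv, min_per_condition), call. = FALSE)
      ok[sel] <- FALSE
    } else {
      E[sel, ] <- sweep(E[sel, , drop = FALSE], 2,
                        colMeans(E[sel, , drop = FALSE]))
    }
  }
  list(residuals = E[ok, , drop = FALSE], t = tr[[1]]$t,
       info = info[ok, , drop = FALSE])
}

#' Psychophysical kernels from energy residuals
#'
#' Group means (with pointwise s.e.m.) of motion-energy residuals,
#' conditioned on choice, confidence-within-choice, or change type, and
#' aligned either to stimulus onset or to movement onset (residuals are
#' re-indexed backwards from each trial's reaction time).
#'
#' @param res Output of [energy_residuals()]; `res$info` must contain the
#'   grouping columns and `rt` for movement alignment.
#' @param grouping `"choice"` (`init_dir`), `"confidence"`
#'   (`init_conf` within `init_dir`), or `"change"` (no change / change of
#'   confidence / change of decision, from `change_decision` and
#'   `change_confidence`).
#' @param align `"onset"` or `"movement"`.
#' @param min_trials Groups smaller than this are omitted (reported via a
#'   message).
#' @return Data frame with `group`, `t` (s; negative = before movement
#'   onset when `align = "movement"`), `mean`, `sem`, `n`.
#' @export
psychophysical_kernels <- function(res, grouping = c("choice", "confidence",
                                                     "change"),
                                   align = c("onset", "movement"),
                                   min_trials = 10L) {
  grouping <- match.arg(grouping)
  align <- match.arg(align)
  info <- res$info
  grp <- switch(grouping,
    choice = info$init_dir,
    confidence = paste(info$init_dir, info$init_conf, sep = "_"),
    change = ifelse(info$change_decision, "change_decision",
             ifelse(info$change_confidence, "change_confidence",
                    "no_change")))
  E <- res$residuals
  dt <- res$t[2] - res$t[1]
  if (align == "movement") {
    nf <- ncol(E)
    Em <- matrix(NA_real_, nrow(E), nf)
    li <- pmin(pmax(round(info$rt / dt), 1L), nf)
    for (i in seq_len(nrow(E))) {
      k <- li[i]
      Em[i, (nf - k + 1):nf] <- E[i, 1:k]
    }
    E <- Em
    tvec <- (seq_len(nf) - nf) * dt     # 0 = movement onset
  } else {
    tvec <- res$t
  }
  out <- list()
  for (g in sort(unique(grp))) {
    sel <- grp == g
    if (sum(sel) < min_trials) {
      message(sprintf("group %s has %d < %d trials; omitted", g,
                      sum(sel), min_trials))
      next
    }
    M <- E[sel, , drop = FALSE]
    n_eff <- colSums(!is.na(M))
    mu <- colMeans(M, na.rm = TRUE)
    sem <- apply(M, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1))
    out[[g]] <- data.frame(group = g, t = tvec, mean = mu, sem = sem,
                           n = n_eff)
  }
  do.call(rbind, out)
}

#' Fit non-decision time from a movement-aligned kernel
#'
#' Fits `f(t) = alpha * (1 - Phi(t | -mu_tnd, sigma_tnd)) * IR(t)` (with
#' `*` denoting convolution and t = 0 at movement onset) to a
#' movement-aligned psychophysical kernel by least squares: the influence
#' of motion fluctuations steps to zero `mu_tnd` before movement onset,
#' smoothed by Gaussian non-decision-time variability and by the filter's
#' impulse response.
#'
#' @param kernel Data frame with `t` (s, negative before movement onset)
#'   and `mean` (kernel values), movement-aligned.
#' @param impulse_response Data frame from [filter_impulse_response()].
#' @param start Optional named start values `alpha`, `mu_tnd`, `sigma_tnd`.
#' @return A list of class `kernel_fit`: `alpha`, `mu_tnd`, `sigma_tnd`,
#'   `fitted` (curve on the kernel grid), `rss`, and `identifiable`
#'   (FALSE, with NA parameters, for a flat kernel).
#' @export
fit_nondecision_from_kernel <- function(kernel, impulse_response,
                                        start = NULL) {
  t <- kernel$t; y <- kernel$mean
  ok <- is.finite(y); t <- t[ok]; y <- y[ok]
  if (length(y) < 8 || stats::sd(y) < 1e-12) {
    # flat kernels carry no latency information
    return(structure(list(alpha = NA, mu_tnd = NA, sigma_tnd = NA,
                          fitted = rep(NA_real_, length(kernel$t)),
                          rss = NA, identifiable = FALSE),
                     class = "kernel_fit"))
  }
  dt <- t[2] - t[1]
  ir <- impulse_response$energy
  model <- function(alpha, mu, sig) {
    step <- if (sig > 0) stats::pnorm(-mu, t, sig) else as.numeric(t <= -mu)
    conv <- stats::convolve(step, rev(ir), type = "open")[seq_along(t)]
    alpha * conv / sum(ir)
  }
  obj <- function(p) {
    f <- model(p[1], p[2], abs(p[3]))
    sum((y - f)^2)
  }
  if (is.null(start))
    start <- c(alpha = max(abs(y)) * sign(mean(y[seq_len(5)])),
               mu_tnd = 0.35, sigma_tnd = 0.08)
  fit <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  p <- fit$par
  structure(list(alpha = p[[1]], mu_tnd = p[[2]], sigma_tnd = abs(p[[3]]),
                 fitted = model(p[1], p[2], abs(p[3])),
                 t = t, rss = fit$value, identifiable = TRUE),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Kernel fit: non-identifiable (flat kernel)\n")
  } else {
    cat(sprintf("Kernel fit: alpha = %.3g, mu_tnd = %.3f s, sigma_tnd = %.3f s (RSS %.3g)\n",
                x$alpha, x$mu_tnd, x$sigma_tnd, x$rss))
  }
  invisible(x)
}
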