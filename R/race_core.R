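# Analytic first-passage machinery for the two-accumulator race.
#
# The pair (x1, x2) of accumulators is a correlated Brownian motion with
# drift (kappa*C, -kappa*C), per-coordinate variance 1/s and correlation
# rho, absorbed at the shared upper bound x1 = B or x2 = B. For rho in the
# set {-cos(pi/k), k >= 2} the survival density is an exact signed sum of
# free Gaussian propagators started from the orbit of the origin under the
# dihedral group generated by oblique reflections across the two bounds.
# Drift is handled by a Girsanov factor that depends only on the endpoint,
# which turns into a per-image weight exp(mu' Sigma^-1 a_j).

.drift <- function(params, coherence) c(params$kappa * coherence,
                                        -params$kappa * coherence)

# k such that corr = -cos(pi/k), or NA when corr is not image-solvable
.solvable_k <- function(corr, tol = 1e-8) {
  if (corr == 0) return(2L)
  k <- pi / acos(-corr)
  kr <- round(k)
  if (kr >= 2 && abs(-cos(pi / kr) - corr) < tol) as.integer(kr) else NA_integer_
}

.check_solvable <- function(corr) {
  k <- .solvable_k(corr)
  if (is.na(k)) {
    kn <- max(2L, round(pi / acos(-corr)))
    stop(sprintf(paste0("correlation %.6g is not in the image-solvable set ",
                        "{-cos(pi/k)}; nearest supported value is -cos(pi/%d) = %.6g"),
                 corr, kn, -cos(pi / kn)), call. = FALSE)
  }
  k
}

# oblique reflections preserving the diffusion metric:
#   across x1 = B: (x1, x2) -> (2B - x1, x2 - 2 rho (x1 - B))
#   across x2 = B: (x1, x2) -> (x1 - 2 rho (x2 - B), 2B - x2)
.reflect1 <- function(x, B, rho) c(2 * B - x[1], x[2] - 2 * rho * (x[1] - B))
.reflect2 <- function(x, B, rho) c(x[1] - 2 * rho * (x[2] - B), 2 * B - x[2])

#' Image sources for the absorbed correlated race
#'
#' Generates the image sources of the method-of-images solution: the orbit
#' of the start point (0, 0) under alternating oblique reflections across
#' the two absorbing bounds, in word-length order, together with the parity
#' sign of each image. For correlation `-cos(pi/k)` the orbit closes after
#' `2k - 1` images.
#'
#' @param params A [race_params()] object.
#' @param max_words Maximum reflection-word length to generate (used to
#'   enumerate candidate sources for non-closing correlations, e.g. when
#'   searching for the minimal image count).
#' @param require_solvable If `TRUE` (default) an unsupported correlation is
#'   an error; if `FALSE` the (non-closing) orbit is truncated at
#'   `max_words`.
#' @return A data frame with columns `x1`, `x2` (source coordinates),
#'   `sign` (+1/-1 parity) and `word` (reflection-word length), ordered by
#'   increasing word length. The original source at the origin is not
#'   included; images only.
#' @export
image_sources <- function(params, max_words = 64L, require_solvable = TRUE) {
  B <- params$bound; rho <- params$corr
  k <- .solvable_k(rho)
  if (require_solvable && is.na(k)) .check_solvable(rho)
  nmax <- if (!is.na(k)) k else max_words
  a <- .reflect1(c(0, 0), B, rho)
  b <- .reflect2(c(0, 0), B, rho)
  out <- list(); wl <- integer(); sg <- integer()
  chain_a <- c(0, 0); chain_b <- c(0, 0)
  for (len in seq_len(nmax)) {
    chain_a <- if (len %% 2 == 1) .reflect1(chain_a, B, rho) else .reflect2(chain_a, B, rho)
    chain_b <- if (len %% 2 == 1) .reflect2(chain_b, B, rho) else .reflect1(chain_b, B, rho)
    s <- (-1L)^len
    out[[length(out) + 1L]] <- chain_a; wl <- c(wl, len); sg <- c(sg, s)
    # at full word length k the two maximal words coincide: keep one
    if (is.na(k) || len < k || sum(abs(chain_a - chain_b)) > 1e-9 * (1 + B)) {
      out[[length(out) + 1L]] <- chain_b; wl <- c(wl, len); sg <- c(sg, s)
    }
  }
  m <- do.call(rbind, out)
  data.frame(x1 = m[, 1], x2 = m[, 2], sign = sg, word = wl)
}

# Girsanov weight of each source for a given drift: exp(mu' Sigma^-1 a_j).
# With mu = kappa*C*(1,-1) and Sigma = [[1,rho],[rho,1]] this reduces to
# exp(kappa*C*(a1 - a2)/(1 - rho)).
.image_weights <- function(params, coherence, src) {
  exp(params$kappa * coherence * (src$x1 - src$x2) / (1 - params$corr))
}

.dnorm2 <- function(x1, x2, m1, m2, t, rho) {
  s <- sqrt(t)
  stats::dnorm(x1, m1, s) *
    stats::dnorm(x2, m2 + rho * (x1 - m1), sqrt(t * (1 - rho^2)))
}

#' Free (unbounded) propagator of the accumulator pair
#'
#' Transition density of the two correlated accumulators in the absence of
#' any bound: a bivariate Gaussian with mean `start + t * (kappa*C, -kappa*C)`,
#' per-component variance `t` and cross-covariance `t * corr`.
#'
#' @param params A [race_params()] object.
#' @param coherence Signed coherence (proportion; negative = leftward).
#' @param t Elapsed time (s), > 0.
#' @param start Length-2 start state.
#' @param end End state: length-2 vector or an n x 2 matrix.
#' @return Density value(s), 1 per (evidence unit)^2.
#' @examples
#' p <- race_params(kappa = 0, bound = 1, corr = 0, tnd_mean = 0.4)
#' free_propagator(p, 0, 1, c(0, 0), c(0, 0)) # 1/(2*pi)
#' @export
free_propagator <- function(params, coherence, t, start = c(0, 0), end) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  if (is.null(dim(end))) end <- matrix(end, ncol = 2)
  mu <- .drift(params, coherence)
  .dnorm2(end[, 1], end[, 2], start[1] + mu[1] * t, start[2] + mu[2] * t,
          t, params$corr)
}

#' Survival density of the absorbed race (method of images)
#'
#' Density, over end states strictly inside the domain, of paths started at
#' the origin that have touched neither absorbing bound by time `t`, formed
#' as a signed, Girsanov-weighted sum of free propagators from the image
#' sources. The density vanishes on both absorbing boundaries.
#'
#' @inheritParams free_propagator
#' @param end End state(s) with both components below the bound.
#' @param sources Optional precomputed [image_sources()] data frame (the
#'   original source at the origin is added internally).
#' @return Density value(s).
#' @export
image_propagator <- function(params, coherence, t, end, sources = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  if (is.null(sources)) {
    .check_solvable(params$corr)
    sources <- image_sources(params)
  }
  if (is.null(dim(end))) end <- matrix(end, ncol = 2)
  src <- rbind(data.frame(x1 = 0, x2 = 0, sign = 1L, word = 0L), sources)
  w <- .image_weights(params, coherence, src) * src$sign
  mu <- .drift(params, coherence)
  dens <- 0
  for (j in seq_len(nrow(src))) {
    dens <- dens + w[j] * .dnorm2(end[, 1], end[, 2],
                                  src$x1[j] + mu[1] * t,
                                  src$x2[j] + mu[2] * t, t, params$corr)
  }
  dens
}

#' Minimal image count satisfying the absorbing boundary condition
#'
#' Adds image sources in word-length order and reports the smallest number
#' for which the signed propagator sum vanishes (relative magnitude below
#' `tol`) on a grid of points along both absorbing boundaries, for several
#' elapsed times and drifts.
#'
#' @param corr Accumulator noise correlation in (-1, 0].
#' @param kappa,bound Race parameters used for the numerical check.
#' @param coherences Drift conditions probed.
#' @param times Elapsed times probed (s).
#' @param n_boundary Number of probe points per boundary.
#' @param tol Relative tolerance for "vanishes".
#' @param max_images Give up (with an error) beyond this many images.
#' @return Integer: the minimal image count (e.g. 3, 5, 7 for correlations
#'   0, -0.5, -cos(pi/4)).
#' @examples
#' minimal_image_count(0)      # 3
#' minimal_image_count(-0.5)   # 5
#' @export
minimal_image_count <- function(corr, kappa = 13.64, bound = 0.74,
                                coherences = c(0, 0.064, 0.512),
                                times = c(0.1, 0.5, 1.5),
                                n_boundary = 25L, tol = 1e-10,
                                max_images = 64L) {
  params <- race_params(kappa = kappa, bound = bound, corr = corr,
                        tnd_mean = 0.4)
  src_all <- image_sources(params, max_words = max_images,
                           require_solvable = FALSE)
  src_all <- src_all[seq_len(min(nrow(src_all), max_images)), ]
  # probe points spread along each boundary (losing coordinate below B)
  off <- seq(0.05, 4, length.out = n_boundary) * bound
  pts <- rbind(cbind(bound, bound - off), cbind(bound - off, bound))
  for (m in seq_len(nrow(src_all))) {
    ok <- TRUE
    for (co in coherences) {
      for (tt in times) {
        d <- image_propagator(params, co, tt, pts, sources = src_all[seq_len(m), ])
        scale <- max(free_propagator(params, co, tt, c(0, 0), pts), 1e-300)
        if (max(abs(d)) > tol * max(scale, 1)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) return(m)
  }
  stop(sprintf("boundary condition not met with up to %d images; correlation %.4g is likely not image-solvable",
               nrow(src_all), corr), call. = FALSE)
}

# Per-winner absorption flux machinery ---------------------------------------
#
# Writing the survival density as p = sum_j g_j with Gaussian terms g_j, the
# outward probability flux across x1 = B is -(1/2) (Sigma grad p)_1 and
# (Sigma grad g_j)_1 = -g_j (x1 - m_j1)/t, so the joint density of
# (decision time, loser state l) for a right-bound win is in closed form:
#   f_R(t, l) = (1/2t) sum_j s_j c_j (B - m_j1) phi(B; m_j1, t)
#                                    phi(l; m_j2 + rho (B - m_j1), t(1-rho^2))
# and the partial integral over l is the same expression with the second
# Gaussian replaced by its CDF. The left-bound flux swaps the roles of the
# two coordinates.

# Partial integral of the flux over loser state l <= upper (upper may be a
# vector along time_grid). The loser state lives on (-Inf, B]: the FPT
# marginal is the integral up to the bound, not over the whole line (over
# which the image terms cancel exactly).
.flux_partial <- function(params, coherence, time_grid, upper, winner,
                          sources = NULL) {
  if (is.null(sources)) sources <- image_sources(params)
  src <- rbind(data.frame(x1 = 0, x2 = 0, sign = 1L, word = 0L), sources)
  w <- .image_weights(params, coherence, src) * src$sign
  mu <- .drift(params, coherence)
  B <- params$bound; rho <- params$corr
  t <- time_grid
  out <- numeric(length(t))
  s_cond <- sqrt(t * (1 - rho^2))
  for (j in seq_len(nrow(src))) {
    if (winner == "right") {
      mw <- src$x1[j] + mu[1] * t; ml <- src$x2[j] + mu[2] * t
    } else {
      mw <- src$x2[j] + mu[2] * t; ml <- src$x1[j] + mu[1] * t
    }
    base <- w[j] * (B - mw) / (2 * t) * stats::dnorm(B, mw, sqrt(t))
    up <- pmin(upper, B)
    cond <- stats::pnorm((up - (ml + rho * (B - mw))) / s_cond)
    out <- out + base * cond
  }
  out
}

#' First-passage-time density of one winner
#'
#' Marginal density over decision time of the event that the given
#' accumulator wins (reaches its bound first), from the analytic image
#' solution.
#'
#' @inheritParams free_propagator
#' @param time_grid Vector of decision times (s), > 0.
#' @param winner `"right"` or `"left"` (which accumulator wins).
#' @param sources Optional precomputed [image_sources()].
#' @return Density values (1/s) on `time_grid`; integrates (with the other
#'   winner) to 1 minus the survival mass.
#' @export
fpt_density <- function(params, coherence, time_grid,
                        winner = c("right", "left"), sources = NULL) {
  winner <- match.arg(winner)
  .check_solvable(params$corr)
  .flux_partial(params, coherence, time_grid, params$bound, winner, sources)
}

#' Joint absorption solution on a (time, loser-state) grid
#'
#' Evaluates, for each winner, the joint density of decision time and the
#' losing accumulator's state at absorption, together with the surviving
#' probability mass at the final grid time.
#'
#' @inheritParams fpt_density
#' @param loser_grid Increasing grid of loser states, spanning well below
#'   the bound up to the bound.
#' @param conservation_tol Warn if |1 - absorbed - surviving| exceeds this.
#' @return An object of class `absorption_solution`: list with `time_grid`,
#'   `loser_grid`, `flux` (list of two n_t x n_l matrices, `right` and
#'   `left`, per second per evidence unit), `fpt` (list of two marginal FPT
#'   density vectors), `p_win` (absorbed probability per winner),
#'   `survival_mass`, and `defect` (probability-conservation defect).
#' @export
absorption_flux <- function(params, coherence,
                            time_grid = seq(1e-3, 5, by = 1e-3),
                            loser_grid = NULL,
                            conservation_tol = 1e-3) {
  if (any(diff(time_grid) <= 0) || any(time_grid <= 0))
    stop("'time_grid' must be positive and strictly increasing", call. = FALSE)
  .check_solvable(params$corr)
  if (is.null(loser_grid)) {
    tmax <- max(time_grid)
    loser_grid <- seq(params$bound - 8 * sqrt(tmax), params$bound,
                      length.out = 201L)
  }
  if (any(diff(loser_grid) <= 0))
    stop("'loser_grid' must be strictly increasing", call. = FALSE)
  sources <- image_sources(params)
  src <- rbind(data.frame(x1 = 0, x2 = 0, sign = 1L, word = 0L), sources)
  w <- .image_weights(params, coherence, src) * src$sign
  mu <- .drift(params, coherence)
  B <- params$bound; rho <- params$corr
  t <- time_grid; nl <- length(loser_grid)
  s_cond <- sqrt(t * (1 - rho^2))
  flux <- list(right = matrix(0, length(t), nl),
               left  = matrix(0, length(t), nl))
  for (winner in c("right", "left")) {
    for (j in seq_len(nrow(src))) {
      if (winner == "right") {
        mw <- src$x1[j] + mu[1] * t; ml <- src$x2[j] + mu[2] * t
      } else {
        mw <- src$x2[j] + mu[2] * t; ml <- src$x1[j] + mu[1] * t
      }
      base <- w[j] * (B - mw) / (2 * t) * stats::dnorm(B, mw, sqrt(t))
      mcond <- ml + rho * (B - mw)
      flux[[winner]] <- flux[[winner]] +
        outer(seq_along(t), seq_len(nl), function(i, k)
          base[i] * stats::dnorm(loser_grid[k], mcond[i], s_cond[i]))
    }
  }
  fpt <- list(right = .flux_partial(params, coherence, t, params$bound, "right", sources),
              left  = .flux_partial(params, coherence, t, params$bound, "left", sources))
  p_win <- vapply(fpt, function(f) .trapz(t, f), numeric(1))
  # survival mass from the image propagator integrated over the domain
  tmax <- max(t)
  gl <- seq(params$bound - 8 * sqrt(tmax) - abs(params$kappa) * tmax,
            params$bound, length.out = 161L)
  surv_d <- image_propagator(params, coherence, tmax,
                             as.matrix(expand.grid(x1 = gl, x2 = gl)),
                             sources = sources)
  survival <- .trapz2(gl, gl, matrix(surv_d, length(gl), length(gl)))
  defect <- abs(1 - sum(p_win) - survival)
  if (defect > conservation_tol)
    warning(sprintf("probability conservation defect %.3g exceeds tolerance %.3g; grids may be too coarse",
                    defect, conservation_tol), call. = FALSE)
  structure(list(params = params, coherence = coherence,
                 time_grid = t, loser_grid = loser_grid,
                 flux = flux, fpt = fpt, p_win = p_win,
                 survival_mass = survival, defect = defect),
            class = "absorption_solution")
}

#' @export
print.absorption_solution <- function(x, ...) {
  cat("Absorption solution of the correlated race\n")
  cat(sprintf("  coherence: %+.3f, P(right wins) = %.4f, P(left wins) = %.4f\n",
              x$coherence, x$p_win[["right"]], x$p_win[["left"]]))
  cat(sprintf("  survival mass at t = %.2f s: %.3g (conservation defect %.2g)\n",
              max(x$time_grid), x$survival_mass, x$defect))
  invisible(x)
}

#' Single-bound first-passage density (1-D reduction)
#'
#' With the losing accumulator's bound removed the winner's first-passage
#' problem is one-dimensional; this evaluates its density via the same
#' image construction restricted to one boundary (a single image), which
#' coincides with the closed-form shifted-Wald (inverse Gaussian) density
#' [fpt_wald()].
#'
#' @inheritParams fpt_density
#' @return Density values (1/s) on `time_grid`.
#' @export
fpt_density_single <- function(params, coherence, time_grid) {
  B <- params$bound; rho <- params$corr
  src <- data.frame(x1 = c(0, 2 * B), x2 = c(0, 2 * rho * B),
                    sign = c(1L, -1L), word = c(0L, 1L))
  w <- .image_weights(params, coherence, src) * src$sign
  mu <- .drift(params, coherence)
  t <- time_grid
  out <- 0
  for (j in 1:2) {
    mw <- src$x1[j] + mu[1] * t
    out <- out + w[j] * (B - mw) / (2 * t) * stats::dnorm(B, mw, sqrt(t))
  }
  out
}

#' Closed-form single-bound drift-diffusion first-passage density
#'
#' Density of the first passage of a unit-variance drift-diffusion process
#' through an absorbing bound (the Wald / inverse-Gaussian density).
#'
#' @param t Times (s), > 0.
#' @param drift Drift rate (evidence units/s).
#' @param bound Absorbing bound (> 0).
#' @return Density values (1/s).
#' @export
fpt_wald <- function(t, drift, bound) {
  bound / sqrt(2 * pi * t^3) * exp(-(bound - drift * t)^2 / (2 * t))
}

# trapezoid rules
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
.trapz2 <- function(x, y, z) {
  wx <- diff(x); wy <- diff(y)
  zc <- (z[-1, -1] + z[-nrow(z), -1] + z[-1, -ncol(z)] + z[-nrow(z), -ncol(z)]) / 4
  sum(outer(wx, wy) * zc)
}
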