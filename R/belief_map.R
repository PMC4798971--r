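# Mapping decision state and elapsed time to the log-odds of being correct.
#
# The confidence variable is the balance of evidence Delta = winner - loser,
# oriented toward the leading (chosen) direction. Under any signed coherence
# C the oriented balance diffuses with drift 2*kappa*C and variance rate
# 2*(1 - rho). The log-odds that the leading direction is correct is the log
# ratio of the prior-weighted balance densities under congruent versus
# opposing coherences. Because every image term of the absorbed density
# carries the same endpoint-only Girsanov factor, this balance-based map
# yields exactly the coherence likelihood ratios of the absorption flux, so
# it is calibrated by construction at decision states and extends smoothly
# to all Delta (including reversed evidence) for the post-initiation stage.

#' Build a belief map from race parameters and a coherence prior
#'
#' Constructs the mapping from (elapsed evidence time, balance of evidence)
#' to the log-odds that a choice in the leading direction is correct,
#' marginalizing over the signed coherence set with the given prior weights.
#' Weight on 0% coherence is split equally between the two directions
#' (the rewarded direction is designated at random on those trials).
#'
#' @param params A [race_params()] object.
#' @param coherences Signed coherence set; must be symmetric about 0.
#' @param prior Positive prior weights, one per element of `coherences`
#'   (normalized internally). Default uniform.
#' @param t_grid,delta_grid Grids used for the tabulated copy of the map
#'   (serialization, plotting, inversion brackets). The map itself is
#'   evaluated in closed form.
#' @param tabulate If `FALSE`, skip computing the tabulated grid copy
#'   (faster; used in fitting loops where only closed-form evaluation is
#'   needed).
#' @return An object of class `belief_map`.
#' @examples
#' p <- race_params(kappa = 13.64, bound = 0.74, tnd_mean = 0.461)
#' m <- build_belief_map(p)
#' log_odds(m, t = 0.5, delta = c(0, 0.5, 1))
#' @export
build_belief_map <- function(params, coherences = coherence_set(),
                             prior = NULL,
                             t_grid = seq(0.01, 5, by = 0.01),
                             delta_grid = seq(-6, 6, by = 0.05),
                             tabulate = TRUE) {
  stopifnot(inherits(params, "race_params"))
  if (is.null(prior)) prior <- rep(1, length(coherences))
  stopifnot(length(prior) == length(coherences), all(prior > 0))
  # symmetry check on the signed set (with weights)
  key <- function(cs, w) {
    o <- order(cs); paste(signif(cs[o], 10), signif(w[o] / sum(w), 10))
  }
  if (!identical(key(coherences, prior), key(-coherences, prior)))
    stop("'coherences' (with 'prior') must be symmetric about 0",
         call. = FALSE)
  w <- prior / sum(prior)
  agg <- tapply(w, factor(signif(coherences, 12)), sum)
  cs <- as.numeric(names(agg)); ws <- as.numeric(agg)
  map <- structure(list(params = params, coherences = cs, weights = ws,
                        t_grid = t_grid, delta_grid = delta_grid),
                   class = "belief_map")
  if (tabulate)
    map$logodds <- outer(t_grid, delta_grid,
                         function(tt, dd) log_odds(map, tt, dd))
  map
}

#' Evaluate the log-odds of being correct
#'
#' @param map A [build_belief_map()] object.
#' @param t Elapsed evidence time(s) (s), > 0.
#' @param delta Balance of evidence, oriented toward the leading direction
#'   (positive = supporting the choice). Recycled against `t`.
#' @return Log-odds that the choice in the leading direction is correct.
#' @export
log_odds <- function(map, t, delta) {
  n <- max(length(t), length(delta))
  t <- rep_len(t, n); delta <- rep_len(delta, n)
  if (any(t <= 0)) stop("'t' must be positive", call. = FALSE)
  p <- map$params
  cs <- map$coherences; ws <- map$weights
  # congruent side: positive coherences plus half the zero weight; the
  # opposing side is its mirror image
  pos <- cs > 0; zero <- cs == 0
  lse <- function(m, w) {
    # log sum_k w_k exp(m[, k]) row-wise, stable
    mx <- m[, 1L]
    for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + w[j] * exp(m[, j] - mx)
    mx + log(acc)
  }
  q <- function(sgn) {
    cc <- c(cs[pos] * sgn, if (any(zero)) 0)
    wv <- c(ws[pos], if (any(zero)) sum(ws[zero]) / 2)
    m <- vapply(cc, function(co)
      -(delta - 2 * p$kappa * co * t)^2 / (4 * (1 - p$corr) * t),
      numeric(n))
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    lse(m, wv)
  }
  q(1) - q(-1)
}

#' Invert the belief map over the balance of evidence
#'
#' Finds, for each time, the oriented balance `delta` at which the log-odds
#' equals a target value (the map is strictly increasing in `delta`).
#' Vectorized bisection.
#'
#' @param map A [build_belief_map()] object.
#' @param t Elapsed evidence time(s) (s).
#' @param lo Target log-odds (scalar or vector recycled against `t`).
#' @return Balance values `delta` with `log_odds(map, t, delta) == lo`.
#' @export
invert_log_odds <- function(map, t, lo) {
  n <- max(length(t), length(lo))
  t <- rep_len(t, n); lo <- rep_len(lo, n)
  p <- map$params
  span <- 2 * p$kappa * max(abs(map$coherences)) * t +
    20 * sqrt(2 * (1 - p$corr) * t) + 1
  lwr <- -span; upr <- span
  for (i in 1:60) {
    mid <- (lwr + upr) / 2
    f <- log_odds(map, t, mid) - lo
    hi <- f > 0
    upr[hi] <- mid[hi]; lwr[!hi] <- mid[!hi]
  }
  (lwr + upr) / 2
}

#' @export
print.belief_map <- function(x, ...) {
  cat("Belief map: log-odds of correct vs (time, balance of evidence)\n")
  cat(sprintf("  coherence set: %s\n",
              paste(sprintf("%+.1f%%", 100 * x$coherences), collapse = " ")))
  cat(sprintf("  kappa = %.4g, corr = %.4g, balance variance rate %.4g /s\n",
              x$params$kappa, x$params$corr, 2 * (1 - x$params$corr)))
  invisible(x)
}

#' Probability equivalent of a log-odds criterion
#'
#' @param theta Log-odds value(s).
#' @return `1 / (1 + exp(-theta))`, the belief probability at the criterion.
#' @examples
#' probability_equivalent(0.89) # ~0.71
#' @export
probability_equivalent <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  stats::plogis(theta)
}

#' Optimal confidence criterion under a payoff matrix
#'
#' The belief probability at which the expected points of the high-risk and
#' low-risk targets are equal, returned in log-odds units. With the standard
#' payoffs (+2/-3 high risk, +1/-1 low risk) the indifference belief is 2/3,
#' i.e. log-odds log(2) = 0.69.
#'
#' @param payoffs 2 x 2 numeric matrix, rows `high`, `low` (risk), columns
#'   `correct`, `error`.
#' @return Log-odds of the indifference belief.
#' @examples
#' optimal_criterion() # 0.6931
#' @export
optimal_criterion <- function(payoffs = rbind(high = c(2, -3),
                                              low = c(1, -1))) {
  stopifnot(is.numeric(payoffs), all(dim(payoffs) == c(2, 2)))
  # p * a_c + (1-p) * a_e equal across rows
  num <- payoffs[2, 2] - payoffs[1, 2]
  den <- (payoffs[1, 1] - payoffs[1, 2]) - (payoffs[2, 1] - payoffs[2, 2])
  if (den == 0)
    stop("degenerate payoffs: expected points never cross in (0, 1)",
         call. = FALSE)
  p_star <- unname(num / den)
  if (p_star <= 0 || p_star >= 1)
    stop("degenerate payoffs: indifference belief outside (0, 1)",
         call. = FALSE)
  log(p_star / (1 - p_star))
}

# classify flux atoms into the four initial categories for one signed
# coherence; returns per-time partial masses for each (winner x confidence)
.initial_flux_split <- function(params, map, coherence, theta, time_grid,
                                sources = NULL, dcut = NULL) {
  if (is.null(sources)) sources <- image_sources(params)
  B <- params$bound
  if (is.null(dcut))   # high iff Delta >= dcut
    dcut <- invert_log_odds(map, time_grid, theta)
  out <- list()
  for (winner in c("right", "left")) {
    tot <- .flux_partial(params, coherence, time_grid, B, winner, sources)
    hi <- .flux_partial(params, coherence, time_grid,
                        pmin(B - dcut, B), winner, sources)
    hi <- pmin(pmax(hi, 0), tot <- pmax(tot, 0))
    out[[winner]] <- list(total = tot, high = hi, low = tot - hi)
  }
  out
}

#' Predicted initial choice/confidence probabilities and reaction times
#'
#' Integrates the absorption flux for one signed coherence, classifying each
#' (decision time, loser state) atom by winner identity (correct or error
#' given the true direction) and by whether the mapped log-odds reaches the
#' confidence criterion. Probabilities are conditional on absorption before
#' the end of the time grid.
#'
#' @param params A [race_params()] object.
#' @param crit A [confidence_criterion()].
#' @param map A [build_belief_map()] built from the same parameters.
#' @param coherence Signed coherence; must belong to the map's set.
#' @param time_grid Decision-time grid (s).
#' @return An object of class `initial_prediction`: list with `probs`
#'   (named: correct_high, correct_low, error_high, error_low, summing
#'   to 1), `mean_dt`, `mean_rt`, `mean_rt_correct` (s; RT adds the mean
#'   non-decision time), `p_absorbed` and `coherence`.
#' @export
initial_outcome_probs <- function(params, crit, map, coherence,
                                  time_grid = seq(1e-3, 5, by = 1e-3)) {
  stopifnot(inherits(crit, "confidence_criterion"),
            inherits(map, "belief_map"))
  if (min(abs(map$coherences - coherence)) > 1e-9)
    stop(sprintf("coherence %.4g is not in the map's coherence set; refusing to extrapolate",
                 coherence), call. = FALSE)
  sp <- .initial_flux_split(params, map, coherence, crit$theta, time_grid)
  ir <- function(f) .trapz(time_grid, f)
  masses <- c(r_high = ir(sp$right$high), r_low = ir(sp$right$low),
              l_high = ir(sp$left$high),  l_low = ir(sp$left$low))
  if (coherence > 0) {
    pr <- c(correct_high = masses[["r_high"]], correct_low = masses[["r_low"]],
            error_high = masses[["l_high"]], error_low = masses[["l_low"]])
    f_corr <- sp$right$total
  } else if (coherence < 0) {
    pr <- c(correct_high = masses[["l_high"]], correct_low = masses[["l_low"]],
            error_high = masses[["r_high"]], error_low = masses[["r_low"]])
    f_corr <- sp$left$total
  } else {
    pr <- c(correct_high = (masses[["r_high"]] + masses[["l_high"]]) / 2,
            correct_low = (masses[["r_low"]] + masses[["l_low"]]) / 2,
            error_high = (masses[["r_high"]] + masses[["l_high"]]) / 2,
            error_low = (masses[["r_low"]] + masses[["l_low"]]) / 2)
    f_corr <- (sp$right$total + sp$left$total) / 2
  }
  p_abs <- sum(pr)
  f_all <- sp$right$total + sp$left$total
  mean_dt <- ir(time_grid * f_all) / ir(f_all)
  mean_dt_corr <- ir(time_grid * f_corr) / ir(f_corr)
  structure(list(probs = pr / p_abs,
                 mean_dt = mean_dt,
                 mean_rt = mean_dt + params$tnd_mean,
                 mean_rt_correct = mean_dt_corr + params$tnd_mean,
                 p_absorbed = p_abs, coherence = coherence,
                 theta = crit$theta),
            class = "initial_prediction")
}

#' @export
print.initial_prediction <- function(x, ...) {
  cat(sprintf("Initial prediction at coherence %+.3f\n", x$coherence))
  print(round(x$probs, 4))
  cat(sprintf("  mean decision time %.3f s, mean RT %.3f s (correct %.3f s)\n",
              x$mean_dt, x$mean_rt, x$mean_rt_correct))
  invisible(x)
}

#' Alternative confidence rules (balance-only and time-only)
#'
#' Variant read-outs of confidence that ignore part of the decision state:
#' `"balance"` thresholds the balance of evidence at absorption (ignoring
#' deliberation time) and `"time"` thresholds the decision time (ignoring
#' the balance). The choice partition is unchanged.
#'
#' @param kind `"balance"` or `"time"`.
#' @param threshold Evidence units (`"balance"`) or seconds (`"time"`).
#' @inheritParams initial_outcome_probs
#' @return An `initial_prediction` (see [initial_outcome_probs()]).
#' @export
alternative_confidence_rule <- function(kind = c("balance", "time"),
                                        threshold, params, coherence,
                                        time_grid = seq(1e-3, 5, by = 1e-3)) {
  kind <- match.arg(kind)
  sources <- image_sources(params)
  B <- params$bound
  split1 <- function(winner) {
    tot <- .flux_partial(params, coherence, time_grid, B, winner, sources)
    hi <- if (kind == "balance") {
      .flux_partial(params, coherence, time_grid, min(B - threshold, B),
                    winner, sources)
    } else {
      tot * (time_grid <= threshold)
    }
    hi <- pmin(pmax(hi, 0), tot <- pmax(tot, 0))
    list(total = tot, high = hi, low = tot - hi)
  }
  sp <- list(right = split1("right"), left = split1("left"))
  ir <- function(f) .trapz(time_grid, f)
  masses <- c(r_high = ir(sp$right$high), r_low = ir(sp$right$low),
              l_high = ir(sp$left$high), l_low = ir(sp$left$low))
  pr <- if (coherence > 0) {
    c(correct_high = masses[["r_high"]], correct_low = masses[["r_low"]],
      error_high = masses[["l_high"]], error_low = masses[["l_low"]])
  } else if (coherence < 0) {
    c(correct_high = masses[["l_high"]], correct_low = masses[["l_low"]],
      error_high = masses[["r_high"]], error_low = masses[["r_low"]])
  } else {
    c(correct_high = (masses[["r_high"]] + masses[["l_high"]]) / 2,
      correct_low = (masses[["r_low"]] + masses[["l_low"]]) / 2,
      error_high = (masses[["r_high"]] + masses[["l_high"]]) / 2,
      error_low = (masses[["r_low"]] + masses[["l_low"]]) / 2)
  }
  f_all <- sp$right$total + sp$left$total
  f_corr <- if (coherence > 0) sp$right$total else if (coherence < 0)
    sp$left$total else f_all / 2
  mean_dt <- ir(time_grid * f_all) / ir(f_all)
  structure(list(probs = pr / sum(pr), mean_dt = mean_dt,
                 mean_rt = mean_dt + params$tnd_mean,
                 mean_rt_correct = ir(time_grid * f_corr) / ir(f_corr) +
                   params$tnd_mean,
                 p_absorbed = sum(pr), coherence = coherence,
                 rule = kind, threshold = threshold),
            class = "initial_prediction")
}
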