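# Post-initiation processing: after the initial commitment the accumulators
# keep integrating, without bounds, the evidence that was still in the
# sensory/motor pipeline (duration t_pip). The final report is read out by
# comparing the log-odds at t_dec + t_pip against three shifted thresholds
# that partition the axis into same-direction high/low and
# opposite-direction low/high zones.

#' Final-report thresholds in the post-initiation stage
#'
#' The log-odds axis (oriented toward the initial direction) is cut by
#' three ordered thresholds into four zones: same-direction/high,
#' same-direction/low, opposite-direction/low, opposite-direction/high.
#' For an initial high-confidence choice the thresholds are
#' `(theta - d1, -d2, -theta - d3)`; for an initial low-confidence choice
#' the first is `theta + d1` instead.
#'
#' @param crit A [confidence_criterion()].
#' @param rev A [revision_params()].
#' @param initial_confidence `"high"` or `"low"`.
#' @return Named numeric vector `c(upper, middle, lower)`, strictly
#'   decreasing; non-ordered thresholds are an error (such parameter points
#'   are invalid and must be rejected in fitting).
#' @examples
#' crit <- confidence_criterion(0.89)
#' rev <- revision_params(0.395, d1 = 0.77, d2 = 0.24, d3 = -0.36)
#' final_zone_thresholds(crit, rev, "low")  # 1.66 -0.24 -0.53
#' @export
final_zone_thresholds <- function(crit, rev,
                                  initial_confidence = c("high", "low")) {
  initial_confidence <- match.arg(initial_confidence)
  th <- crit$theta
  upper <- if (initial_confidence == "high") th - rev$d1 else th + rev$d1
  thr <- c(upper = upper, middle = -rev$d2, lower = -th - rev$d3)
  if (!(thr[1] > thr[2] && thr[2] > thr[3]))
    stop(sprintf("invalid zone thresholds (%.3g, %.3g, %.3g): must be strictly decreasing",
                 thr[1], thr[2], thr[3]), call. = FALSE)
  thr
}

# Absorption atoms in (decision time, oriented balance) form, with weights,
# per winner, pruned to keep 1 - prune of the absorbed mass. These do not
# depend on the revision parameters and can be cached across fit iterations.
.post_atoms <- function(params, coherence,
                        time_grid = seq(2e-3, 5, by = 2e-3),
                        loser_grid = NULL, prune = 1e-7) {
  sol <- absorption_flux(params, coherence, time_grid, loser_grid,
                         conservation_tol = 5e-3)
  dl <- diff(sol$loser_grid); dt <- diff(sol$time_grid)
  wl <- c(dl / 2, 0) + c(0, dl / 2)
  wt <- c(dt / 2, 0) + c(0, dt / 2)
  atoms <- list()
  for (winner in c("right", "left")) {
    wmat <- sol$flux[[winner]] * outer(wt, wl)
    keep <- wmat > prune * max(wmat)
    idx <- which(keep, arr.ind = TRUE)
    atoms[[winner]] <- data.frame(
      ti = idx[, 1],
      t = sol$time_grid[idx[, 1]],
      delta = params$bound - sol$loser_grid[idx[, 2]],
      w = wmat[keep])
  }
  attr(atoms, "time_grid") <- sol$time_grid
  atoms
}

#' Propagate decision states through the post-initiation period
#'
#' For each absorption atom (decision time, oriented balance), the balance
#' diffuses freely (no absorbing bounds) for `t_pip` seconds with drift set
#' by the true signed coherence (zero on 0% coherence trials), and the
#' belief map is queried at the total elapsed evidence time
#' `t_dec + t_pip`. The returned object carries the atoms grouped by
#' initial category together with the post-initiation Gaussian transition,
#' from which final log-odds (zone) probabilities are computed.
#'
#' @param params A [race_params()] object.
#' @param map A [build_belief_map()] object.
#' @param coherence Signed coherence.
#' @param crit A [confidence_criterion()] classifying the initial report.
#' @param t_pip Post-initiation processing time (s), >= 0.
#' @param time_grid,loser_grid Grids for the absorption solution.
#' @return An object of class `post_initiation`: per-winner atoms with
#'   initial confidence labels, the oriented post-initiation drift and
#'   standard deviation, and the map/criterion needed for classification.
#' @export
propagate_post_initiation <- function(params, map, coherence, crit, t_pip,
                                      time_grid = seq(2e-3, 5, by = 2e-3),
                                      loser_grid = NULL) {
  stopifnot(t_pip >= 0)
  atoms <- .post_atoms(params, coherence, time_grid, loser_grid)
  for (winner in c("right", "left")) {
    a <- atoms[[winner]]
    lo0 <- log_odds(map, a$t, a$delta)
    a$conf_init <- ifelse(lo0 >= crit$theta, "high", "low")
    a$lo_init <- lo0
    # oriented drift: positive evidence supports the chosen direction
    a$post_mean <- a$delta +
      (if (winner == "right") 1 else -1) * 2 * params$kappa * coherence * t_pip
    atoms[[winner]] <- a
  }
  structure(list(params = params, map = map, coherence = coherence,
                 crit = crit, t_pip = t_pip,
                 post_sd = sqrt(2 * (1 - params$corr) * t_pip),
                 atoms = atoms),
            class = "post_initiation")
}

# balance cutoffs corresponding to the zone thresholds at each total
# elapsed time; rows follow t_f, columns the thresholds
.zone_cutoffs <- function(map, t_f, thresholds) {
  vapply(thresholds, function(th) invert_log_odds(map, t_f, th),
         numeric(length(t_f)))
}

# Per-atom probabilities of the four final zones. `cuts_high`/`cuts_low`
# are precomputed balance cutoffs (one row per time-grid point, one column
# per zone threshold), shared across coherences and winners; atoms index
# into them via `ti`. Returns a 2x4 matrix (initial confidence x final
# zone) in the oriented frame (same_high, same_low, opp_low, opp_high).
.zone_joint_one_winner <- function(ppi, a, cuts_high, cuts_low) {
  joint <- matrix(0, 2, 4,
                  dimnames = list(c("high", "low"),
                                  c("same_high", "same_low",
                                    "opp_low", "opp_high")))
  for (conf in c("high", "low")) {
    sel <- a$conf_init == conf
    if (!any(sel)) next
    cuts <- (if (conf == "high") cuts_high else cuts_low)[a$ti[sel], ,
                                                          drop = FALSE]
    if (ppi$t_pip > 0) {
      z <- (cuts - a$post_mean[sel]) / ppi$post_sd
      p_below <- stats::pnorm(z)             # P(final lo < threshold_k)
    } else {
      p_below <- 1 * (a$delta[sel] < cuts)
    }
    w <- a$w[sel]
    p4 <- cbind(1 - p_below[, 1],              # same, high
                p_below[, 1] - p_below[, 2],   # same, low
                p_below[, 2] - p_below[, 3],   # opposite, low
                p_below[, 3])                  # opposite, high
    joint[conf, ] <- colSums(p4 * w)
  }
  joint
}

#' Joint initial-by-final outcome probabilities
#'
#' Composes the post-initiation propagation with the shifted zone
#' thresholds, producing for each coherence the 4 x 4 joint probabilities
#' of the initial and final (direction-correctness x confidence)
#' categories, plus the derived conditional change probabilities.
#'
#' @param params A [race_params()] object.
#' @param crit A [confidence_criterion()].
#' @param rev A [revision_params()]; `t_pip` must not exceed the mean
#'   non-decision time.
#' @param map A [build_belief_map()] object.
#' @param coherences Signed coherences to evaluate.
#' @param time_grid,loser_grid Grids for the absorption solution.
#' @return An object of class `outcome_table`: for each coherence a 4 x 4
#'   matrix (`joint`, rows = initial category, columns = final category,
#'   both in correct/error x high/low terms, summing to 1), conditional
#'   change-of-decision probabilities given initial correct/error,
#'   conditional change-of-confidence probabilities given initial
#'   high/low, and aggregate change rates weighted by the predicted
#'   initial-category frequencies.
#' @export
outcome_table <- function(params, crit, rev, map,
                          coherences = coherence_set(),
                          time_grid = seq(2e-3, 5, by = 2e-3),
                          loser_grid = NULL) {
  stopifnot(inherits(rev, "revision_params"))
  if (rev$t_pip > params$tnd_mean)
    stop("t_pip must not exceed the mean non-decision time", call. = FALSE)
  thr_high <- final_zone_thresholds(crit, rev, "high")
  thr_low <- final_zone_thresholds(crit, rev, "low")
  cats <- c("correct_high", "correct_low", "error_high", "error_low")
  atoms_cache <- attr(coherences, "atoms_cache")
  out <- vector("list", length(coherences))
  # balance cutoffs shared by all coherences: theta at the decision time
  # (initial classification) and the zone thresholds at t + t_pip
  tf <- time_grid + rev$t_pip
  cut_theta <- invert_log_odds(map, time_grid, crit$theta)
  cuts_high <- .zone_cutoffs(map, tf, thr_high)
  cuts_low <- .zone_cutoffs(map, tf, thr_low)
  post_sd <- sqrt(2 * (1 - params$corr) * rev$t_pip)
  for (i in seq_along(coherences)) {
    co <- coherences[i]
    atoms <- if (!is.null(atoms_cache)) atoms_cache[[i]] else
      .post_atoms(params, co, time_grid, loser_grid)
    ppi <- list(t_pip = rev$t_pip, post_sd = post_sd)
    zj <- list()
    for (winner in c("right", "left")) {
      a <- atoms[[winner]]
      a$conf_init <- ifelse(a$delta >= cut_theta[a$ti], "high", "low")
      a$post_mean <- a$delta +
        (if (winner == "right") 1 else -1) * 2 * params$kappa * co * rev$t_pip
      zj[[winner]] <- .zone_joint_one_winner(ppi, a, cuts_high, cuts_low)
    }
    jr <- zj$right
    jl <- zj$left
    # orient to correctness: for c > 0 a right win is correct; zones map
    # (same_high, same_low, opp_low, opp_high) onto final categories
    joint <- matrix(0, 4, 4, dimnames = list(cats, cats))
    place <- function(j, correct_init) {
      # rows: initial high/low of this winner; columns: final zones
      ini <- if (correct_init) c("correct_high", "correct_low") else
        c("error_high", "error_low")
      fin_same <- if (correct_init) c("correct_high", "correct_low") else
        c("error_high", "error_low")
      fin_opp <- if (correct_init) c("error_low", "error_high") else
        c("correct_low", "correct_high")
      m <- matrix(0, 4, 4, dimnames = list(cats, cats))
      m[ini[1], c(fin_same, fin_opp)[c(1, 2, 3, 4)]] <- j["high", ]
      m[ini[2], c(fin_same, fin_opp)[c(1, 2, 3, 4)]] <- j["low", ]
      m
    }
    joint <- if (co > 0) {
      place(jr, TRUE) + place(jl, FALSE)
    } else if (co < 0) {
      place(jl, TRUE) + place(jr, FALSE)
    } else {
      (place(jr, TRUE) + place(jl, FALSE) +
         place(jl, TRUE) + place(jr, FALSE)) / 2
    }
    joint <- joint / sum(joint)
    ini_m <- rowSums(joint)
    is_corr <- c(TRUE, TRUE, FALSE, FALSE)
    is_high <- c(TRUE, FALSE, TRUE, FALSE)
    dec_change <- outer(is_corr, is_corr, "!=")
    conf_change <- outer(is_high, is_high, "!=")
    cond <- function(sel, chg) {
      w <- sum(joint[sel, , drop = FALSE])
      if (w <= 0) return(NA_real_)
      sum(joint[sel, , drop = FALSE] * chg[sel, , drop = FALSE]) / w
    }
    out[[i]] <- list(
      coherence = co, joint = joint,
      p_change_decision = c(given_correct = cond(is_corr, dec_change),
                            given_error = cond(!is_corr, dec_change)),
      p_change_confidence = c(given_high = cond(is_high, conf_change),
                              given_low = cond(!is_high, conf_change)),
      rate_change_decision = sum(joint * dec_change),
      rate_change_confidence = sum(joint * conf_change),
      initial_marginal = ini_m)
  }
  structure(list(coherences = coherences, tables = out,
                 crit = crit, rev = rev),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome table: initial x final category probabilities\n")
  for (tb in x$tables) {
    cat(sprintf("  coherence %+.3f: P(change dec) = %.4f, P(change conf) = %.4f\n",
                tb$coherence, tb$rate_change_decision,
                tb$rate_change_confidence))
  }
  invisible(x)
}

#' Tidy data frame of an outcome table
#'
#' @param x An [outcome_table()] object.
#' @param row.names,optional,... Passed for S3 compatibility (unused).
#' @return Data frame with columns `coherence`, `initial_cat`, `final_cat`,
#'   `probability`.
#' @export
as.data.frame.outcome_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  do.call(rbind, lapply(x$tables, function(tb) {
    g <- expand.grid(initial_cat = rownames(tb$joint),
                     final_cat = colnames(tb$joint),
                     stringsAsFactors = FALSE)
    data.frame(coherence = tb$coherence, g,
               probability = as.vector(tb$joint))
  }))
}
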