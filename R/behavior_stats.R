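# Trial screening, trajectory-based change detection, logistic analyses,
# the confidence-accuracy odds-ratio dissociation, and points accounting.

#' Exclude fast-guess trials
#'
#' Removes trials with a reaction time strictly below the cutoff (150 ms
#' by default; a trial at exactly the cutoff is retained) and reports the
#' number removed.
#'
#' @param trials Data frame with an `rt` column (s).
#' @param min_rt Exclusion cutoff (s).
#' @return The filtered data frame, with attribute `n_excluded`.
#' @export
exclude_trials <- function(trials, min_rt = 0.150) {
  stopifnot("rt" %in% names(trials))
  drop <- trials$rt < min_rt
  out <- trials[!drop, , drop = FALSE]
  if (any(drop))
    message(sprintf("excluded %d trial(s) with RT < %.0f ms", sum(drop),
                    1000 * min_rt))
  attr(out, "n_excluded") <- sum(drop)
  out
}

# area accumulated by the path on each side of a dividing line, from the
# point where the hand leaves the home region to target arrival; the
# "height" differential is the progress along the orthogonal axis
.side_areas <- function(u, v) {
  # u: coordinate across the dividing line (signed); v: progress coordinate
  dv <- abs(diff(v))
  um <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  c(neg = sum(pmax(-um, 0) * dv), pos = sum(pmax(um, 0) * dv))
}

#' Classify changes of mind from a reach trajectory
#'
#' The final target is read from the trajectory endpoint. The initial
#' direction choice is inferred from the area between the hand path
#' (beginning once the hand is 1 cm from home, i.e. at movement
#' initiation) and the vertical line through the starting location: if the
#' area on the side opposite the final choice exceeds the criterion the
#' trial is a change of decision. The same procedure on the horizontal
#' line classifies changes of confidence.
#'
#' @param trajectory Data frame `(t, x, y)` (s, cm), starting in the home
#'   region and ending in a target.
#' @param geometry A [reach_geometry()].
#' @param area_criterion Opposite-side area criterion (cm^2).
#' @return An object of class `change_classification`: initial and final
#'   target (direction, confidence), change flags, and the four
#'   opposite-side areas.
#' @export
detect_change <- function(trajectory, geometry = reach_geometry(),
                          area_criterion = 0.1) {
  x <- trajectory$x; y <- trajectory$y
  r <- sqrt(x^2 + y^2)
  i0 <- which(r > geometry$home_radius)[1]
  if (is.na(i0))
    stop("trajectory never leaves the home region", call. = FALSE)
  xe <- x[length(x)]; ye <- y[length(y)]
  tg <- geometry$targets
  d2 <- (tg$x - xe)^2 + (tg$y - ye)^2
  fin <- tg[which.min(d2), ]
  seg <- seq(i0, length(x))
  ax <- .side_areas(x[seg], y[seg])   # areas left/right of the vertical line
  ay <- .side_areas(y[seg], x[seg])   # areas below/above the horizontal line
  # opposite side relative to the final choice
  opp_dec <- if (fin$x > 0) ax[["neg"]] else ax[["pos"]]
  fin_top <- fin$y > 0
  opp_conf <- if (fin_top) ay[["neg"]] else ay[["pos"]]
  change_dec <- opp_dec > area_criterion
  change_conf <- opp_conf > area_criterion
  init_dir <- if (change_dec)
    setdiff(c("right", "left"), fin$direction) else fin$direction
  init_conf <- if (change_conf)
    setdiff(c("high", "low"), fin$confidence) else fin$confidence
  structure(list(initial = c(direction = init_dir, confidence = init_conf),
                 final = c(direction = fin$direction,
                           confidence = fin$confidence),
                 change_decision = change_dec,
                 change_confidence = change_conf,
                 areas = c(left = ax[["neg"]], right = ax[["pos"]],
                           bottom = ay[["neg"]], top = ay[["pos"]]),
                 opposite_areas = c(decision = unname(opp_dec),
                                    confidence = unname(opp_conf))),
            class = "change_classification")
}

#' @export
print.change_classification <- function(x, ...) {
  cat(sprintf("Initial %s/%s -> final %s/%s (change decision: %s, change confidence: %s)\n",
              x$initial[["direction"]], x$initial[["confidence"]],
              x$final[["direction"]], x$final[["confidence"]],
              x$change_decision, x$change_confidence))
  invisible(x)
}

#' Logistic model of high-confidence probability
#'
#' Fits `P(high) = [1 + exp(-(b0 + b1 |C|))]^-1` by maximum likelihood.
#'
#' @param trials Data frame with `coherence` and `init_conf` columns.
#' @param conf_col Column holding the confidence labels.
#' @return List with `coefficients` (b0, b1), the `glm` fit, and a
#'   `separation` flag.
#' @export
logistic_confidence <- function(trials, conf_col = "init_conf") {
  y <- as.integer(trials[[conf_col]] == "high")
  if (length(unique(y)) < 2)
    stop("both confidence levels must be present", call. = FALSE)
  d <- data.frame(y = y, acoh = abs(trials$coherence))
  fit <- suppressWarnings(stats::glm(y ~ acoh, binomial(), data = d))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 50)
  list(coefficients = c(b0 = unname(stats::coef(fit)[1]),
                        b1 = unname(stats::coef(fit)[2])),
       fit = fit, separation = sep)
}

#' Logistic model of rightward choice with a confidence interaction
#'
#' Fits `P(right) = [1 + exp(-(b0 + b1 C + b2 I + b3 I C))]^-1` where `I`
#' indicates a high-confidence report, and tests the one-sided null
#' hypothesis `b3 <= 0` (high confidence is associated with greater
#' sensitivity when `b3 > 0`).
#'
#' @param trials Data frame with `coherence`, `init_dir`, `init_conf`.
#' @return List with `coefficients` (b0..b3), the one-sided `p_value` for
#'   `b3 > 0`, the `glm` fit, and a `separation` flag.
#' @export
logistic_choice_with_confidence <- function(trials) {
  d <- data.frame(y = as.integer(trials$init_dir == "right"),
                  C = trials$coherence,
                  I = as.integer(trials$init_conf == "high"))
  if (length(unique(d$I)) < 2) {
    # a single confidence level reduces the model to a plain logistic in C
    fit <- suppressWarnings(stats::glm(y ~ C, binomial(), data = d))
    return(list(coefficients = c(b0 = unname(stats::coef(fit)[1]),
                                 b1 = unname(stats::coef(fit)[2]),
                                 b2 = NA_real_, b3 = NA_real_),
                p_value = NA_real_, fit = fit,
                separation = !fit$converged))
  }
  fit <- suppressWarnings(stats::glm(y ~ C * I, binomial(), data = d))
  cf <- summary(fit)$coefficients
  b3 <- cf["C:I", ]
  p_one <- stats::pnorm(b3[["z value"]], lower.tail = FALSE)
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 100)
  list(coefficients = c(b0 = unname(stats::coef(fit)["(Intercept)"]),
                        b1 = unname(stats::coef(fit)["C"]),
                        b2 = unname(stats::coef(fit)["I"]),
                        b3 = unname(stats::coef(fit)["C:I"])),
       p_value = p_one, fit = fit, separation = sep)
}

.odds_ratio <- function(high_c, low_c, high_e, low_e) {
  if (high_e == 0 || low_c == 0 || low_e == 0 || high_c == 0) return(NA_real_)
  (high_c / low_c) / (high_e / low_e)
}

#' Confidence-accuracy odds ratios for initial and final reports
#'
#' For each unsigned coherence, computes the odds ratio
#' `OR = odds(high | correct) / odds(high | error)` twice: once from the
#' initial confidence report and once from the final report, both with
#' correctness defined by the initial direction choice. Bootstrap
#' resampling of trials gives confidence intervals, and a two-sided sign
#' test across coherence points summarizes the systematic OR(final) >
#' OR(initial) discrepancy. Points with an empty cell (e.g. no errors) are
#' excluded and counted.
#'
#' @param trials Data frame with `coherence`, `correct_init`, `init_conf`,
#'   `final_conf`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @param conf_level Level of the percentile intervals.
#' @return An object of class `odds_ratio_result`: per-coherence table
#'   with `or_initial`, `or_final`, bootstrap CIs, a `p_boot` for the
#'   per-point OR difference, the sign-test p-value across usable points,
#'   and the number of excluded points.
#' @export
odds_ratio_analysis <- function(trials, n_boot = 1000L, seed = 1L,
                                conf_level = 0.95) {
  set.seed(seed)
  ucoh <- sort(unique(abs(trials$coherence)))
  alpha <- (1 - conf_level) / 2
  rows <- list(); excluded <- 0L
  for (u in ucoh) {
    s <- trials[abs(trials$coherence) == u, ]
    ors <- function(d) {
      c(ini = .odds_ratio(sum(d$correct_init & d$init_conf == "high"),
                          sum(d$correct_init & d$init_conf == "low"),
                          sum(!d$correct_init & d$init_conf == "high"),
                          sum(!d$correct_init & d$init_conf == "low")),
        fin = .odds_ratio(sum(d$correct_init & d$final_conf == "high"),
                          sum(d$correct_init & d$final_conf == "low"),
                          sum(!d$correct_init & d$final_conf == "high"),
                          sum(!d$correct_init & d$final_conf == "low")))
    }
    pt <- ors(s)
    if (any(is.na(pt))) {
      excluded <- excluded + 1L
      next
    }
    bs <- replicate(n_boot, ors(s[sample.int(nrow(s), replace = TRUE), ]))
    ci <- apply(bs, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    dif <- bs["fin", ] - bs["ini", ]
    p_boot <- 2 * min(mean(dif <= 0, na.rm = TRUE),
                      mean(dif >= 0, na.rm = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      coherence = u, or_initial = pt[["ini"]], or_final = pt[["fin"]],
      or_initial_lo = ci[1, "ini"], or_initial_hi = ci[2, "ini"],
      or_final_lo = ci[1, "fin"], or_final_hi = ci[2, "fin"],
      p_boot = p_boot)
  }
  tab <- do.call(rbind, rows)
  sign_p <- if (!is.null(tab) && nrow(tab) > 0) {
    above <- sum(tab$or_final > tab$or_initial)
    stats::binom.test(above, nrow(tab))$p.value
  } else NA_real_
  structure(list(table = tab, sign_test_p = sign_p,
                 n_excluded_points = excluded, n_boot = n_boot),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat("Confidence-accuracy odds ratios (initial vs final report)\n")
  if (!is.null(x$table))
    print(round(x$table[, c("coherence", "or_initial", "or_final",
                            "p_boot")], 3), row.names = FALSE)
  cat(sprintf("  sign test across points: p = %.4g; excluded points: %d\n",
              x$sign_test_p, x$n_excluded_points))
  invisible(x)
}

#' Points earned and the benefit of changing one's mind
#'
#' Scores each trial from the payoff matrix applied to the final choice
#' (+2/-3 high risk, +1/-1 low risk) and, over change-of-mind trials only,
#' averages the difference between the points earned and the points that
#' the initial choice would have earned.
#'
#' @param trials Data frame with `correct_init`, `init_conf`,
#'   `correct_final`, `final_conf` (change flags are derived if absent).
#' @param payoffs 2 x 2 matrix, rows high/low risk, columns correct/error.
#' @return List with `points` (per-trial, final choice), `points_initial`
#'   (counterfactual), `total`, `n_changes`, and `change_benefit` (mean
#'   extra points per change trial; `NA` when there are no changes).
#' @export
points_accounting <- function(trials, payoffs = rbind(high = c(2, -3),
                                                      low = c(1, -1))) {
  pay <- function(correct, conf)
    ifelse(conf == "high",
           ifelse(correct, payoffs["high", 1], payoffs["high", 2]),
           ifelse(correct, payoffs["low", 1], payoffs["low", 2]))
  pts <- pay(trials$correct_final, trials$final_conf)
  pts0 <- pay(trials$correct_init, trials$init_conf)
  changed <- trials$correct_init != trials$correct_final |
    trials$init_conf != trials$final_conf
  list(points = pts, points_initial = pts0, total = sum(pts),
       n_changes = sum(changed),
       change_benefit = if (any(changed))
         mean(pts[changed] - pts0[changed]) else NA_real_)
}
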