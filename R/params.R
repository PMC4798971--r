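#' Parameters of the correlated race model
#'
#' Container for the parameters governing the pre-decision race between a
#' rightward and a leftward evidence accumulator. Momentary evidence is a
#' bivariate Gaussian with mean `(kappa * C, -kappa * C)` per second for
#' signed coherence `C`, unit variance per second in each accumulator
#' (a normalization convention; `kappa` and `bound` absorb the scale), and
#' correlation `corr` between the two noise streams. The first accumulator
#' to reach the shared absorbing bound `B` commits the choice; reaction time
#' adds a Gaussian non-decision time.
#'
#' @param kappa Drift sensitivity (1/s per unit coherence proportion), >= 0.
#' @param bound Absorbing bound B (evidence units), identical for both
#'   accumulators, > 0.
#' @param corr Correlation of the accumulator noise streams, in (-1, 0].
#'   The analytic machinery additionally requires `corr` to lie in the
#'   image-solvable set `-cos(pi/k)` for integer k >= 2 (0, -0.5 and
#'   -cos(pi/4) are the common cases).
#' @param tnd_mean Mean non-decision time (s), > 0.
#' @param tnd_sd Standard deviation of the non-decision time (s), >= 0.
#'
#' @return An object of class `race_params`.
#' @examples
#' p <- race_params(kappa = 13.64, bound = 0.74, tnd_mean = 0.461)
#' p
#' @export
race_params <- function(kappa, bound, corr = -cos(pi / 4), tnd_mean = 0.4,
                        tnd_sd = 0.06) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
            is.numeric(bound), length(bound) == 1L, bound > 0,
            is.numeric(corr), length(corr) == 1L,
            is.numeric(tnd_mean), length(tnd_mean) == 1L, tnd_mean > 0,
            is.numeric(tnd_sd), length(tnd_sd) == 1L, tnd_sd >= 0)
  if (corr <= -1 || corr > 0)
    stop("'corr' must lie in (-1, 0]", call. = FALSE)
  structure(list(kappa = kappa, bound = bound, corr = corr,
                 tnd_mean = tnd_mean, tnd_sd = tnd_sd),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat("Correlated race model parameters\n")
  cat(sprintf("  kappa (drift sensitivity): %.4g /s\n", x$kappa))
  cat(sprintf("  bound B:                   %.4g\n", x$bound))
  cat(sprintf("  noise correlation:         %.4g\n", x$corr))
  cat(sprintf("  non-decision time:         %.3f s (sd %.3f s)\n",
              x$tnd_mean, x$tnd_sd))
  invisible(x)
}

#' Confidence criterion on the log-odds of being correct
#'
#' A time-invariant threshold `theta` (log-odds units) separating high- from
#' low-confidence reports: the choice is reported with high confidence when
#' the mapped log-odds of being correct is at least `theta`.
#'
#' @param theta Log-odds threshold, > 0.
#' @return An object of class `confidence_criterion`.
#' @examples
#' confidence_criterion(0.89)
#' @export
confidence_criterion <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  structure(list(theta = theta), class = "confidence_criterion")
}

#' @export
print.confidence_criterion <- function(x, ...) {
  cat(sprintf("Confidence criterion: theta = %.4g log-odds (p = %.3f)\n",
              x$theta, stats::plogis(x$theta)))
  invisible(x)
}

#' Post-initiation revision parameters
#'
#' Parameters of the post-decision stage: after the initial commitment the
#' accumulators keep integrating evidence that was in the processing
#' pipeline for a further `t_pip` seconds, and the final (direction,
#' confidence) report is read out from the log-odds at that point using
#' thresholds shifted by `d1`, `d2`, `d3` relative to the initial criteria
#' (hysteresis and motor-cost asymmetries).
#'
#' @param t_pip Post-initiation processing time (s), >= 0. Must not exceed
#'   the mean non-decision time of the race it is combined with; the check
#'   against `tnd_mean` is applied where both are available (e.g. in
#'   [outcome_table()] and the stage-2 fit).
#' @param d1,d2,d3 Threshold shifts (log-odds units); unconstrained in sign.
#' @return An object of class `revision_params`.
#' @examples
#' revision_params(t_pip = 0.395, d1 = 0.77, d2 = 0.24, d3 = -0.36)
#' @export
revision_params <- function(t_pip, d1 = 0, d2 = 0, d3 = 0) {
  stopifnot(is.numeric(t_pip), length(t_pip) == 1L, t_pip >= 0,
            is.numeric(d1), length(d1) == 1L,
            is.numeric(d2), length(d2) == 1L,
            is.numeric(d3), length(d3) == 1L)
  structure(list(t_pip = t_pip, d1 = d1, d2 = d2, d3 = d3),
            class = "revision_params")
}

#' @export
print.revision_params <- function(x, ...) {
  cat("Post-initiation revision parameters\n")
  cat(sprintf("  t_pip: %.3f s\n", x$t_pip))
  cat(sprintf("  threshold shifts (d1, d2, d3): %.3g, %.3g, %.3g\n",
              x$d1, x$d2, x$d3))
  invisible(x)
}

#' Experimental coherence set
#'
#' The default signed coherence set of the motion-discrimination design:
#' plus and minus 0, 3.2, 6.4, 12.8, 25.6 and 51.2% (proportions), negative
#' values coding leftward motion. Zero appears with both signs because the
#' rewarded direction on 0% trials is designated at random.
#'
#' @return Numeric vector of 12 signed coherences.
#' @export
coherence_set <- function() {
  c(-0.512, -0.256, -0.128, -0.064, -0.032, 0,
    0, 0.032, 0.064, 0.128, 0.256, 0.512)
}
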