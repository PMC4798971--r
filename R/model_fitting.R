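# Two-stage maximum-likelihood fitting.
#
# Stage 1 fits (kappa, B, mu_tnd, theta) to the per-coherence counts of the
# four initial categories (multinomial) plus the sample mean RT of correct
# trials (Gaussian with the observed s.e.m. as its standard deviation;
# all trials at 0% coherence). Stage 2 freezes the stage-1 estimates and
# fits (t_pip, d1, d2, d3) to the 16 initial-by-final counts.

#' Tabulate behavioral counts from a trial table
#'
#' Collapses a trial table to the sufficient statistics of the two fitting
#' stages: per unsigned coherence, counts of the 4 initial categories, the
#' sample mean reaction time with its s.e.m. for correct trials (all
#' trials at 0% coherence), and the 4 x 4 counts of initial by final
#' categories.
#'
#' @param trials A `trial_table` (see [simulate_trials()]) or data frame
#'   with columns `coherence`, `correct_init`, `init_conf`, `rt`, and
#'   (for stage 2) `correct_final`, `final_conf`.
#' @return An object of class `behavioral_counts`.
#' @export
tabulate_behavior <- function(trials) {
  cats <- c("correct_high", "correct_low", "error_high", "error_low")
  icat <- function(correct, conf)
    paste0(ifelse(correct, "correct", "error"), "_", conf)
  trials$ucoh <- abs(trials$coherence)
  ucoh <- sort(unique(trials$ucoh))
  has_final <- all(c("correct_final", "final_conf") %in% names(trials))
  per <- lapply(ucoh, function(u) {
    s <- trials[trials$ucoh == u, ]
    n4 <- table(factor(icat(s$correct_init, s$init_conf), levels = cats))
    rts <- if (u == 0) s$rt else s$rt[s$correct_init]
    n16 <- NULL
    if (has_final) {
      n16 <- table(factor(icat(s$correct_init, s$init_conf), levels = cats),
                   factor(icat(s$correct_final, s$final_conf), levels = cats))
    }
    list(coherence = u, n4 = as.vector(n4), n = nrow(s),
         mean_rt = mean(rts),
         sem_rt = stats::sd(rts) / sqrt(length(rts)),
         n16 = n16)
  })
  structure(list(coherences = ucoh, per = per, categories = cats,
                 n_total = nrow(trials)),
            class = "behavioral_counts")
}

#' @export
print.behavioral_counts <- function(x, ...) {
  cat(sprintf("Behavioral counts: %d trials, %d coherence levels\n",
              x$n_total, length(x$coherences)))
  for (p in x$per)
    cat(sprintf("  %5.1f%%: n=%5d  [%s]  mean RT %.3f +- %.3f s\n",
                100 * p$coherence, p$n, paste(p$n4, collapse = " "),
                p$mean_rt, p$sem_rt))
  invisible(x)
}

#' Fitting configuration
#'
#' @param n_starts Number of multi-start optimization runs.
#' @param seed Seed for drawing start points.
#' @param corr Fixed accumulator correlation.
#' @param sigma_tnd Fixed non-decision-time standard deviation (s).
#' @param bounds Named list of `c(lower, upper)` boxes for `kappa`,
#'   `bound`, `mu_tnd`, `theta`, `t_pip` (upper bound of `t_pip` is
#'   additionally capped at the fitted `mu_tnd`), and `dtheta`.
#' @param time_grid Decision-time grid used in the likelihood.
#' @param n_loser Loser-state grid size for the stage-2 absorption atoms.
#' @param prob_floor Probability floor applied before taking logs.
#' @param reltol Relative convergence tolerance passed to the optimizer.
#' @param maxit Maximum optimizer iterations per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 30L, seed = 1L, corr = -cos(pi / 4),
                       sigma_tnd = 0.06,
                       bounds = list(kappa = c(1, 50), bound = c(0.1, 5),
                                     mu_tnd = c(0.1, 1),
                                     theta = c(0.05, 5),
                                     t_pip = c(0, 1),
                                     dtheta = c(-3, 3)),
                       time_grid = seq(5e-3, 5, by = 5e-3),
                       n_loser = 121L, prob_floor = 1e-10,
                       reltol = 1e-6, maxit = 500L) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 corr = corr, sigma_tnd = sigma_tnd, bounds = bounds,
                 time_grid = time_grid, n_loser = as.integer(n_loser),
                 prob_floor = prob_floor, reltol = reltol,
                 maxit = as.integer(maxit)),
            class = "fit_config")
}

# model-predicted initial category probabilities and correct-trial mean RT
# for each unsigned coherence (one map and one theta cutoff per call)
.predict_initial <- function(params, theta, ucoh, time_grid) {
  map <- build_belief_map(params, coherence_set(), tabulate = FALSE)
  sources <- image_sources(params)
  dcut <- invert_log_odds(map, time_grid, theta)
  lapply(ucoh, function(u) {
    sp <- .initial_flux_split(params, map, u, theta, time_grid,
                              sources, dcut)
    ir <- function(f) .trapz(time_grid, f)
    masses <- c(ir(sp$right$high), ir(sp$right$low),
                ir(sp$left$high), ir(sp$left$low))
    pr <- if (u > 0) {
      stats::setNames(masses, c("correct_high", "correct_low",
                                "error_high", "error_low"))
    } else {
      stats::setNames(rep((masses[1:2] + masses[3:4]) / 2, 2),
                      c("correct_high", "correct_low",
                        "error_high", "error_low"))
    }
    f_corr <- if (u > 0) sp$right$total else
      (sp$right$total + sp$left$total) / 2
    list(probs = pr / sum(pr),
         mean_rt_correct = ir(time_grid * f_corr) / ir(f_corr) +
           params$tnd_mean)
  })
}

#' Stage-1 negative log likelihood
#'
#' Multinomial negative log likelihood of the four initial-category counts
#' plus a Gaussian term for each correct-trial sample mean RT (standard
#' deviation = the observed s.e.m.), summed over coherence levels;
#' additive constants are dropped. Error-trial mean RTs do not enter the
#' cost.
#'
#' @param params A [race_params()] object.
#' @param crit A [confidence_criterion()].
#' @param data A [tabulate_behavior()] object.
#' @param time_grid Decision-time grid.
#' @param prob_floor Floor for predicted probabilities (a floored category
#'   triggers a warning).
#' @return Scalar negative log likelihood.
#' @export
nll_initial <- function(params, crit, data,
                        time_grid = seq(5e-3, 5, by = 5e-3),
                        prob_floor = 1e-10) {
  pred <- .predict_initial(params, crit$theta, data$coherences, time_grid)
  nll <- 0
  for (i in seq_along(data$per)) {
    d <- data$per[[i]]; pr <- pred[[i]]$probs
    if (any(pr < prob_floor & d$n4 > 0))
      warning("predicted probability floored for an observed category",
              call. = FALSE)
    pr <- pmax(pr, prob_floor)
    nll <- nll - sum(d$n4 * log(pr)) +
      0.5 * ((d$mean_rt - pred[[i]]$mean_rt_correct) / d$sem_rt)^2
  }
  nll
}

# box transform: optimizer works on unconstrained z, model sees bounded par
.to_box <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
.from_box <- function(x, lo, hi) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                                         1e-8), 1 - 1e-8))

# multi-start Nelder-Mead with a restart polish of the best run (a restart
# rebuilds the simplex, which recovers from premature collapse)
.multistart <- function(obj, n_starts, seed, maxit, reltol, lo, hi,
                        par_names) {
  set.seed(seed)
  starts <- matrix(stats::runif(length(lo) * n_starts, -1.5, 1.5),
                   ncol = length(lo))
  runs <- vector("list", n_starts)
  best_z <- NULL; best_v <- Inf
  for (r in seq_len(n_starts)) {
    fit <- stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    runs[[r]] <- data.frame(start = r, nll0 = obj(starts[r, ]),
                            nll = fit$value, convergence = fit$convergence,
                            t(stats::setNames(.to_box(fit$par, lo, hi),
                                              par_names)))
    if (fit$value < best_v) { best_v <- fit$value; best_z <- fit$par }
  }
  repeat {   # polish until a restart no longer improves materially
    fit <- stats::optim(best_z, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    improved <- best_v - fit$value
    if (fit$value < best_v) { best_v <- fit$value; best_z <- fit$par }
    if (improved < 1e-3) break
  }
  runs <- do.call(rbind, runs)
  list(runs = runs, estimates = stats::setNames(.to_box(best_z, lo, hi),
                                                par_names), nll = best_v)
}

#' Stage-1 maximum-likelihood fit
#'
#' Bounded multi-start Nelder-Mead minimization of [nll_initial()] over
#' (kappa, B, mu_tnd, theta) with the accumulator correlation and sigma_tnd
#' fixed by the configuration.
#'
#' @param data A [tabulate_behavior()] object covering all coherences.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `estimates` (named vector),
#'   `params` / `crit` (fitted objects), `nll`, `starts` (per-start
#'   summary), and the fixed-parameter record.
#' @export
fit_initial <- function(data, config = fit_config()) {
  b <- config$bounds
  lo <- c(b$kappa[1], b$bound[1], b$mu_tnd[1], b$theta[1])
  hi <- c(b$kappa[2], b$bound[2], b$mu_tnd[2], b$theta[2])
  obj <- function(z) {
    x <- .to_box(z, lo, hi)
    params <- race_params(kappa = x[1], bound = x[2], corr = config$corr,
                          tnd_mean = x[3], tnd_sd = config$sigma_tnd)
    nll_initial(params, confidence_criterion(x[4]), data,
                config$time_grid, config$prob_floor)
  }
  ms <- .multistart(obj, config$n_starts, config$seed, config$maxit,
                    config$reltol, lo, hi,
                    c("kappa", "bound", "mu_tnd", "theta"))
  est <- ms$estimates; runs <- ms$runs
  if (all(runs$convergence != 0))
    stop("no optimization start converged; see the per-start table",
         call. = FALSE)
  structure(list(
    stage = "initial", estimates = est, nll = ms$nll, starts = runs,
    params = race_params(kappa = est[["kappa"]], bound = est[["bound"]],
                         corr = config$corr, tnd_mean = est[["mu_tnd"]],
                         tnd_sd = config$sigma_tnd),
    crit = confidence_criterion(est[["theta"]]),
    fixed = c(corr = config$corr, sigma_tnd = config$sigma_tnd),
    config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit (%s stage)\n", x$stage))
  print(round(x$estimates, 4))
  cat(sprintf("  NLL = %.3f over %d start(s); fixed: %s\n", x$nll,
              nrow(x$starts),
              paste(names(x$fixed), round(x$fixed, 4), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

# predicted 16-category probabilities per unsigned coherence, using cached
# absorption atoms (atoms do not depend on the revision parameters)
.predict_revision <- function(carried, rev, data, atoms_cache, map,
                              time_grid) {
  co <- data$coherences
  attr(co, "atoms_cache") <- atoms_cache
  ot <- outcome_table(carried$params, carried$crit, rev, map,
                      coherences = co, time_grid = time_grid)
  lapply(ot$tables, function(tb) tb$joint)
}

#' Stage-2 negative log likelihood
#'
#' Multinomial negative log likelihood of the 16 initial-by-final category
#' counts per unsigned coherence under the revision model, with the stage-1
#' parameters carried over. Parameter points whose zone thresholds are not
#' strictly ordered receive `+Inf`.
#'
#' @param rev A [revision_params()].
#' @param carried A stage-1 `fit_result` (or a list with elements `params`
#'   and `crit`).
#' @param data A [tabulate_behavior()] object with 16-category counts.
#' @param map Optional [build_belief_map()] for the carried parameters.
#' @param time_grid Decision-time grid.
#' @param atoms_cache Internal: precomputed absorption atoms.
#' @param prob_floor Probability floor before logs.
#' @return Scalar negative log likelihood.
#' @export
nll_revision <- function(rev, carried, data, map = NULL,
                         time_grid = seq(5e-3, 5, by = 5e-3),
                         atoms_cache = NULL, prob_floor = 1e-10) {
  if (is.null(map))
    map <- build_belief_map(carried$params, coherence_set(),
                            tabulate = FALSE)
  ok <- tryCatch({
    final_zone_thresholds(carried$crit, rev, "high")
    final_zone_thresholds(carried$crit, rev, "low")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || rev$t_pip > carried$params$tnd_mean) return(Inf)
  if (is.null(atoms_cache))
    atoms_cache <- lapply(data$coherences, function(u)
      .post_atoms(carried$params, u, time_grid))
  pred <- .predict_revision(carried, rev, data, atoms_cache, map, time_grid)
  nll <- 0
  for (i in seq_along(data$per)) {
    n16 <- data$per[[i]]$n16
    if (is.null(n16))
      stop("data lacks 16-category counts; supply final categories",
           call. = FALSE)
    pr <- pmax(pred[[i]], prob_floor)
    nll <- nll - sum(n16 * log(pr))
  }
  nll
}

#' Stage-2 maximum-likelihood fit
#'
#' Multi-start bounded Nelder-Mead minimization of [nll_revision()] over
#' (t_pip, d1, d2, d3), with all four stage-1 estimates held fixed.
#'
#' @param data A [tabulate_behavior()] with 16-category counts.
#' @param carried The stage-1 `fit_result`.
#' @param config A [fit_config()].
#' @return A `fit_result` with the revision estimates; the carried stage-1
#'   estimates are attached unchanged.
#' @export
fit_revision <- function(data, carried, config = fit_config()) {
  b <- config$bounds
  lo <- c(b$t_pip[1], b$dtheta[1], b$dtheta[1], b$dtheta[1])
  hi <- c(min(b$t_pip[2], carried$params$tnd_mean),
          b$dtheta[2], b$dtheta[2], b$dtheta[2])
  map <- build_belief_map(carried$params, coherence_set(), tabulate = FALSE)
  atoms_cache <- lapply(data$coherences, function(u)
    .post_atoms(carried$params, u, config$time_grid,
                loser_grid = seq(carried$params$bound -
                                   8 * sqrt(max(config$time_grid)),
                                 carried$params$bound,
                                 length.out = config$n_loser)))
  obj <- function(z) {
    x <- .to_box(z, lo, hi)
    v <- nll_revision(revision_params(x[1], x[2], x[3], x[4]), carried,
                      data, map, config$time_grid, atoms_cache,
                      config$prob_floor)
    if (!is.finite(v)) 1e10 else v
  }
  ms <- .multistart(obj, config$n_starts, config$seed + 1L, config$maxit,
                    config$reltol, lo, hi, c("t_pip", "d1", "d2", "d3"))
  est <- ms$estimates; runs <- ms$runs
  structure(list(
    stage = "revision", estimates = est, nll = ms$nll, starts = runs,
    rev = revision_params(est[["t_pip"]], est[["d1"]], est[["d2"]],
                          est[["d3"]]),
    carried = carried$estimates,
    params = carried$params, crit = carried$crit,
    fixed = c(carried$estimates, carried$fixed),
    config = config),
    class = "fit_result")
}
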