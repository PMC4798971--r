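# Delimited-text serialization: belief maps, outcome tables, trial tables
# and fit reports. All files are self-describing plain text.

#' Write a belief map to a delimited grid file
#'
#' Header lines (prefixed `#`) record the race parameters, coherence set
#' and prior; the body is a tab-separated grid with the time grid in the
#' first column and one column per balance value.
#'
#' @param map A [build_belief_map()] object (tabulated).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_belief_map <- function(map, path) {
  if (is.null(map$logodds))
    stop("map has no tabulated grid; rebuild with tabulate = TRUE",
         call. = FALSE)
  p <- map$params
  hdr <- c(
    sprintf("# kappa\t%.12g", p$kappa),
    sprintf("# bound\t%.12g", p$bound),
    sprintf("# corr\t%.12g", p$corr),
    sprintf("# tnd_mean\t%.12g", p$tnd_mean),
    sprintf("# tnd_sd\t%.12g", p$tnd_sd),
    sprintf("# coherences\t%s", paste(map$coherences, collapse = ",")),
    sprintf("# weights\t%s", paste(map$weights, collapse = ",")),
    sprintf("# delta_grid\t%s", paste(map$delta_grid, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(cbind(t = map$t_grid, map$logodds), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a belief map written by [write_belief_map()]
#'
#' @param path File path.
#' @return A `belief_map` object (closed-form evaluation available through
#'   the stored parameters; the tabulated grid is restored as written).
#' @export
read_belief_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    sub(paste0("# ", key, "\t"), "", ln)
  }
  num <- function(key) as.numeric(get(key))
  vec <- function(key) as.numeric(strsplit(get(key), ",")[[1]])
  params <- race_params(kappa = num("kappa"), bound = num("bound"),
                        corr = num("corr"), tnd_mean = num("tnd_mean"),
                        tnd_sd = num("tnd_sd"))
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t")
  map <- build_belief_map(params, coherences = vec("coherences"),
                          prior = vec("weights"),
                          t_grid = body[[1]], delta_grid = vec("delta_grid"),
                          tabulate = FALSE)
  map$logodds <- as.matrix(body[, -1, drop = FALSE])
  dimnames(map$logodds) <- NULL
  map
}

#' Write an outcome table as tidy delimited text
#'
#' @param x An [outcome_table()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write or read a trial table
#'
#' Tab-separated text with a header row; the column schema is documented
#' in [simulate_trials()].
#'
#' @param trials A `trial_table` data frame.
#' @param path File path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a fit report as structured text
#'
#' `key = value` lines for the estimates, fixed parameters and fit
#' diagnostics, followed by the per-start table as tab-separated text.
#'
#' @param fit A `fit_result` from [fit_initial()] or [fit_revision()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("stage = %s", fit$stage), con)
  for (nm in names(fit$estimates))
    writeLines(sprintf("%s = %.6g", nm, fit$estimates[[nm]]), con)
  for (nm in names(fit$fixed))
    writeLines(sprintf("fixed.%s = %.6g", nm, fit$fixed[[nm]]), con)
  writeLines(sprintf("nll = %.6f", fit$nll), con)
  writeLines(sprintf("n_starts = %d", nrow(fit$starts)), con)
  writeLines("", con)
  utils::write.table(fit$starts, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a fitting configuration from a YAML file
#'
#' Recognized keys mirror the [fit_config()] arguments (`n_starts`,
#' `seed`, `corr`, `sigma_tnd`, `reltol`, `maxit`, `n_loser`,
#' `prob_floor`, plus a `bounds` mapping of `lower, upper` pairs and a
#' `time_grid` mapping with `from`, `to`, `by`); unstated keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A [fit_config()] object.
#' @export
read_fit_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  cfg <- fit_config()
  for (k in c("n_starts", "seed", "corr", "sigma_tnd", "n_loser",
              "prob_floor", "reltol", "maxit"))
    if (!is.null(y[[k]])) cfg[[k]] <- y[[k]]
  if (!is.null(y$bounds))
    for (k in names(y$bounds))
      cfg$bounds[[k]] <- as.numeric(unlist(y$bounds[[k]]))
  if (!is.null(y$time_grid))
    cfg$time_grid <- seq(y$time_grid$from, y$time_grid$to,
                         by = y$time_grid$by)
  cfg$n_starts <- as.integer(cfg$n_starts)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write or read a set of reach trajectories
#'
#' One packed tab-separated container with columns
#' `trial`, `t`, `x`, `y`.
#'
#' @param paths List of per-trial `(t, x, y)` data frames
#'   ([synthesize_trajectories()]).
#' @param path File path.
#' @return `path` (write) or the list of per-trial data frames (read).
#' @export
write_trajectories <- function(paths, path) {
  long <- do.call(rbind, lapply(seq_along(paths), function(i)
    cbind(trial = i, paths[[i]])))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t")
  lapply(split(long[c("t", "x", "y")], long$trial),
         function(d) { rownames(d) <- NULL; d })
}

#' Write or read a dot movie as delimited text
#'
#' Columns `frame`, `x`, `y` (deg), with the generation settings stored
#' as `# key value` header lines.
#'
#' @param movie A [generate_dot_movie()] object.
#' @param path File path.
#' @return `path` (write) or a `dot_movie` (read).
#' @export
write_dot_movie <- function(movie, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("coherence", "direction", "aperture", "density", "speed",
              "frame_rate", "n_dots", "seed"))
    writeLines(sprintf("# %s\t%s", k, attr(movie, k)), con)
  writeLines(sprintf("# n_frames\t%d", length(movie)), con)
  writeLines("frame\tx\ty", con)
  for (f in seq_along(movie)) {
    fr <- movie[[f]]
    if (nrow(fr))
      utils::write.table(cbind(f, fr), con, sep = "\t", col.names = FALSE,
                         row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dot_movie
#' @export
read_dot_movie <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key)
    sub(paste0("# ", key, "\t"), "",
        hdr[startsWith(hdr, paste0("# ", key, "\t"))])
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t")
  nf <- as.integer(get("n_frames"))
  frames <- rep(list(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("x", "y")))), nf)
  for (f in unique(body$frame)) {
    sub <- body[body$frame == f, c("x", "y")]
    frames[[f]] <- as.matrix(sub)
    rownames(frames[[f]]) <- NULL
  }
  structure(frames, class = "dot_movie",
            coherence = as.numeric(get("coherence")),
            direction = get("direction"),
            aperture = as.numeric(get("aperture")),
            density = as.numeric(get("density")),
            speed = as.numeric(get("speed")),
            frame_rate = as.numeric(get("frame_rate")),
            n_dots = as.integer(get("n_dots")),
            seed = as.integer(get("seed")))
}
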