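# Shared fixtures: the first fitted subject's parameter set is the
# workhorse generating model for most tests, with smaller grids where a
# test only needs qualitative structure.

s1_params <- function() race_params(kappa = 13.64, bound = 0.74,
                                    tnd_mean = 0.461, tnd_sd = 0.06)
s1_crit <- function() confidence_criterion(0.89)
s1_rev <- function() revision_params(0.395, d1 = 0.77, d2 = 0.24,
                                     d3 = -0.36)

coarse_tgrid <- function() seq(2e-3, 5, by = 2e-3)

# memoized expensive fixtures, shared across test files in one run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

s1_map <- function() fixture("s1_map",
  build_belief_map(s1_params(), tabulate = FALSE))

# a moderate simulated data set from the full Subject-1 model
s1_trials <- function() fixture("s1_trials",
  simulate_trials(s1_params(), s1_crit(), s1_rev(),
                  session_design(n_per = 400), seed = 101))
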