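# Shared fixtures: trajectories are expensive enough to be worth caching
# across test files.  Everything is generated in code at test time.

cc_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = cc_test_cache))
    assign(key, force(expr), envir = cc_test_cache)
  get(key, envir = cc_test_cache)
}

# default calibrated model
test_model <- function() cached("model", cc_model())

# WT limit-cycle trajectory used by many metric tests (0.02 h grid keeps the
# peak-refinement error well below the 0.01 h reporting precision)
wt_traj <- function() cached("wt_traj",
  cc_run_scenario(test_model(), "WT", horizon = 130, burn_in = 240,
                  out_dt = 0.02))

ko_traj <- function() cached("ko_traj",
  cc_run_scenario(test_model(), "KO", horizon = 130, burn_in = 240,
                  out_dt = 0.02))
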