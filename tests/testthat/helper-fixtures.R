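# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

sim_default <- function() fixture("sim_default", function()
  simulateAgingData(simulationConfig(seed = 11)))

# Full pipeline run on the default simulation (reused by pipeline and
# acceptance tests).
pipeline_default <- function() fixture("pipeline_default", function()
  runTissuePipeline(sim_default()$se, sim_default()$sets, seed = 7))

# Design shared by the regression tests: 9 ages x 2 sexes x 2 replicates.
grid_design <- function() {
  ages <- seq(3, 27, by = 3)
  list(t = rep(ages, each = 4), sex = rep(c(0, 1, 0, 1), length(ages)),
       ages = ages)
}
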