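# One full default-design simulated experiment, built once per test run
# and shared across test files (simulation + preprocessing ~ seconds).
.fixture_env <- new.env(parent = emptyenv())

fixture_experiment <- function() {
  if (is.null(.fixture_env$ex)) {
    .fixture_env$ex <- simulate_experiment(experiment_config(seed = 101))
    .fixture_env$trials <- preprocess_trials(.fixture_env$ex$trials,
                                             .fixture_env$ex$staircases)
  }
  list(ex = .fixture_env$ex, trials = .fixture_env$trials)
}
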