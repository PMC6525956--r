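# Shared fixtures: the default experiments are deterministic (noise-free
# stimuli) but moderately expensive, so they are computed once per test run.

.exp_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .exp_cache, inherits = FALSE)) {
    assign(key, fn(), envir = .exp_cache)
  }
  get(key, envir = .exp_cache)
}

default_six_unit_experiment <- function() {
  cached("six_unit", function() simulate_experiment(experiment_config(seed = 1)))
}

default_two_unit_experiment <- function() {
  cached("two_unit", function() {
    simulate_experiment(experiment_config(network = "two_unit", seed = 1))
  })
}

# small sweep for cheap structural tests
mini_experiment <- function(n_steps = 4) {
  cfg <- experiment_config(stimulus = list(n_steps = n_steps), seed = 1)
  simulate_experiment(cfg)
}

# a random spike train over [0, T): sorted uniform times, Poisson-like count
random_train <- function(T, rate_hz) {
  n <- stats::rpois(1, rate_hz * T / 1000)
  sort(stats::runif(n, 0, T * (1 - 1e-9)))
}
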