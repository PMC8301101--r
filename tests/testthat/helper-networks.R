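# Small network builders and a cache for the scaled-down protocol sweep
# (simulated once per test run and shared by the simulation-level tests).

tiny_config <- function(n_E = 1L, n_I = 1L, p_connect = 0) {
  cfg <- default_config(n_E = n_E, n_I = n_I, n_stim = 1L, beta = 1L)
  cfg$network$p_connect <- p_connect
  cfg
}

single_neuron_net <- function(seed = 1L) build_network(tiny_config(), seed)

.sim_cache <- new.env(parent = emptyenv())

# Scaled-down training-time sweep (0, 48, 96 s) used by the acceptance
# tests; cached so the simulation cost is paid once per run.
scaled_sweep <- function() {
  if (!exists("sweep", envir = .sim_cache)) {
    sweep <- training_time_sweep(scaled_config(), c(0, 48, 96), seed = 101L)
    assign("sweep", sweep, envir = .sim_cache)
  }
  get("sweep", envir = .sim_cache)
}

sweep_responses <- function(run) {
  extract_responses(run$spikes$testing, run$cue_log,
                    n_neurons = run$config$network$n_E)
}
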