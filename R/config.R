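#' Default simulation configuration
#'
#' Returns the full parameter set of the self-organizing recurrent network
#' and its stimulation protocol. Values follow the published reference
#' parameterization of the model: a population of `n_E = 1000` excitatory
#' and `n_I = 200` inhibitory conductance-based leaky integrate-and-fire
#' neurons, sparse random connectivity at `p_connect = 0.04`, STDP on the
#' recurrent excitatory synapses with synaptic normalization to
#' `W_total = 50` nS, and an adaptive firing threshold (intrinsic
#' plasticity) whose decay/increment rates set the homeostatic target rate
#' `eta_decay_ip / eta_spike_ip` (about 3 Hz).
#'
#' Units: conductances nS, voltages mV, capacitance pF, times ms (except
#' `eta_decay_ip`, mV/s, and phase durations, s).
#'
#' @param n_E,n_I excitatory / inhibitory population sizes.
#' @param n_stim number of stimuli (disjoint stimulation groups).
#' @param beta neurons per stimulation group.
#' @param training_s training-phase duration in seconds.
#' @param testing_s testing-phase duration in seconds.
#' @return A nested list with components `neuron`, `plasticity`, `network`
#'   and `protocol`.
#' @seealso [scaled_config()] for a small network preserving the same
#'   dynamical regime, [validate_config()] for checking a configuration.
#' @export
default_config <- function(n_E = 1000L, n_I = 200L, n_stim = 5L, beta = 40L,
                           training_s = 100, testing_s = 100) {
  cfg <- list(
    neuron = list(
      g_leak = 30, v_rest = -70, c_membrane = 300, tau_membrane = 20,
      tau_ampa = 2, tau_gaba = 5, v_ampa = 0, v_gaba = -85,
      sigma_noise = 1, tau_noise = 20,
      eta_decay_ip = 0.2, eta_spike_ip = 0.066,
      tau_refrac_E = 10, tau_refrac_I = 2,
      v_th_init = -55, v_th_inh = -55
    ),
    plasticity = list(
      A_plus = 0.05, A_minus = 0.05, tau_plus = 20, tau_minus = 20,
      W_total = 50
    ),
    network = list(
      n_E = as.integer(n_E), n_I = as.integer(n_I), p_connect = 0.04,
      w_ee_init = 0.5, w_other_init = 1.0
    ),
    protocol = list(
      warmup_s = 50, training_s = training_s, relaxation_s = 50,
      testing_s = testing_s,
      n_stim = as.integer(n_stim), beta = as.integer(beta),
      input_weight = 20, poisson_rate = 50,
      cycle_ms = 200, active_ms = 100, recall_period_ms = 500,
      p_cycle_active = 1, shared_poisson = TRUE,
      training_order = "random"
    ),
    dt = 0.1
  )
  cfg
}

#' Scaled-down configuration
#'
#' A small network (300 excitatory, 60 inhibitory neurons, 3 stimuli of 20
#' neurons) that exhibits the same qualitative self-organization as the
#' full-size model but simulates roughly an order of magnitude faster. The
#' testing phase is shortened to 60 s which, with 3 stimuli at one recall
#' cue per 500 ms, still yields 40 trials per stimulus -- the same per-class
#' trial count as the full protocol.
#'
#' The connection probability is rescaled to preserve the reference
#' excitatory in-degree (40 incoming EE synapses per neuron). Because
#' synaptic normalization fixes the summed incoming weight at `W_total`,
#' keeping the in-degree keeps the per-synapse weight scale -- and with it
#' EPSP sizes, the recurrent background drive and the equilibrium firing
#' thresholds -- in the same regime as the full-size network. Shrinking the
#' network at fixed `p_connect` would instead concentrate `W_total` on a
#' third as many synapses, tripling EPSPs and qualitatively changing the
#' dynamics.
#'
#' @param training_s training-phase duration in seconds.
#' @return configuration list as from [default_config()].
#' @export
scaled_config <- function(training_s = 100) {
  cfg <- default_config(n_E = 300L, n_I = 60L, n_stim = 3L, beta = 20L,
                        training_s = training_s, testing_s = 60)
  cfg$network$p_connect <- 40 / cfg$network$n_E  # reference EE in-degree
  # with fewer stimuli a group would be active in 1/3 of cycles instead of
  # 1/5; activating a source in only 3/5 of cycles keeps the per-group
  # activation rate (and hence the homeostatic threshold elevation of the
  # stimulated groups) at its reference value
  cfg$protocol$p_cycle_active <- cfg$protocol$n_stim / 5
  # start thresholds near the noise-driven equilibrium (~ -67 mV) so the
  # 50 s warm-up genuinely converges before training begins
  cfg$neuron$v_th_init <- -65
  cfg
}

# OU-noise calibration factor: the membrane low-pass (rate a = g_leak/c) of
# an OU process (rate 1/tau_noise, sd sigma) has stationary sd
# sigma * (calib/tau_membrane) / sqrt(a*(a + 1/tau_noise)); calib below makes
# the subthreshold membrane-voltage noise sd equal sigma_noise.
noise_calibration <- function(neuron) {
  a <- neuron$g_leak / neuron$c_membrane
  neuron$tau_membrane * sqrt(a * (a + 1 / neuron$tau_noise))
}

# flatten neuron+plasticity params and add derived quantities for the C++ core
sim_params <- function(cfg) {
  p <- c(cfg$neuron, cfg$plasticity)
  p$noise_calib <- noise_calibration(cfg$neuron)
  p
}

#' Validate a configuration
#'
#' Checks parameter ranges, population sizes and protocol consistency, and
#' warns where values deviate from the reference parameterization of
#' [default_config()]. Scaling `n_E`, `n_I`, `n_stim`, `beta` and phase
#' durations is considered legitimate and is not flagged.
#'
#' @param cfg configuration list as from [default_config()].
#' @return A data frame report with columns `level` (`"error"`/`"warning"`),
#'   `key` and `message`; zero rows for a clean configuration.
#' @export
validate_config <- function(cfg) {
  rep <- list()
  add <- function(level, key, message)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, key = key,
                                           message = message)
  need <- list(
    neuron = c("g_leak", "v_rest", "c_membrane", "tau_membrane", "tau_ampa",
               "tau_gaba", "v_ampa", "v_gaba", "sigma_noise", "tau_noise",
               "eta_decay_ip", "eta_spike_ip", "tau_refrac_E", "tau_refrac_I"),
    plasticity = c("A_plus", "A_minus", "tau_plus", "tau_minus", "W_total"),
    network = c("n_E", "n_I", "p_connect", "w_ee_init", "w_other_init"),
    protocol = c("warmup_s", "training_s", "relaxation_s", "testing_s",
                 "n_stim", "beta", "input_weight", "poisson_rate",
                 "cycle_ms", "active_ms", "recall_period_ms",
                 "p_cycle_active", "shared_poisson", "training_order")
  )
  for (sec in names(need)) {
    missing <- setdiff(need[[sec]], names(cfg[[sec]]))
    for (k in missing) add("error", k, sprintf("missing key '%s' in section '%s'", k, sec))
  }
  if (length(rep)) return(do.call(rbind, rep))

  nw <- cfg$network; pr <- cfg$protocol; ne <- cfg$neuron
  if (nw$p_connect < 0 || nw$p_connect > 1)
    add("error", "p_connect", "connection probability must be in [0, 1]")
  if (nw$n_E <= 0 || nw$n_I <= 0)
    add("error", "n_E/n_I", "population sizes must be positive")
  if (pr$n_stim * pr$beta > nw$n_E)
    add("error", "n_stim*beta", "stimulation groups do not fit into the excitatory population")
  if (any(unlist(pr[c("warmup_s", "training_s", "relaxation_s", "testing_s")]) < 0))
    add("error", "durations", "phase durations must be >= 0")
  if (!(ne$v_gaba < ne$v_rest && ne$v_rest < ne$v_ampa))
    add("error", "reversal potentials", "need v_gaba < v_rest < v_ampa")
  taus <- unlist(ne[c("tau_membrane", "tau_ampa", "tau_gaba", "tau_noise",
                      "tau_refrac_E", "tau_refrac_I")])
  if (any(taus <= 0)) add("error", "time constants", "all time constants must be > 0")
  if (cfg$plasticity$W_total <= 0) add("error", "Wtotal", "W_total must be > 0")
  if (pr$p_cycle_active <= 0 || pr$p_cycle_active > 1)
    add("error", "p_cycle_active", "per-cycle activation probability must be in (0, 1]")
  if (cfg$plasticity$A_plus < 0 || cfg$plasticity$A_minus < 0)
    add("error", "A_plus/A_minus", "STDP amplitudes must be >= 0")

  ref <- default_config()
  for (sec in c("neuron", "plasticity")) {
    for (k in names(ref[[sec]])) {
      if (k %in% c("v_th_init", "v_th_inh")) next
      if (!isTRUE(all.equal(cfg[[sec]][[k]], ref[[sec]][[k]])))
        add("warning", k, sprintf("'%s' = %g deviates from reference value %g",
                                  k, cfg[[sec]][[k]], ref[[sec]][[k]]))
    }
  }
  if (length(rep)) do.call(rbind, rep)
  else data.frame(level = character(), key = character(), message = character())
}
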